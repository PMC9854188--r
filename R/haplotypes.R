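#' Construct a marker map
#'
#' A marker map is the coordinate backbone of a scan: one row per biallelic
#' SNP with chromosome label, 1-based base-pair position, identifier and the
#' two alleles. Positions must be strictly increasing within each chromosome;
#' rows are sorted by (chrom, pos) on construction.
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based positions.
#' @param snp_id character vector of marker identifiers.
#' @param ref_allele,alt_allele allele strings (single bases for SNPs).
#' @return A `data.frame` of class `marker_map` with columns `chrom`, `pos`,
#'   `snp_id`, `ref_allele`, `alt_allele`.
#' @export
marker_map <- function(chrom, pos, snp_id = NULL,
                       ref_allele = "A", alt_allele = "G") {
  n <- length(pos)
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(n))
  mm <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    snp_id = as.character(snp_id),
    ref_allele = rep_len(as.character(ref_allele), n),
    alt_allele = rep_len(as.character(alt_allele), n),
    stringsAsFactors = FALSE
  )
  ord <- order(mm$chrom, mm$pos)
  if (is.unsorted(ord)) mm <- mm[ord, , drop = FALSE]
  rownames(mm) <- NULL
  validate_marker_map(mm)
  class(mm) <- c("marker_map", "data.frame")
  mm
}

validate_marker_map <- function(mm) {
  stopifnot(all(c("chrom", "pos", "snp_id", "ref_allele", "alt_allele") %in%
                  names(mm)))
  for (ch in unique(mm$chrom)) {
    p <- mm$pos[mm$chrom == ch]
    if (any(diff(p) <= 0))
      stop("marker positions must be strictly increasing within chromosome ",
           ch)
  }
  invisible(mm)
}

#' Construct a phased haplotype set
#'
#' The substrate of all component statistics: a 0/1 allele matrix with one
#' row per haplotype (two per diploid sample) and one column per marker of
#' the embedded [marker_map()]. Entries count copies of the alt allele.
#' `NA` entries (missing calls) are only permitted on unphased, pre-QC data;
#' scanning operations require complete phased data and refuse to impute.
#'
#' @param alleles integer matrix in \{0,1,NA\}, `2 * n_samples` rows.
#' @param sample_ids character vector of diploid sample labels.
#' @param map a [marker_map()] with one row per column of `alleles`.
#' @param phased logical; `FALSE` marks genotype-only ingestion (e.g. an
#'   unphased PLINK .ped), which is usable for QC and allele frequencies but
#'   not for haplotype statistics.
#' @return An object of class `haplotype_set`: a list with elements
#'   `alleles`, `sample_ids`, `sample_of_haplotype`, `map`, `phased`.
#' @export
haplotype_set <- function(alleles, sample_ids, map, phased = TRUE) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) != 2L * length(sample_ids))
    stop("haplotype rows (", nrow(alleles), ") must equal 2 x samples (",
         length(sample_ids), ")")
  if (ncol(alleles) != nrow(map))
    stop("allele columns (", ncol(alleles), ") must match marker map rows (",
         nrow(map), ")")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids")
  bad <- alleles[!is.na(alleles)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("alleles must be coded 0/1 (alt-allele dosage per haplotype)")
  soh <- rep(sample_ids, each = 2L)
  rownames(alleles) <- paste0(soh, "_", rep(1:2, length(sample_ids)))
  structure(
    list(alleles = alleles, sample_ids = as.character(sample_ids),
         sample_of_haplotype = soh, map = map, phased = isTRUE(phased)),
    class = "haplotype_set"
  )
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", length(x$sample_ids), "samples,",
      nrow(x$alleles), "haplotypes,", ncol(x$alleles), "markers on",
      length(unique(x$map$chrom)), "chromosome(s);",
      if (x$phased) "phased" else "unphased",
      if (anyNA(x$alleles)) "(has missing calls)" else "(complete)", "\n")
  invisible(x)
}

#' @export
n_samples <- function(hs) length(hs$sample_ids)

hap_rows_for <- function(hs, ids) {
  miss <- setdiff(ids, hs$sample_ids)
  if (length(miss))
    stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  which(hs$sample_of_haplotype %in% ids)
}

require_complete_phased <- function(hs, what = "this operation") {
  if (!hs$phased)
    stop(what, " requires phased haplotypes; data was ingested as ",
         "unphased genotypes")
  if (anyNA(hs$alleles))
    stop(what, " requires complete data; impute/phase upstream ",
         "(imputation is out of scope)")
  invisible(hs)
}

#' Per-SNP alternate-allele frequencies
#'
#' Frequencies are computed over the `2 * length(ids)` haplotypes of the
#' named samples (all samples by default). Missing calls are excluded from
#' the denominator marker by marker.
#'
#' @param hs a [haplotype_set()].
#' @param ids sample labels to include; default all.
#' @return Numeric vector in \[0,1\], one entry per marker.
#' @export
allele_frequencies <- function(hs, ids = hs$sample_ids) {
  if (!length(ids)) stop("ids must be non-empty")
  rows <- hap_rows_for(hs, ids)
  colMeans(hs$alleles[rows, , drop = FALSE], na.rm = TRUE)
}

#' Define a selected-vs-reference cohort contrast
#'
#' @param selected_ids,reference_ids disjoint, non-empty sample label sets.
#' @param label contrast name used in reports.
#' @return An object of class `cohort_contrast`.
#' @export
cohort_contrast <- function(selected_ids, reference_ids,
                            label = "selected_vs_reference") {
  selected_ids <- as.character(selected_ids)
  reference_ids <- as.character(reference_ids)
  if (!length(selected_ids) || !length(reference_ids))
    stop("contrast error: both cohorts must be non-empty")
  if (length(intersect(selected_ids, reference_ids)))
    stop("contrast error: cohorts overlap (",
         paste(intersect(selected_ids, reference_ids), collapse = ", "), ")")
  structure(list(selected_ids = selected_ids, reference_ids = reference_ids,
                 label = label),
            class = "cohort_contrast")
}

#' Split a haplotype set into selected and reference cohorts
#'
#' @param hs a [haplotype_set()].
#' @param contrast a [cohort_contrast()]; every id must be present in `hs`.
#' @return List with elements `selected` and `reference`, both
#'   `haplotype_set`s over the same marker map.
#' @export
split_cohorts <- function(hs, contrast) {
  stopifnot(inherits(contrast, "cohort_contrast"))
  subset_one <- function(ids) {
    rows <- hap_rows_for(hs, ids)
    haplotype_set(hs$alleles[rows, , drop = FALSE], ids, hs$map,
                  phased = hs$phased)
  }
  list(selected = subset_one(contrast$selected_ids),
       reference = subset_one(contrast$reference_ids))
}

#' Read a cohort contrast from a two-column file
#'
#' Expects a tab- or whitespace-separated file with columns `sample_id` and
#' `cohort`, the latter containing the strings `selected` and `reference`.
#'
#' @param path file path.
#' @param label contrast label; default the file base name.
#' @return A [cohort_contrast()].
#' @export
read_contrast <- function(path, label = NULL) {
  tab <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(tab) < 2)
    stop("contrast file needs two columns: sample_id, cohort")
  names(tab)[1:2] <- c("sample_id", "cohort")
  grp <- tolower(tab$cohort)
  if (!all(grp %in% c("selected", "reference")))
    stop("cohort column must contain only 'selected'/'reference'")
  cohort_contrast(tab$sample_id[grp == "selected"],
                  tab$sample_id[grp == "reference"],
                  label = if (is.null(label))
                    sub("\\.[^.]*$", "", basename(path)) else label)
}
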