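#' Read phased genotypes from a VCF file
#'
#' Ingests biallelic SNP records on the declared autosomes into a
#' [haplotype_set()] plus [marker_map()]. Genotypes must carry a GT field;
#' under `strict = TRUE` any unphased ("/"-separated) call is an error,
#' otherwise unphased records are skipped with a warning. Multiallelic and
#' non-SNP records are skipped. Missing calls become `NA` haplotype entries.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param autosomes character vector of chromosome labels to keep; records
#'   on other sequences are dropped.
#' @param strict logical; error (rather than skip) on unphased genotypes.
#' @return A list with elements `hs` ([haplotype_set()]) and `map`
#'   ([marker_map()]).
#' @export
read_vcf <- function(path, autosomes = as.character(1:31), strict = TRUE) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown"))
  if (!("GT" %in% names(VariantAnnotation::geno(vcf))))
    stop("format error: VCF has no GT field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  alt <- rep(NA_character_, length(n_alt))
  alt[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  keep <- chrom %in% autosomes & n_alt == 1L &
    nchar(ref) == 1L & !is.na(alt) & nchar(alt) == 1L
  gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  chrom <- chrom[keep]
  pos <- BiocGenerics::start(rr)[keep]
  ids <- names(rr)[keep]
  ref <- ref[keep]
  alt <- alt[keep]
  if (!nrow(gt)) stop("no biallelic autosomal SNPs found in ", path)

  unphased <- grepl("/", gt, fixed = TRUE) & gt != "./."
  if (any(unphased)) {
    if (strict)
      stop("phasing error: ", sum(unphased),
           " unphased genotype(s) (use strict = FALSE to skip those records)")
    drop_rec <- rowSums(matrix(unphased, nrow = nrow(gt))) > 0
    warning("skipping ", sum(drop_rec), " record(s) with unphased genotypes")
    gt <- gt[!drop_rec, , drop = FALSE]
    chrom <- chrom[!drop_rec]; pos <- pos[!drop_rec]; ids <- ids[!drop_rec]
    ref <- ref[!drop_rec]; alt <- alt[!drop_rec]
  }

  samples <- colnames(gt)
  n_snp <- nrow(gt)
  alleles <- matrix(NA_integer_, nrow = 2L * length(samples), ncol = n_snp)
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  to_int <- function(a) {
    out <- rep(NA_integer_, length(a))
    out[a == "0"] <- 0L
    out[a == "1"] <- 1L
    out
  }
  # gt is SNP x sample; haplotype rows are sample-major
  alleles[seq(1L, by = 2L, length.out = length(samples)), ] <- t(matrix(to_int(a1), nrow = n_snp))
  alleles[seq(2L, by = 2L, length.out = length(samples)), ] <- t(matrix(to_int(a2), nrow = n_snp))

  mm <- marker_map(chrom, pos, ids, ref, alt)
  ord <- order(chrom, pos)
  hs <- haplotype_set(alleles[, ord, drop = FALSE], samples, mm, phased = TRUE)
  list(hs = hs, map = mm)
}

#' Write a haplotype set to a phased VCF
#'
#' Emits a minimal VCF v4.2 with phased GT entries, suitable for round
#' tripping through [read_vcf()]. Output is byte-stable: no timestamps.
#'
#' @param hs a phased [haplotype_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(hs, path) {
  require_complete_phased(hs, "write_vcf")
  mm <- hs$map
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=csscan",
    paste0("##contig=<ID=", unique(mm$chrom), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", hs$sample_ids), collapse = "\t")
  ), con)
  h1 <- hs$alleles[seq(1L, nrow(hs$alleles), by = 2L), , drop = FALSE]
  h2 <- hs$alleles[seq(2L, nrow(hs$alleles), by = 2L), , drop = FALSE]
  for (j in seq_len(nrow(mm))) {
    gts <- paste0(h1[, j], "|", h2[, j])
    writeLines(paste(c(mm$chrom[j], mm$pos[j], mm$snp_id[j],
                       mm$ref_allele[j], mm$alt_allele[j], ".", "PASS", ".",
                       "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}
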