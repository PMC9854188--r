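#' Scan configuration
#'
#' Bundles every tunable of the full scan. Defaults follow common CSS
#' practice: 100 kb smoothing for dense panels (use 1 Mb for ~50K-array
#' density), genome-wide top 0.1%/1% empirical thresholds, < 1 Mb cluster
#' merging, +/-0.5 Mb flanks, and QC at missing rate > 0.05 / MAF < 0.01.
#'
#' @param genotypes path to a phased VCF or a PLINK prefix.
#' @param contrast a [cohort_contrast()] or path to a contrast file
#'   (see [read_contrast()]).
#' @param annotation optional BED/GFF3 gene annotation path or gene
#'   `data.frame` (see [read_genes()]).
#' @param format `"vcf"` or `"plink"`; guessed from the path by default.
#' @param autosomes chromosome labels to keep on VCF ingestion.
#' @param window_bp smoothing window (bp).
#' @param top_fracs significance fractions, smallest first.
#' @param merge_bp cluster merge distance (bp).
#' @param flank_bp flank width (bp).
#' @param gap_bp intra-cluster gap; defaults to `window_bp`.
#' @param min_top1 minimum top-1% SNPs per cluster.
#' @param max_missing,min_maf QC thresholds (applied only when the input
#'   has missing calls).
#' @param ehh_truncation,ehh_max_gap EHH settings (see [ehh()]).
#' @param out_dir output directory.
#' @return A validated `scan_config` list.
#' @export
scan_config <- function(genotypes, contrast, annotation = NULL,
                        format = NULL, autosomes = as.character(1:31),
                        window_bp = 100000, top_fracs = c(0.001, 0.01),
                        merge_bp = 1000000, flank_bp = 500000,
                        gap_bp = NULL, min_top1 = 5L,
                        max_missing = 0.05, min_maf = 0.01,
                        ehh_truncation = 0.05, ehh_max_gap = 200000,
                        out_dir = ".") {
  if (is.null(format))
    format <- if (grepl("\\.vcf(\\.gz)?$", genotypes)) "vcf" else "plink"
  stopifnot(window_bp > 0, merge_bp > 0, flank_bp > 0,
            all(top_fracs > 0 & top_fracs < 1),
            !is.unsorted(top_fracs))
  cfg <- list(genotypes = genotypes, contrast = contrast,
              annotation = annotation, format = format,
              autosomes = autosomes, window_bp = window_bp,
              top_fracs = top_fracs, merge_bp = merge_bp,
              flank_bp = flank_bp,
              gap_bp = if (is.null(gap_bp)) window_bp else gap_bp,
              min_top1 = min_top1, max_missing = max_missing,
              min_maf = min_maf, ehh_truncation = ehh_truncation,
              ehh_max_gap = ehh_max_gap, out_dir = out_dir)
  class(cfg) <- "scan_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full composite selection signal scan
#'
#' Orchestrates ingest, QC, cohort split, component statistics, CSS
#' combination, smoothing, empirical thresholds, cluster calling/merging/
#' ranking, and gene mapping; writes the per-SNP scan table, QC report,
#' region report, BED intervals and a log. Deterministic given fixed
#' inputs.
#'
#' @param config a [scan_config()].
#' @return Invisibly, a list with `track`, `regions`, `scores`,
#'   `qc_report`, `thresholds` and the output `paths`.
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("csscan scan log",
                 paste0("genotypes: ", config$genotypes),
                 paste0("window_bp: ", config$window_bp))

  gt <- stage("ingest", {
    if (config$format == "vcf") read_vcf(config$genotypes, config$autosomes)
    else read_plink(config$genotypes)
  })
  hs <- gt$hs
  log_lines <- c(log_lines, paste0("markers ingested: ", ncol(hs$alleles)),
                 paste0("samples: ", length(hs$sample_ids)))

  qc_report <- NULL
  if (anyNA(hs$alleles)) {
    qc <- stage("qc", qc_filter(hs, config$max_missing, config$min_maf))
    hs <- qc$hs
    qc_report <- qc$report
    log_lines <- c(log_lines, paste0("markers after QC: ", ncol(hs$alleles)))
  }

  contrast <- stage("contrast", {
    if (inherits(config$contrast, "cohort_contrast")) config$contrast
    else read_contrast(config$contrast)
  })
  cohorts <- stage("contrast", split_cohorts(hs, contrast))

  scores <- stage("components",
                  component_scores(cohorts$selected, cohorts$reference,
                                   config$ehh_truncation,
                                   config$ehh_max_gap))
  track <- stage("css", css_track(scores, hs$map, config$window_bp,
                                  config$top_fracs))
  th <- attr(track, "thresholds")
  log_lines <- c(log_lines,
                 paste0("threshold ", names(th), ": ",
                        formatC(th, digits = 6, format = "g")))

  regions <- stage("regions", {
    r <- call_clusters(track, config$gap_bp, config$min_top1)
    r <- merge_clusters(r, config$merge_bp)
    r <- rank_regions(r)
    attach_flanks(r, config$flank_bp)
  })
  stopifnot(nrow(track) == ncol(hs$alleles))
  log_lines <- c(log_lines, paste0("regions called: ", nrow(regions)))

  if (!is.null(config$annotation)) {
    genes <- stage("genes", {
      if (is.character(config$annotation)) {
        if (!file.exists(config$annotation))
          stop("annotation file not found: ", config$annotation)
        read_genes(config$annotation)
      } else config$annotation
    })
    regions <- stage("genes", map_genes(regions, genes, config$flank_bp))
  }

  paths <- c(
    scan = write_css_track(track, file.path(config$out_dir,
                                            "scan_table.tsv")),
    write_report(regions, file.path(config$out_dir, "scan")))
  if (!is.null(qc_report))
    paths <- c(paths, qc = write_qc_report(
      qc_report, file.path(config$out_dir, "qc_report.tsv")))
  log_path <- file.path(config$out_dir, "scan_log.txt")
  writeLines(log_lines, log_path)
  paths <- c(paths, log = log_path)

  invisible(list(track = track, regions = regions, scores = scores,
                 qc_report = qc_report, thresholds = th, paths = paths))
}

#' Genotype-class frequencies at one SNP by group
#'
#' Tabulates the frequencies of the three genotype classes (ref hom, het,
#' alt hom, labelled with the map's allele letters) per sample group,
#' each row summing to 1.
#'
#' @param hs a [haplotype_set()].
#' @param snp_id marker identifier.
#' @param grouping named character vector or factor mapping sample id to
#'   group label (e.g. breed).
#' @return `data.frame` with columns `group`, `n`, and one frequency
#'   column per genotype class.
#' @export
summarize_genotype_frequencies <- function(hs, snp_id, grouping) {
  j <- match(snp_id, hs$map$snp_id)
  if (is.na(j)) stop("lookup error: unknown snp_id ", snp_id)
  grouping <- grouping[hs$sample_ids]
  if (anyNA(grouping))
    stop("lookup error: grouping missing for sample(s) ",
         paste(hs$sample_ids[is.na(grouping)], collapse = ", "))
  n <- length(hs$sample_ids)
  dose <- hs$alleles[seq(1L, 2L * n, 2L), j] +
    hs$alleles[seq(2L, 2L * n, 2L), j]
  r <- hs$map$ref_allele[j]
  a <- hs$map$alt_allele[j]
  classes <- c(paste0(r, r), paste0(r, a), paste0(a, a))
  out <- do.call(rbind, lapply(split(dose, grouping), function(d) {
    tab <- tabulate(d + 1L, nbins = 3L)
    tab / sum(tab)
  }))
  colnames(out) <- classes
  data.frame(group = rownames(out),
             n = as.integer(table(grouping)[rownames(out)]),
             out, check.names = FALSE, row.names = NULL)
}
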