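#' Marker quality control
#'
#' Removes markers whose genotype missing rate exceeds `max_missing`
#' (strictly greater) or whose minor-allele frequency falls below `min_maf`
#' (strictly less); markers sitting exactly at either threshold survive.
#' Both statistics are computed over all samples pooled, matching QC applied
#' to a merged panel before any cohort contrast is formed.
#'
#' @param hs a [haplotype_set()] (missing calls allowed).
#' @param max_missing maximum tolerated missing-call rate (default 0.05).
#' @param min_maf minimum tolerated minor-allele frequency (default 0.01).
#' @return A list: `hs` (filtered set), `map` (filtered map), and `report`,
#'   a one-row `data.frame` with columns `n_input`, `n_fail_missing`,
#'   `n_fail_maf`, `n_removed`, `n_retained`. Markers failing both criteria
#'   count once in `n_removed` but in both `n_fail_*` columns.
#' @export
qc_filter <- function(hs, max_missing = 0.05, min_maf = 0.01) {
  A <- hs$alleles
  miss_rate <- colMeans(is.na(A))
  p <- colMeans(A, na.rm = TRUE)
  p[is.nan(p)] <- NA_real_                      # all-missing marker
  maf <- pmin(p, 1 - p)
  fail_missing <- miss_rate > max_missing
  fail_maf <- is.na(maf) | maf < min_maf
  keep <- !(fail_missing | fail_maf)
  if (!any(keep))
    stop("empty-panel error: QC removed all ", ncol(A), " markers")
  mm <- hs$map[keep, , drop = FALSE]
  rownames(mm) <- NULL
  class(mm) <- c("marker_map", "data.frame")
  out <- haplotype_set(A[, keep, drop = FALSE], hs$sample_ids, mm,
                       phased = hs$phased)
  report <- data.frame(
    n_input = ncol(A),
    n_fail_missing = sum(fail_missing),
    n_fail_maf = sum(fail_maf),
    n_removed = sum(!keep),
    n_retained = sum(keep)
  )
  list(hs = out, map = mm, report = report)
}

#' Write a QC report as a tab-separated table
#'
#' @param report the `report` element of [qc_filter()] output.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
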