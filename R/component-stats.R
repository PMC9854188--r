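#' Per-SNP Weir-Cockerham FST between two cohorts
#'
#' Two-population Weir & Cockerham (1984) theta in its haploid formulation,
#' computed from haplotype allele counts: with cohort haplotype counts
#' \eqn{n_1, n_2}, alt frequencies \eqn{p_1, p_2} and
#' \eqn{n_c = n_1 + n_2 - (n_1^2 + n_2^2)/(n_1 + n_2)},
#' \deqn{MSP = \sum_i n_i (p_i - \bar p)^2, \quad
#'       MSG = \sum_i n_i p_i (1 - p_i) / \sum_i (n_i - 1),}
#' \deqn{\theta = (MSP - MSG) / (MSP + (n_c - 1) MSG).}
#' Negative estimates are retained (the downstream composite uses ranks,
#' which order negatives correctly). SNPs monomorphic for the same allele
#' in both cohorts have an undefined estimator and return `NA`.
#'
#' @param sel,ref [haplotype_set()]s over the same marker map.
#' @return Numeric vector, one value per SNP; `NA` where undefined.
#' @export
fst_per_snp <- function(sel, ref) {
  check_same_map(sel, ref)
  if (length(sel$sample_ids) < 2L || length(ref$sample_ids) < 2L)
    stop("each cohort needs >= 2 samples")
  n1 <- nrow(sel$alleles)
  n2 <- nrow(ref$alleles)
  p1 <- colMeans(sel$alleles)
  p2 <- colMeans(ref$alleles)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2          # r - 1 = 1
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n1 + n2 - 2)
  denom <- msp + (nc - 1) * msg
  theta <- (msp - msg) / denom
  theta[denom == 0] <- NA_real_
  theta
}

check_same_map <- function(sel, ref) {
  if (ncol(sel$alleles) != ncol(ref$alleles) ||
      !identical(sel$map$pos, ref$map$pos) ||
      !identical(sel$map$chrom, ref$map$chrom))
    stop("contract error: cohorts must share one marker map")
  invisible(TRUE)
}

#' Per-SNP change in selected allele frequency (dSAF)
#'
#' Signed difference of alt-allele frequencies,
#' `p_selected - p_reference`; positive values mean the alt allele is
#' commoner in the selected cohort. Exactly antisymmetric in its arguments.
#'
#' @inheritParams fst_per_snp
#' @return Numeric vector in \[-1, 1\].
#' @export
delta_saf <- function(sel, ref) {
  check_same_map(sel, ref)
  colMeans(sel$alleles) - colMeans(ref$alleles)
}

#' Extended haplotype homozygosity decay from a core SNP
#'
#' EHH at extension distance d is the probability that two haplotypes drawn
#' without replacement are identical over all markers spanning the core to
#' d (core allele included): \eqn{\sum_h \binom{n_h}{2} / \binom{n}{2}}
#' over distinct extended haplotypes h. EHH at distance 0 is 1 by
#' convention. Extension stops past a value below `truncation`, at an
#' inter-marker gap above `max_gap`, or at the chromosome end; the terminal
#' sub-threshold value is recorded in the profile but excluded from
#' integration by [ihh()].
#'
#' @param hs a complete, phased [haplotype_set()].
#' @param core_index marker column index (1-based).
#' @param truncation EHH floor below which extension stops (default 0.05).
#' @param max_gap largest tolerated inter-marker gap in bp (default 200 kb).
#' @return An `ehh_profile`: data.frame with columns `distance` (signed bp
#'   offset from the core) and `ehh`, ordered left to right, with
#'   attributes `core_index`, `truncation`.
#' @export
ehh <- function(hs, core_index, truncation = 0.05, max_gap = 200000) {
  require_complete_phased(hs, "EHH")
  m <- ncol(hs$alleles)
  if (core_index < 1L || core_index > m)
    stop("index error: core_index ", core_index, " outside 1..", m)
  b <- chrom_bounds(hs$map)
  prof <- cpp_ehh_profile(hs$alleles, as.numeric(hs$map$pos),
                          core_index - 1L,
                          b$lo[core_index] - 1L, b$hi[core_index] - 1L,
                          truncation, max_gap)
  out <- data.frame(distance = prof$distance, ehh = prof$ehh)
  attr(out, "core_index") <- core_index
  attr(out, "truncation") <- truncation
  class(out) <- c("ehh_profile", "data.frame")
  out
}

# first/last marker index of each marker's chromosome
chrom_bounds <- function(mm) {
  r <- rle(mm$chrom)
  hi <- cumsum(r$lengths)
  lo <- c(1L, utils::head(hi, -1L) + 1L)
  idx <- rep(seq_along(r$lengths), r$lengths)
  list(lo = lo[idx], hi = hi[idx])
}

#' Integrated EHH (iHH)
#'
#' Trapezoidal integral of the EHH decay over physical distance, summed
#' over both directions from the core. Integration starts at (0 bp, EHH 1)
#' and is truncated at the profile's EHH floor: recorded values below the
#' floor contribute nothing. Units are base pairs.
#'
#' @param profile an `ehh_profile` from [ehh()].
#' @return Non-negative scalar; 0 for a core-only profile.
#' @export
ihh <- function(profile) {
  floor_ <- attr(profile, "truncation")
  if (is.null(floor_)) floor_ <- 0
  side <- function(d, e) {
    area <- 0
    d_prev <- 0
    e_prev <- 1
    for (k in seq_along(d)) {
      if (e[k] < floor_) break
      area <- area + (abs(d[k]) - d_prev) * (e_prev + e[k]) / 2
      d_prev <- abs(d[k])
      e_prev <- e[k]
    }
    area
  }
  left <- profile$distance < 0
  right <- profile$distance > 0
  side(rev(profile$distance[left]), rev(profile$ehh[left])) +
    side(profile$distance[right], profile$ehh[right])
}

ihh_all <- function(hs, truncation, max_gap) {
  b <- chrom_bounds(hs$map)
  cpp_ihh_all(hs$alleles, as.numeric(hs$map$pos), b$lo - 1L, b$hi - 1L,
              truncation, max_gap)
}

#' Unstandardized XP-EHH at one core SNP
#'
#' `ln(iHH_selected / iHH_reference)`; positive values mean longer
#' haplotype homozygosity around the core in the selected cohort. If either
#' integral is zero the statistic is unavailable and `NA` is returned.
#'
#' @inheritParams fst_per_snp
#' @param core_index marker column index (1-based).
#' @inheritParams ehh
#' @return Scalar, or `NA` when undefined.
#' @export
xpehh_raw <- function(sel, ref, core_index, truncation = 0.05,
                      max_gap = 200000) {
  i_s <- ihh(ehh(sel, core_index, truncation, max_gap))
  i_r <- ihh(ehh(ref, core_index, truncation, max_gap))
  if (i_s <= 0 || i_r <= 0) return(NA_real_)
  log(i_s) - log(i_r)              # form chosen for exact antisymmetry
}

#' Standardize raw XP-EHH genome-wide
#'
#' Subtracts the mean and divides by the standard deviation over available
#' (non-`NA`) entries; unavailable entries stay `NA`.
#'
#' @param raw numeric vector of unstandardized log-ratios.
#' @return Vector with mean 0 and sd 1 over available entries.
#' @export
xpehh_standardize <- function(raw) {
  ok <- !is.na(raw)
  if (sum(ok) < 2L) stop("need >= 2 available raw values")
  s <- stats::sd(raw[ok])
  if (s == 0) stop("degenerate-distribution error: sd of raw XP-EHH is 0")
  out <- raw
  out[ok] <- (raw[ok] - mean(raw[ok])) / s
  out
}

#' All three component statistics for a contrast
#'
#' Computes per-SNP FST, dSAF and standardized XP-EHH for a selected vs
#' reference cohort pair sharing one marker map. XP-EHH requires phased,
#' complete data; each statistic carries an availability flag per SNP
#' (FST is unavailable at SNPs monomorphic in both cohorts, XP-EHH where
#' either cohort's iHH is zero).
#'
#' @inheritParams fst_per_snp
#' @param truncation,max_gap EHH settings, see [ehh()].
#' @return An object of class `component_scores`: data.frame with columns
#'   `chrom`, `pos`, `snp_id`, `fst`, `dsaf`, `xpehh`, `xpehh_raw` and
#'   logical availability columns `fst_ok`, `dsaf_ok`, `xpehh_ok`.
#' @export
component_scores <- function(sel, ref, truncation = 0.05, max_gap = 200000) {
  check_same_map(sel, ref)
  require_complete_phased(sel, "component_scores")
  require_complete_phased(ref, "component_scores")
  fst <- fst_per_snp(sel, ref)
  dsaf <- delta_saf(sel, ref)
  i_s <- ihh_all(sel, truncation, max_gap)
  i_r <- ihh_all(ref, truncation, max_gap)
  raw <- ifelse(i_s > 0 & i_r > 0, log(i_s) - log(i_r), NA_real_)
  xp <- xpehh_standardize(raw)
  out <- data.frame(
    chrom = sel$map$chrom, pos = sel$map$pos, snp_id = sel$map$snp_id,
    fst = fst, dsaf = dsaf, xpehh = xp, xpehh_raw = raw,
    fst_ok = !is.na(fst), dsaf_ok = !is.na(dsaf), xpehh_ok = !is.na(xp),
    stringsAsFactors = FALSE
  )
  class(out) <- c("component_scores", "data.frame")
  out
}

#' Write component scores as a tab-separated table
#'
#' @param scores a [component_scores()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_component_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
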