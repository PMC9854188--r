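#' Fractional ranks
#'
#' Ranks available values ascending and maps rank k of n available values to
#' k / (n + 1), so ranks lie strictly inside (0, 1) and survive the
#' inverse-normal transform. Ties receive the mean of their tied integer
#' ranks; `NA` (unavailable) entries stay `NA` and do not consume ranks.
#'
#' @param values numeric vector, `NA` = unavailable.
#' @return Numeric vector of the same length with entries in (0, 1) or `NA`.
#' @export
fractional_rank <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("need >= 2 available values to rank")
  out <- rep(NA_real_, length(values))
  out[ok] <- rank(values[ok], ties.method = "average") / (sum(ok) + 1)
  out
}

#' Combine component statistics into the raw composite selection signal
#'
#' Each component is converted to fractional ranks (direction: larger value
#' = more evidence of selection in the target cohort), the ranks to
#' inverse-normal scores \eqn{z = \Phi^{-1}(r)}, and the scores averaged
#' per SNP over its \eqn{m_i} available components. Under the null the mean
#' score is \eqn{N(0, 1/m_i)}, so the combined one-sided p-value is
#' \eqn{p_i = 1 - \Phi(\bar z_i \sqrt{m_i})} and the CSS is
#' \eqn{-\log_{10} p_i}. SNPs with fewer available components stay in the
#' scan with the correspondingly smaller \eqn{m_i}.
#'
#' @param scores a [component_scores()] data.frame, or a plain numeric
#'   matrix of per-SNP component values (columns = components, `NA` =
#'   unavailable).
#' @return Numeric vector of per-SNP raw CSS values (\eqn{-\log_{10} p}).
#' @export
css_combine <- function(scores) {
  comp <- if (inherits(scores, "component_scores"))
    cbind(fst = scores$fst, dsaf = scores$dsaf, xpehh = scores$xpehh)
  else as.matrix(scores)
  ranks <- apply(comp, 2L, fractional_rank)
  if (is.null(dim(ranks))) ranks <- matrix(ranks, ncol = ncol(comp))
  css_from_ranks(ranks)
}

#' @rdname css_combine
#' @param ranks matrix of fractional ranks in (0, 1) (`NA` = unavailable),
#'   one row per SNP.
#' @export
css_from_ranks <- function(ranks) {
  ranks <- as.matrix(ranks)
  bad <- !is.na(ranks) & (ranks <= 0 | ranks >= 1)
  if (any(bad))
    stop("contract error: fractional ranks must lie strictly in (0, 1)")
  m <- rowSums(!is.na(ranks))
  if (any(m == 0))
    stop("every SNP needs >= 1 available component")
  z <- stats::qnorm(ranks)
  zbar <- rowMeans(z, na.rm = TRUE)
  # -log10 p with p = P(N(0,1) > zbar * sqrt(m)), in log space for stability
  -stats::pnorm(zbar * sqrt(m), lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Smooth a per-SNP track in centered physical windows
#'
#' The smoothed value at a SNP is the mean of the raw values of all SNPs on
#' the same chromosome whose position lies within half a window
#' (`window_bp / 2`) of it, the SNP itself included. Windows never cross
#' chromosome boundaries. An isolated SNP keeps its raw value.
#'
#' @param raw numeric vector of per-SNP values.
#' @param mm the [marker_map()] aligned with `raw`.
#' @param window_bp full window span in bp (100 kb for dense panels, 1 Mb
#'   for sparse ones).
#' @return Numeric vector of smoothed values.
#' @export
smooth_track <- function(raw, mm, window_bp) {
  stopifnot(length(raw) == nrow(mm), window_bp > 0)
  half <- window_bp / 2
  out <- numeric(length(raw))
  for (ch in unique(mm$chrom)) {
    idx <- which(mm$chrom == ch)
    p <- mm$pos[idx]
    x <- raw[idx]
    cs <- c(0, cumsum(x))
    # windows are closed: |pos_j - pos_i| <= half
    lo <- findInterval(p - half, p, left.open = TRUE) + 1L
    hi <- findInterval(p + half, p)
    out[idx] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

#' Genome-wide empirical thresholds and significance flags
#'
#' Pools all autosomes and flags, for each fraction f in `top_fracs`,
#' exactly `ceiling(f * n)` SNPs with the largest smoothed values. Ties at
#' a quantile boundary are broken deterministically by (chrom, pos) after
#' value. A constant track has no meaningful quantiles and is an error.
#'
#' @param smoothed numeric vector of smoothed CSS values.
#' @param mm aligned [marker_map()] (tie-break coordinates).
#' @param top_fracs named or unnamed fractions, default `c(0.001, 0.01)`.
#' @return List: `thresholds` (smallest flagged value per fraction) and
#'   `flags`, a logical matrix with one column per fraction.
#' @export
empirical_thresholds <- function(smoothed, mm, top_fracs = c(0.001, 0.01)) {
  n <- length(smoothed)
  if (n < 1 / min(top_fracs))
    stop("threshold error: need >= ", ceiling(1 / min(top_fracs)),
         " SNPs for the smallest fraction")
  if (max(smoothed) == min(smoothed))
    stop("threshold error: smoothed track is constant")
  ord <- order(-smoothed, mm$chrom, mm$pos)
  flags <- matrix(FALSE, n, length(top_fracs),
                  dimnames = list(NULL, paste0("top", top_fracs)))
  thresholds <- stats::setNames(numeric(length(top_fracs)),
                                colnames(flags))
  for (k in seq_along(top_fracs)) {
    n_top <- ceiling(top_fracs[k] * n)
    flags[ord[seq_len(n_top)], k] <- TRUE
    thresholds[k] <- smoothed[ord[n_top]]
  }
  list(thresholds = thresholds, flags = flags)
}

#' Build the full CSS track for a contrast
#'
#' Combines component scores into raw CSS, smooths them in `window_bp`
#' windows, and attaches genome-wide empirical top-fraction flags.
#'
#' @param scores a [component_scores()] result.
#' @param mm aligned [marker_map()].
#' @param window_bp smoothing window span in bp.
#' @param top_fracs significance fractions (default top 0.1% and top 1%).
#' @return A `css_track` data.frame: `chrom`, `pos`, `snp_id`, `raw_css`,
#'   `smoothed_css`, `top001`, `top01` (logical flags for the two default
#'   fractions), with attributes `thresholds` and `window_bp`.
#' @export
css_track <- function(scores, mm, window_bp = 100000,
                      top_fracs = c(0.001, 0.01)) {
  raw <- css_combine(scores)
  sm <- smooth_track(raw, mm, window_bp)
  th <- empirical_thresholds(sm, mm, top_fracs)
  out <- data.frame(chrom = mm$chrom, pos = mm$pos, snp_id = mm$snp_id,
                    raw_css = raw, smoothed_css = sm,
                    stringsAsFactors = FALSE)
  out$top001 <- th$flags[, 1]
  out$top01 <- th$flags[, 2]
  attr(out, "thresholds") <- th$thresholds
  attr(out, "window_bp") <- window_bp
  class(out) <- c("css_track", "data.frame")
  out
}

#' Write a CSS scan track as a tab-separated table
#'
#' @param track a [css_track()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_css_track <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
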