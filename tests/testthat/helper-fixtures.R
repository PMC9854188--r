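# Fixture builders and independent brute-force oracles shared by the suite.
# Oracles deliberately avoid the code paths they check.

# haplotype_set from a plain matrix; one map position per 10 kb by default
toy_hs <- function(alleles, pos = NULL, chrom = "1", phased = TRUE,
                   prefix = "s") {
  alleles <- as.matrix(alleles)
  n_sam <- nrow(alleles) / 2
  if (is.null(pos)) pos <- seq_len(ncol(alleles)) * 10000L
  mm <- marker_map(rep(chrom, ncol(alleles)), pos)
  haplotype_set(alleles, paste0(prefix, seq_len(n_sam)), mm, phased = phased)
}

random_cohorts <- function(n_sel = 5, n_ref = 8, n_snp = 12, seed = 1) {
  set.seed(seed)
  p <- runif(n_snp, 0.1, 0.9)
  draw <- function(n) matrix(rbinom(2 * n * n_snp, 1, rep(p, each = 2 * n)),
                             nrow = 2 * n)
  pos <- sort(sample.int(5e5, n_snp))
  mm <- marker_map(rep("1", n_snp), pos)
  list(sel = haplotype_set(draw(n_sel), paste0("S", 1:n_sel), mm),
       ref = haplotype_set(draw(n_ref), paste0("R", 1:n_ref), mm),
       map = mm)
}

# Weir-Cockerham theta via R's one-way ANOVA mean squares (method of
# moments), per locus: an independent route to the same estimator.
oracle_fst_anova <- function(x1, x2) {
  y <- c(x1, x2)
  g <- factor(rep(c("a", "b"), c(length(x1), length(x2))))
  ms <- suppressWarnings(anova(stats::lm(y ~ g)))[["Mean Sq"]]  # perfect fits
  msb <- ms[1]
  msw <- ms[2]
  n1 <- length(x1); n2 <- length(x2)
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  denom <- msb + (nc - 1) * msw
  if (denom == 0) return(NA_real_)
  (msb - msw) / denom
}

# EHH by exhaustive haplotype-string counting over the span core..j
oracle_ehh <- function(A, pos, core, truncation = 0.05, max_gap = 2e5) {
  n <- nrow(A)
  span_ehh <- function(cols) {
    key <- apply(A[, cols, drop = FALSE], 1, paste, collapse = "")
    cnt <- table(key)
    sum(choose(cnt, 2)) / choose(n, 2)
  }
  one_side <- function(dir) {
    d <- numeric(0); e <- numeric(0)
    prev <- pos[core]
    j <- core + dir
    while (j >= 1 && j <= ncol(A)) {
      if (abs(pos[j] - prev) > max_gap) break
      cols <- if (dir > 0) core:j else j:core
      v <- span_ehh(cols)
      d <- c(d, pos[j] - pos[core]); e <- c(e, v)
      if (v < truncation) break
      prev <- pos[j]
      j <- j + dir
    }
    list(d = d, e = e)
  }
  l <- one_side(-1); r <- one_side(1)
  list(distance = c(rev(l$d), 0, r$d), ehh = c(rev(l$e), 1, r$e))
}

# trapezoid integration of an (distance, ehh) decay, floor-truncated
oracle_ihh <- function(distance, ehh, truncation = 0.05) {
  side <- function(d, e) {
    a <- 0; dp <- 0; ep <- 1
    for (k in seq_along(d)) {
      if (e[k] < truncation) break
      a <- a + (abs(d[k]) - dp) * (ep + e[k]) / 2
      dp <- abs(d[k]); ep <- e[k]
    }
    a
  }
  lt <- distance < 0; rt <- distance > 0
  side(rev(distance[lt]), rev(ehh[lt])) + side(distance[rt], ehh[rt])
}

# O(n^2) all-pairs window mean
oracle_smooth <- function(raw, chrom, pos, window_bp) {
  half <- window_bp / 2
  vapply(seq_along(raw), function(i) {
    inwin <- chrom == chrom[i] & abs(pos - pos[i]) <= half
    mean(raw[inwin])
  }, 0)
}

# sort-based top-fraction flags with (value desc, chrom, pos) tie-break
oracle_flags <- function(x, chrom, pos, frac) {
  k <- ceiling(frac * length(x))
  ord <- order(-x, chrom, pos)
  out <- logical(length(x))
  out[ord[seq_len(k)]] <- TRUE
  out
}

# exhaustive maximal-run cluster enumeration
oracle_clusters <- function(chrom, pos, top01, top001, gap_bp, min_top1 = 5) {
  res <- NULL
  for (ch in unique(chrom)) {
    i <- which(chrom == ch & top01)
    if (!length(i)) next
    runs <- split(i, cumsum(c(1, diff(pos[i]) > gap_bp)))
    for (r in runs) {
      if (length(r) >= min_top1 && any(top001[r]))
        res <- rbind(res, data.frame(chrom = ch, start_bp = min(pos[r]),
                                     stop_bp = max(pos[r]),
                                     n_top1 = length(r),
                                     n_top01 = sum(top001[r])))
    }
  }
  res
}

# all-pairs closed-interval overlap
oracle_overlap <- function(gchrom, gstart, gstop, rchrom, rstart, rstop) {
  which(gchrom == rchrom & gstart <= rstop & gstop >= rstart)
}
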