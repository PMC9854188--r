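#' Simulation configuration for a two-cohort sweep panel
#'
#' Defaults describe the desk-scale stated world used throughout the test
#' suite: a 19-vs-81 diploid contrast (a rare breed against a pooled
#' reference), two chromosomes of 2,500 biallelic SNPs at a mean spacing of
#' 20 kb (about 50 Mb per chromosome, an intermediate marker density between
#' a 500K array and a 50K array on a ~2.4 Gb genome), a neutral
#' Balding-Nichols differentiation background of FST = 0.05 (typical of
#' closely related horse populations), and one implanted sweep in which 80%
#' of selected-cohort haplotypes versus 10% of reference haplotypes carry a
#' founder haplotype over a +/-500 kb window around the core.
#'
#' @param n_sel,n_ref diploid cohort sizes.
#' @param n_snps SNPs per chromosome.
#' @param n_chrom number of autosomes.
#' @param mean_spacing mean inter-marker distance, bp.
#' @param background_fst Balding-Nichols differentiation parameter F in
#'   \[0, 1); 0 gives identical cohort frequencies.
#' @param sweep_chrom,sweep_pos implant site (chromosome label and bp);
#'   `sweep_pos = NULL` places the sweep at the middle marker of
#'   `sweep_chrom` once the map is realized.
#' @param carrier_frac_sel,carrier_frac_ref probability that a haplotype of
#'   each cohort carries the founder haplotype; a detectable sweep needs
#'   `carrier_frac_sel > carrier_frac_ref`.
#' @param sweep_halfwidth_bp half-span of the founder haplotype, bp.
#' @param escape_rate per-bp rate of the geometric/exponential "escape"
#'   (recombination off the founder) that truncates copying; the default
#'   2e-6 gives a 500 kb mean copied length per side.
#' @param mut_noise per-site flip probability applied to copied founder
#'   sites (mutation/genotyping noise).
#' @param seed RNG seed; every generation step derives its stream from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_sel = 19, n_ref = 81, n_snps = 2500, n_chrom = 2,
                       mean_spacing = 20000, background_fst = 0.05,
                       sweep_chrom = "1", sweep_pos = NULL,
                       carrier_frac_sel = 0.8, carrier_frac_ref = 0.1,
                       sweep_halfwidth_bp = 500000, escape_rate = 2e-6,
                       mut_noise = 0.01, seed = 1) {
  cfg <- list(n_sel = n_sel, n_ref = n_ref, n_snps = n_snps,
              n_chrom = n_chrom, mean_spacing = mean_spacing,
              background_fst = background_fst,
              sweep_chrom = as.character(sweep_chrom),
              sweep_pos = if (is.null(sweep_pos)) NULL else as.numeric(sweep_pos),
              carrier_frac_sel = carrier_frac_sel,
              carrier_frac_ref = carrier_frac_ref,
              sweep_halfwidth_bp = sweep_halfwidth_bp,
              escape_rate = escape_rate, mut_noise = mut_noise,
              seed = as.integer(seed))
  with(cfg, {
    if (n_sel < 1 || n_ref < 1 || n_snps < 1 || n_chrom < 1 ||
        mean_spacing <= 0)
      stop("config error: sizes and spacing must be positive")
    if (background_fst < 0 || background_fst >= 1)
      stop("config error: background_fst must be in [0, 1)")
    for (f in c(carrier_frac_sel, carrier_frac_ref, mut_noise))
      if (f < 0 || f > 1) stop("config error: fractions must be in [0, 1]")
  })
  class(cfg) <- "sim_config"
  cfg
}

# Derived sub-seeds keep the three generation stages on distinct RNG
# streams while remaining reproducible from one user-facing seed.
stage_seed <- function(cfg, k) (cfg$seed * 7L + k) %% .Machine$integer.max

#' Sample neutral allele frequencies (Balding-Nichols)
#'
#' Ancestral frequencies are Uniform(0.05, 0.95); each cohort's frequency
#' is drawn independently from Beta(p(1-F)/F, (1-p)(1-F)/F) with
#' F = `background_fst`, whose mean is p and whose between-cohort
#' differentiation is F. F = 0 degenerates to both cohorts sharing p.
#'
#' @param cfg a [sim_config()].
#' @return List of numeric vectors `p_anc`, `p_sel`, `p_ref` (length
#'   `n_chrom * n_snps`).
#' @export
sample_neutral_freqs <- function(cfg) {
  set.seed(stage_seed(cfg, 1L))
  m <- cfg$n_chrom * cfg$n_snps
  p <- stats::runif(m, 0.05, 0.95)
  f <- cfg$background_fst
  if (f == 0) {
    p_sel <- p_ref <- p
  } else {
    a <- p * (1 - f) / f
    b <- (1 - p) * (1 - f) / f
    p_sel <- stats::rbeta(m, a, b)
    p_ref <- stats::rbeta(m, a, b)
  }
  list(p_anc = p, p_sel = p_sel, p_ref = p_ref)
}

#' Simulate neutral phased haplotypes from cohort frequencies
#'
#' Haplotype alleles are independent Bernoulli draws from the cohort
#' frequency at each site (no background linkage disequilibrium). Marker
#' positions are cumulative exponential spacings with the configured mean,
#' independently per chromosome.
#'
#' @param freqs output of [sample_neutral_freqs()].
#' @param cfg a [sim_config()].
#' @return A phased [haplotype_set()]; selected samples are labelled
#'   `S...`, reference samples `R...`.
#' @export
simulate_neutral_haplotypes <- function(freqs, cfg) {
  set.seed(stage_seed(cfg, 2L))
  m <- cfg$n_chrom * cfg$n_snps
  stopifnot(length(freqs$p_sel) == m)
  pos <- integer(0)
  chrom <- character(0)
  for (ch in seq_len(cfg$n_chrom)) {
    gaps <- pmax(1, round(stats::rexp(cfg$n_snps, 1 / cfg$mean_spacing)))
    pos <- c(pos, cumsum(gaps))
    chrom <- c(chrom, rep(as.character(ch), cfg$n_snps))
  }
  mm <- marker_map(chrom, pos,
                   snp_id = paste0("snp", chrom, "_",
                                   sequence(rep(cfg$n_snps, cfg$n_chrom))),
                   ref_allele = "A", alt_allele = "G")
  h_sel <- 2L * cfg$n_sel
  h_ref <- 2L * cfg$n_ref
  A <- matrix(0L, nrow = h_sel + h_ref, ncol = m)
  A[seq_len(h_sel), ] <- matrix(
    stats::rbinom(h_sel * m, 1L, rep(freqs$p_sel, each = h_sel)),
    nrow = h_sel)
  A[h_sel + seq_len(h_ref), ] <- matrix(
    stats::rbinom(h_ref * m, 1L, rep(freqs$p_ref, each = h_ref)),
    nrow = h_ref)
  ids <- c(sprintf("S%03d", seq_len(cfg$n_sel)),
           sprintf("R%03d", seq_len(cfg$n_ref)))
  haplotype_set(A, ids, mm, phased = TRUE)
}

#' Implant a selective sweep into a neutral panel
#'
#' A founder haplotype is drawn over the markers within
#' `sweep_halfwidth_bp` of `sweep_pos` (allele at each site Bernoulli with
#' the current pooled frequency). Each haplotype of each cohort becomes a
#' carrier with its cohort's carrier probability. Carriers copy the founder
#' from the core marker outward until an exponential escape distance (rate
#' `escape_rate` per bp, drawn per haplotype and direction) truncates the
#' copy, then per-site flips are applied at `mut_noise`. The core site
#' itself models the beneficial mutation: carriers get the alt allele,
#' non-carriers the ref allele, so the expected core dSAF equals
#' `carrier_frac_sel - carrier_frac_ref`.
#'
#' @param hs a phased [haplotype_set()] from
#'   [simulate_neutral_haplotypes()].
#' @param cfg a [sim_config()].
#' @return List: `hs` (with the sweep implanted) and `truth`, a
#'   `sweep_truth` list recording the implant site, the core marker index
#'   and id, carrier fractions and the config echo.
#' @export
implant_sweep <- function(hs, cfg) {
  set.seed(stage_seed(cfg, 3L))
  mm <- hs$map
  on_ch <- which(mm$chrom == cfg$sweep_chrom)
  if (!length(on_ch)) stop("config error: sweep_chrom not in map")
  if (is.null(cfg$sweep_pos))
    cfg$sweep_pos <- mm$pos[on_ch[ceiling(length(on_ch) / 2)]]
  win <- on_ch[abs(mm$pos[on_ch] - cfg$sweep_pos) <= cfg$sweep_halfwidth_bp]
  if (!length(win)) stop("config error: sweep window contains no markers")
  core <- on_ch[which.min(abs(mm$pos[on_ch] - cfg$sweep_pos))]
  core_pos <- mm$pos[core]
  pooled <- colMeans(hs$alleles[, win, drop = FALSE])
  founder <- stats::rbinom(length(win), 1L, pooled)
  founder[win == core] <- 1L

  n_hap <- nrow(hs$alleles)
  h_sel <- 2L * cfg$n_sel
  frac <- c(rep(cfg$carrier_frac_sel, h_sel),
            rep(cfg$carrier_frac_ref, n_hap - h_sel))
  carrier <- stats::rbinom(n_hap, 1L, frac) == 1L
  A <- hs$alleles
  d <- mm$pos[win] - core_pos
  for (i in which(carrier)) {
    reach_left <- if (cfg$escape_rate > 0)
      stats::rexp(1, cfg$escape_rate) else Inf
    reach_right <- if (cfg$escape_rate > 0)
      stats::rexp(1, cfg$escape_rate) else Inf
    copied <- (d >= -reach_left) & (d <= reach_right)
    seg <- founder[copied]
    if (cfg$mut_noise > 0) {
      flips <- stats::rbinom(length(seg), 1L, cfg$mut_noise) == 1L
      seg[flips] <- 1L - seg[flips]
    }
    A[i, win[copied]] <- seg
    A[i, core] <- 1L
  }
  A[!carrier, core] <- 0L
  truth <- structure(
    list(sweep_chrom = cfg$sweep_chrom, sweep_pos = cfg$sweep_pos,
         core_index = core, core_snp_id = mm$snp_id[core],
         core_pos = core_pos,
         carrier_frac_sel = cfg$carrier_frac_sel,
         carrier_frac_ref = cfg$carrier_frac_ref, config = cfg),
    class = "sweep_truth")
  list(hs = haplotype_set(A, hs$sample_ids, mm, phased = TRUE),
       truth = truth)
}

#' Simulate a complete two-cohort panel with one implanted sweep
#'
#' End-to-end composition of [sample_neutral_freqs()],
#' [simulate_neutral_haplotypes()] and [implant_sweep()] (the implant is
#' skipped when both carrier fractions are zero). Fully seed-deterministic.
#'
#' @param cfg a [sim_config()].
#' @return List: `hs`, `map`, `contrast` ([cohort_contrast()]), `truth`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  freqs <- sample_neutral_freqs(cfg)
  hs <- simulate_neutral_haplotypes(freqs, cfg)
  if (cfg$carrier_frac_sel > 0 || cfg$carrier_frac_ref > 0) {
    imp <- implant_sweep(hs, cfg)
    hs <- imp$hs
    truth <- imp$truth
  } else {
    truth <- NULL
  }
  contrast <- cohort_contrast(
    hs$sample_ids[seq_len(cfg$n_sel)],
    hs$sample_ids[cfg$n_sel + seq_len(cfg$n_ref)],
    label = "simulated")
  list(hs = hs, map = hs$map, contrast = contrast, truth = truth)
}

#' Write a simulated panel as a VCF fixture with truth sidecar
#'
#' Writes `sim.vcf` (phased), `contrast.tsv` (sample-to-cohort table) and,
#' when a sweep was implanted, `truth.tsv`. Output is byte-identical across
#' runs with the same config.
#'
#' @param sim output of [simulate_cohort()].
#' @param out_dir directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(out_dir, "sim.vcf")
  write_vcf(sim$hs, vcf)
  ctr <- file.path(out_dir, "contrast.tsv")
  utils::write.table(
    data.frame(sample_id = c(sim$contrast$selected_ids,
                             sim$contrast$reference_ids),
               cohort = rep(c("selected", "reference"),
                            c(length(sim$contrast$selected_ids),
                              length(sim$contrast$reference_ids)))),
    ctr, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(vcf = vcf, contrast = ctr)
  if (!is.null(sim$truth)) {
    tr <- file.path(out_dir, "truth.tsv")
    t <- sim$truth
    utils::write.table(
      data.frame(sweep_chrom = t$sweep_chrom, sweep_pos = t$sweep_pos,
                 core_pos = t$core_pos, core_snp_id = t$core_snp_id,
                 carrier_frac_sel = t$carrier_frac_sel,
                 carrier_frac_ref = t$carrier_frac_ref),
      tr, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, truth = tr)
  }
  invisible(paths)
}
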