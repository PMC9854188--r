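#' Read genotypes from PLINK files
#'
#' Accepts either a text `.ped`/`.map` pair or a binary `.bed`/`.bim`/`.fam`
#' triple (SNP-major). PLINK stores unphased genotypes, so the result is
#' flagged `phased = FALSE`: it supports QC, allele frequencies and
#' frequency-based statistics, but haplotype statistics (EHH, XP-EHH) refuse
#' it until phased haplotypes are supplied (e.g. via [read_vcf()]).
#' Heterozygous genotypes are stored with the alt allele on the first
#' haplotype row of the sample; that within-sample order is arbitrary.
#'
#' For `.ped`/`.map` input the alt allele at each SNP is the
#' alphabetically later of the observed alleles; for `.bim` input, A1
#' (column 5) is taken as alt and A2 as ref, the usual minor/major
#' convention. Markers with out-of-order positions are re-sorted with a
#' warning.
#'
#' @param prefix path prefix (without extension).
#' @return A list with elements `hs` and `map` as for [read_vcf()].
#' @export
read_plink <- function(prefix) {
  if (file.exists(paste0(prefix, ".bed"))) {
    read_plink_bed(prefix)
  } else if (file.exists(paste0(prefix, ".ped"))) {
    read_plink_ped(prefix)
  } else {
    stop("format error: neither ", prefix, ".bed nor ", prefix, ".ped exists")
  }
}

finish_plink <- function(alleles, samples, chrom, pos, snp_id, ref, alt) {
  ord <- order(chrom, pos)
  if (any(diff(ord) < 0)) {
    warning("marker positions out of order; re-sorting by (chrom, pos)")
    alleles <- alleles[, ord, drop = FALSE]
    chrom <- chrom[ord]; pos <- pos[ord]; snp_id <- snp_id[ord]
    ref <- ref[ord]; alt <- alt[ord]
  }
  mm <- marker_map(chrom, pos, snp_id, ref, alt)
  hs <- haplotype_set(alleles, samples, mm, phased = FALSE)
  list(hs = hs, map = mm)
}

read_plink_ped <- function(prefix) {
  ped <- data.table::fread(paste0(prefix, ".ped"), header = FALSE,
                           data.table = FALSE, colClasses = "character")
  map <- data.table::fread(paste0(prefix, ".map"), header = FALSE,
                           data.table = FALSE)
  n_snp <- nrow(map)
  if (ncol(ped) != 6L + 2L * n_snp)
    stop("format error: .ped has ", ncol(ped), " columns but .map implies ",
         6L + 2L * n_snp)
  samples <- ped[[2]]
  gl <- as.matrix(ped[, -(1:6), drop = FALSE])  # sample x (2*snp) letters
  a1 <- gl[, seq(1L, 2L * n_snp, by = 2L), drop = FALSE]
  a2 <- gl[, seq(2L, 2L * n_snp, by = 2L), drop = FALSE]
  ref <- alt <- character(n_snp)
  alleles <- matrix(NA_integer_, nrow = 2L * nrow(ped), ncol = n_snp)
  i1 <- seq(1L, 2L * nrow(ped), by = 2L)
  for (j in seq_len(n_snp)) {
    obs <- sort(setdiff(unique(c(a1[, j], a2[, j])), "0"))
    if (length(obs) > 2L)
      stop("format error: marker ", map[[2]][j], " has >2 alleles")
    ref[j] <- if (length(obs)) obs[1] else "A"
    alt[j] <- if (length(obs) == 2L) obs[2] else "0"
    enc <- function(a) ifelse(a == "0", NA_integer_,
                              as.integer(a == alt[j]))
    e1 <- enc(a1[, j]); e2 <- enc(a2[, j])
    # alt allele first within each het sample (arbitrary; data is unphased)
    alleles[i1, j] <- pmax(e1, e2)
    alleles[i1 + 1L, j] <- pmin(e1, e2)
  }
  finish_plink(alleles, samples, as.character(map[[1]]), as.integer(map[[4]]),
               as.character(map[[2]]), ref, alt)
}

read_plink_bed <- function(prefix) {
  bim <- data.table::fread(paste0(prefix, ".bim"), header = FALSE,
                           data.table = FALSE)
  fam <- data.table::fread(paste0(prefix, ".fam"), header = FALSE,
                           data.table = FALSE)
  n_snp <- nrow(bim)
  n_sam <- nrow(fam)
  bed <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3L + n_snp * ceiling(n_sam / 4))
  if (length(bed) < 3L || bed[1] != as.raw(0x6c) || bed[2] != as.raw(0x1b))
    stop("format error: bad .bed magic number")
  if (bed[3] != as.raw(0x01))
    stop("format error: only SNP-major .bed files are supported")
  bpl <- ceiling(n_sam / 4)
  if (length(bed) != 3L + n_snp * bpl)
    stop("format error: .bed size inconsistent with .bim/.fam counts")
  body <- bed[-(1:3)]
  # decode 2-bit codes, sample-fastest from the low bits of each byte
  bits <- matrix(as.integer(rawToBits(body)), nrow = 8L * bpl)
  b0 <- bits[seq(1L, 8L * bpl, by = 2L), , drop = FALSE][1:n_sam, , drop = FALSE]
  b1 <- bits[seq(2L, 8L * bpl, by = 2L), , drop = FALSE][1:n_sam, , drop = FALSE]
  code <- b0 + 2L * b1                      # sample x snp
  dosage <- matrix(NA_integer_, n_sam, n_snp)
  dosage[code == 0L] <- 2L                  # hom A1 = hom alt
  dosage[code == 2L] <- 1L                  # het
  dosage[code == 3L] <- 0L                  # hom A2 = hom ref
  alleles <- matrix(NA_integer_, nrow = 2L * n_sam, ncol = n_snp)
  i1 <- seq(1L, 2L * n_sam, by = 2L)
  alleles[i1, ] <- ifelse(is.na(dosage), NA_integer_,
                          as.integer(dosage >= 1L))
  alleles[i1 + 1L, ] <- ifelse(is.na(dosage), NA_integer_,
                               as.integer(dosage == 2L))
  finish_plink(alleles, as.character(fam[[2]]), as.character(bim[[1]]),
               as.integer(bim[[4]]), as.character(bim[[2]]),
               ref = as.character(bim[[6]]), alt = as.character(bim[[5]]))
}

#' Write a haplotype set as a PLINK .ped/.map pair
#'
#' Genotype letters come from the map's ref/alt alleles; missing calls are
#' written as "0". Phase is not representable in .ped and is lost.
#'
#' @param hs a [haplotype_set()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(hs, prefix) {
  mm <- hs$map
  map <- data.frame(mm$chrom, mm$snp_id, 0L, mm$pos)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- length(hs$sample_ids)
  letters_of <- function(j, a) ifelse(is.na(a), "0",
                                      ifelse(a == 1L, mm$alt_allele[j],
                                             mm$ref_allele[j]))
  h1 <- hs$alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  h2 <- hs$alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  geno <- matrix("", nrow = n, ncol = 2L * ncol(h1))
  for (j in seq_len(ncol(h1))) {
    geno[, 2L * j - 1L] <- letters_of(j, h1[, j])
    geno[, 2L * j] <- letters_of(j, h2[, j])
  }
  ped <- cbind(hs$sample_ids, hs$sample_ids, 0L, 0L, 0L, -9L, geno)
  utils::write.table(ped, paste0(prefix, ".ped"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
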