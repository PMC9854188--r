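# cluster calling, merging, ranking, gene mapping, report output

fake_track <- function(chrom, pos, smoothed, top01, top001,
                       window_bp = 1e5) {
  out <- data.frame(chrom = chrom, pos = pos, snp_id = paste0("s", seq_along(pos)),
                    raw_css = smoothed, smoothed_css = smoothed,
                    top001 = top001, top01 = top01,
                    stringsAsFactors = FALSE)
  attr(out, "window_bp") <- window_bp
  class(out) <- c("css_track", "data.frame")
  out
}

test_that("call_clusters applies the >=1 significant / >=5 support rule", {
  pos <- seq(1e5, 6e5, by = 1e5)
  # six top-1% SNPs, one also top-0.1%: qualifies
  tr <- fake_track("1", pos, smoothed = 6:1, top01 = rep(TRUE, 6),
                   top001 = c(FALSE, TRUE, rep(FALSE, 4)))
  r <- call_clusters(tr)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start_bp, 1e5)
  expect_equal(r$stop_bp, 6e5)
  expect_equal(r$n_top1, 6L)
  expect_equal(r$n_top01, 1L)
  expect_equal(r$peak_css, 6)
  # four top-1% SNPs incl. a significant one: fails the support rule
  tr4 <- fake_track("1", pos[1:4], smoothed = 4:1, top01 = rep(TRUE, 4),
                    top001 = c(TRUE, rep(FALSE, 3)))
  expect_equal(nrow(call_clusters(tr4)), 0L)
  # five top-1% including the significant one passes by default but not
  # under the stricter "five in addition" reading
  tr5 <- fake_track("1", pos[1:5], smoothed = 5:1, top01 = rep(TRUE, 5),
                    top001 = c(TRUE, rep(FALSE, 4)))
  expect_equal(nrow(call_clusters(tr5)), 1L)
  expect_equal(nrow(call_clusters(tr5, support_includes_significant = FALSE)),
               0L)
  # a gap wider than gap_bp splits the run
  tr_gap <- fake_track("1", c(pos, 5e6 + pos), smoothed = rep(6:1, 2),
                       top01 = rep(TRUE, 12),
                       top001 = rep(c(FALSE, TRUE, rep(FALSE, 4)), 2))
  expect_equal(nrow(call_clusters(tr_gap)), 2L)
})

test_that("call_clusters matches the exhaustive-run oracle on random flags", {
  set.seed(51)
  for (rep in 1:50) {
    n <- 400
    chrom <- rep(c("1", "2"), each = n / 2)
    pos <- unlist(lapply(1:2, function(i) sort(sample.int(5e6, n / 2))))
    sm <- rexp(n)
    top01 <- rep(FALSE, n)
    top01[sample.int(n, 60)] <- TRUE
    top001 <- top01 & (runif(n) < 0.25)
    tr <- fake_track(chrom, pos, sm, top01, top001, window_bp = 3e5)
    got <- call_clusters(tr)
    want <- oracle_clusters(chrom, pos, top01, top001, gap_bp = 3e5)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      want <- want[order(want$chrom, want$start_bp), ]
      expect_equal(got$start_bp, want$start_bp)
      expect_equal(got$stop_bp, want$stop_bp)
      expect_equal(got$n_top1, want$n_top1)
      expect_equal(got$n_top01, want$n_top01)
    }
  }
})

test_that("merge_clusters merges strictly-below-1Mb gaps, transitively", {
  reg <- function(chrom, start, stop) data.frame(
    chrom = chrom, start_bp = start, stop_bp = stop, n_snps = 10L,
    n_top01 = 1L, n_top1 = 5L, peak_css = 2, stringsAsFactors = FALSE)
  two <- rbind(reg("1", 1e6, 2e6), reg("1", 2.9e6, 3.5e6))  # 0.9 Mb apart
  m <- merge_clusters(two)
  expect_equal(nrow(m), 1L)
  expect_equal(m$stop_bp, 3.5e6)
  expect_equal(m$n_top1, 10L)
  exact <- rbind(reg("1", 1e6, 2e6), reg("1", 3e6, 3.5e6))  # exactly 1.0 Mb
  expect_equal(nrow(merge_clusters(exact)), 2L)
  chain <- rbind(reg("1", 1e6, 2e6), reg("1", 2.5e6, 3e6),
                 reg("1", 3.5e6, 4e6))                      # 0.5 Mb gaps
  expect_equal(nrow(merge_clusters(chain)), 1L)
  # different chromosomes never merge
  cross <- rbind(reg("1", 1e6, 2e6), reg("2", 2.1e6, 3e6))
  expect_equal(nrow(merge_clusters(cross)), 2L)
})

test_that("region pipeline is idempotent and gap-monotone", {
  set.seed(52)
  for (rep in 1:10) {
    n <- 300
    pos <- sort(sample.int(8e6, n))
    top01 <- runif(n) < 0.3
    top001 <- top01 & runif(n) < 0.3
    tr <- fake_track("1", pos, rexp(n), top01, top001, window_bp = 2e5)
    r1 <- merge_clusters(call_clusters(tr))
    expect_equal(merge_clusters(r1), r1)       # merging is a fixed point
    span <- function(g) {
      r <- call_clusters(tr, gap_bp = g)
      if (!nrow(r)) 0 else sum(r$stop_bp - r$start_bp)
    }
    expect_lte(span(1e5), span(2e5))           # smaller gap, smaller span
  }
})

test_that("rank_regions sorts by peak with positional tie-break", {
  r <- data.frame(chrom = c("3", "1", "7"), start_bp = c(1, 2, 3),
                  stop_bp = c(10, 20, 30), n_snps = 5L, n_top01 = 1L,
                  n_top1 = 6L, peak_css = c(2.50, 2.83, 2.71))
  rr <- rank_regions(r)
  expect_equal(rr$peak_css, c(2.83, 2.71, 2.50))
  expect_equal(rr$rank, 1:3)
  single <- rank_regions(r[1, ])
  expect_equal(single$rank, 1L)
  tie <- r
  tie$peak_css <- 2
  expect_equal(rank_regions(tie)$chrom, c("1", "3", "7"))
})

test_that("map_genes separates in-peak from in-flank genes", {
  regions <- data.frame(chrom = "1", start_bp = 100000L, stop_bp = 200000L,
                        n_snps = 10L, n_top01 = 2L, n_top1 = 6L,
                        peak_css = 3, rank = 1L)
  genes <- data.frame(chrom = "1",
                      start_bp = c(240000L, 150000L, 650000L, 99000L),
                      stop_bp = c(260000L, 160000L, 660000L, 100000L),
                      name = c("FLANKY", "INPEAK", "FARAWAY", "EDGE"),
                      biotype = NA_character_)
  got <- map_genes(regions, genes, flank_bp = 50000)
  expect_setequal(got$genes_peak[[1]], c("INPEAK", "EDGE"))  # 1-bp overlap
  expect_equal(got$genes_flank[[1]], "FLANKY")
  got2 <- map_genes(regions, genes, flank_bp = 500000)
  expect_setequal(got2$genes_flank[[1]], c("FLANKY", "FARAWAY"))
  bad <- genes
  bad$chrom <- "chr1"
  expect_error(map_genes(regions, bad), "namespace error")
})

test_that("map_genes matches the all-pairs interval oracle", {
  set.seed(53)
  for (rep in 1:50) {
    nr <- sample(1:5, 1)
    ng <- sample(5:30, 1)
    regions <- data.frame(
      chrom = sample(c("1", "2"), nr, replace = TRUE),
      start_bp = s <- sample.int(5e6, nr), stop_bp = s + sample.int(5e5, nr),
      n_snps = 5L, n_top01 = 1L, n_top1 = 6L, peak_css = 1, rank = 1L)
    genes <- data.frame(
      chrom = sample(c("1", "2"), ng, replace = TRUE),
      start_bp = g <- sample.int(6e6, ng), stop_bp = g + sample.int(2e5, ng),
      name = paste0("G", seq_len(ng)), biotype = NA_character_)
    got <- map_genes(regions, genes, flank_bp = 2e5)
    for (i in seq_len(nr)) {
      in_peak <- oracle_overlap(genes$chrom, genes$start_bp, genes$stop_bp,
                                regions$chrom[i], regions$start_bp[i],
                                regions$stop_bp[i])
      in_ext <- oracle_overlap(genes$chrom, genes$start_bp, genes$stop_bp,
                               regions$chrom[i],
                               max(1, regions$start_bp[i] - 2e5),
                               regions$stop_bp[i] + 2e5)
      expect_setequal(got$genes_peak[[i]], genes$name[in_peak])
      expect_setequal(got$genes_flank[[i]],
                      genes$name[setdiff(in_ext, in_peak)])
    }
  }
})

test_that("write_report emits the table and 0-based half-open BED", {
  regions <- attach_flanks(data.frame(
    chrom = "1", start_bp = 100L, stop_bp = 200L, n_snps = 6L,
    n_top01 = 1L, n_top1 = 6L, peak_css = 2.5, rank = 1L), 50L)
  prefix <- tempfile()
  paths <- write_report(regions, prefix)
  tab <- read.delim(paths["tsv"])
  expect_equal(nrow(tab), 1L)
  bed <- read.delim(paths["bed"], comment.char = "#", header = FALSE)
  expect_equal(nrow(bed), 2L)                  # peak + flank lines
  expect_equal(bed$V2[1], 99L)                 # 1-based closed -> 0-based
  expect_equal(bed$V3[1], 200L)
  expect_equal(bed$V2[2], 49L)
  # empty region list -> header-only outputs
  paths0 <- write_report(rank_regions(merge_clusters(
    call_clusters(fake_track("1", c(1e5, 2e5), c(1, 2),
                             top01 = c(FALSE, FALSE),
                             top001 = c(FALSE, FALSE))))), tempfile())
  expect_equal(length(readLines(paths0["bed"])), 1L)
  expect_equal(nrow(read.delim(paths0["tsv"])), 0L)
})

test_that("gene annotation readers accept BED and GFF3", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("1\t999\t2000\tGENEA", "2\t5000\t7000\tGENEB"), bed)
  g <- read_genes(bed)
  expect_equal(g$start_bp, c(1000L, 5001L))    # BED is 0-based half-open
  expect_equal(g$stop_bp, c(2000L, 7000L))
  expect_equal(g$name, c("GENEA", "GENEB"))
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    paste("1", "src", "gene", "1000", "2000", ".", "+", ".",
          "ID=g1;Name=GENEA;biotype=protein_coding", sep = "\t"),
    paste("1", "src", "gene", "3000", "4000", ".", "+", ".",
          "ID=g2;Name=PSEUDO;biotype=pseudogene", sep = "\t"),
    paste("1", "src", "exon", "1000", "1100", ".", "+", ".",
          "ID=e1", sep = "\t")), gff)
  g2 <- read_genes(gff)
  expect_equal(g2$name, "GENEA")               # protein-coding genes only
  expect_equal(g2$start_bp, 1000L)
})
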