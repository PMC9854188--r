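#' Call cluster regions of significant SNPs
#'
#' Top-1% SNPs on each chromosome are grouped into runs in which consecutive
#' members are at most `gap_bp` apart. A run becomes a cluster region when
#' it contains at least one significant (top-0.1%) SNP and at least
#' `min_top1` top-1% SNPs. By default the significant SNPs count toward the
#' support of `min_top1` (they are themselves in the top 1%); set
#' `support_includes_significant = FALSE` for the stricter reading that
#' requires `min_top1` supporting SNPs in addition. Region bounds are the
#' outermost member-SNP positions.
#'
#' @param track a [css_track()].
#' @param gap_bp largest intra-run gap between consecutive top-1% SNPs;
#'   defaults to the track's smoothing window span.
#' @param min_top1 minimum top-1% SNPs per region (default 5).
#' @param support_includes_significant see Description.
#' @return A `data.frame` of regions: `chrom`, `start_bp`, `stop_bp`,
#'   `n_snps` (map SNPs inside the bounds), `n_top01`, `n_top1`,
#'   `peak_css`. Zero rows when nothing qualifies.
#' @export
call_clusters <- function(track, gap_bp = attr(track, "window_bp"),
                          min_top1 = 5L,
                          support_includes_significant = TRUE) {
  stopifnot(!is.null(track$top001), !is.null(track$top01))
  if (is.null(gap_bp)) stop("gap_bp missing and track has no window_bp")
  out <- empty_regions()
  for (ch in unique(track$chrom)) {
    on_ch <- track[track$chrom == ch, , drop = FALSE]
    cand <- on_ch[on_ch$top01, , drop = FALSE]
    if (!nrow(cand)) next
    run_id <- cumsum(c(1L, as.integer(diff(cand$pos) > gap_bp)))
    for (r in split(seq_len(nrow(cand)), run_id)) {
      members <- cand[r, , drop = FALSE]
      n_top01 <- sum(members$top001)
      n_top1 <- nrow(members)
      support <- if (support_includes_significant) n_top1
                 else n_top1 - n_top01
      if (n_top01 >= 1L && support >= min_top1) {
        start <- min(members$pos)
        stop_ <- max(members$pos)
        out <- rbind(out, data.frame(
          chrom = ch, start_bp = start, stop_bp = stop_,
          n_snps = sum(on_ch$pos >= start & on_ch$pos <= stop_),
          n_top01 = n_top01, n_top1 = n_top1,
          peak_css = max(members$smoothed_css),
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out[order(out$chrom, out$start_bp), , drop = FALSE]
}

empty_regions <- function() {
  data.frame(chrom = character(), start_bp = integer(), stop_bp = integer(),
             n_snps = integer(), n_top01 = integer(), n_top1 = integer(),
             peak_css = numeric(), stringsAsFactors = FALSE)
}

#' Merge nearby cluster regions
#'
#' Same-chromosome regions whose gap (`next start - previous stop`) is
#' strictly below `merge_bp` are merged transitively into one region; SNP
#' counts are summed and the peak CSS is the maximum. Regions spaced exactly
#' `merge_bp` apart are kept separate.
#'
#' @param regions a region `data.frame` from [call_clusters()].
#' @param merge_bp merge distance in bp (default 1 Mb).
#' @return Merged region `data.frame`, sorted by (chrom, start).
#' @export
merge_clusters <- function(regions, merge_bp = 1000000) {
  if (!nrow(regions)) return(regions)
  regions <- regions[order(regions$chrom, regions$start_bp), , drop = FALSE]
  out <- regions[0, , drop = FALSE]
  cur <- regions[1, , drop = FALSE]
  for (i in seq_len(nrow(regions))[-1]) {
    nxt <- regions[i, , drop = FALSE]
    if (nxt$chrom == cur$chrom &&
        (nxt$start_bp - cur$stop_bp) < merge_bp) {
      cur$stop_bp <- max(cur$stop_bp, nxt$stop_bp)
      cur$n_snps <- cur$n_snps + nxt$n_snps
      cur$n_top01 <- cur$n_top01 + nxt$n_top01
      cur$n_top1 <- cur$n_top1 + nxt$n_top1
      cur$peak_css <- max(cur$peak_css, nxt$peak_css)
    } else {
      out <- rbind(out, cur)
      cur <- nxt
    }
  }
  out <- rbind(out, cur)
  rownames(out) <- NULL
  out
}

#' Rank regions by peak CSS
#'
#' Rank 1 is the region with the highest peak smoothed CSS; ties are broken
#' by (chrom, start). The result is sorted by rank.
#'
#' @param regions a region `data.frame` with `peak_css` set.
#' @return The regions with a `rank` column, sorted by rank.
#' @export
rank_regions <- function(regions) {
  if (!nrow(regions)) {
    regions$rank <- integer()
    return(regions)
  }
  ord <- order(-regions$peak_css, regions$chrom, regions$start_bp)
  regions <- regions[ord, , drop = FALSE]
  regions$rank <- seq_len(nrow(regions))
  rownames(regions) <- NULL
  regions
}

#' Attach flanking intervals to regions
#'
#' @param regions a region `data.frame`.
#' @param flank_bp flank width each side (default 0.5 Mb); flank starts are
#'   floored at 1.
#' @return Regions with `flank_start`, `flank_stop` columns.
#' @export
attach_flanks <- function(regions, flank_bp = 500000) {
  regions$flank_start <- pmax(1L, regions$start_bp - as.integer(flank_bp))
  regions$flank_stop <- regions$stop_bp + as.integer(flank_bp)
  regions
}

#' Read gene annotation from BED or GFF3
#'
#' Uses rtracklayer to parse the file; for GFF3 only `gene` features are
#' kept and, when a biotype attribute is present, only protein-coding
#' genes. Coordinates are returned 1-based closed.
#'
#' @param path annotation file (.bed, .gff3/.gff).
#' @return A `data.frame` with columns `chrom`, `start_bp`, `stop_bp`,
#'   `name`, `biotype`.
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  is_gff <- grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)
  if (is_gff && "type" %in% names(df)) df <- df[df$type == "gene", ,
                                                drop = FALSE]
  bt_col <- intersect(c("biotype", "gene_biotype", "gene_type"), names(df))
  biotype <- if (length(bt_col)) as.character(df[[bt_col[1]]])
             else rep(NA_character_, nrow(df))
  if (is_gff && any(!is.na(biotype)))
    keep <- is.na(biotype) | biotype == "protein_coding"
  else keep <- rep(TRUE, nrow(df))
  name_col <- intersect(c("Name", "name", "gene_name", "ID"), names(df))
  nm <- if (length(name_col)) as.character(df[[name_col[1]]])
        else paste0("gene", seq_len(nrow(df)))
  out <- data.frame(chrom = as.character(df$seqnames),
                    start_bp = df$start, stop_bp = df$end,
                    name = nm, biotype = biotype,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map genes onto cluster regions and their flanks
#'
#' A gene is "in-peak" when its interval shares at least one bp with the
#' region's [start, stop] (closed intervals), and "in-flank" when it
#' overlaps the flank extension but not the peak.
#'
#' @param regions ranked regions (flanks are computed from `flank_bp` if
#'   absent).
#' @param genes gene `data.frame` as from [read_genes()].
#' @param flank_bp flank width each side (default 0.5 Mb).
#' @return `regions` with list-columns `genes_peak`, `genes_flank` and
#'   count columns `n_genes_peak`, `n_genes_flank`.
#' @export
map_genes <- function(regions, genes, flank_bp = 500000) {
  if (!all(c("flank_start", "flank_stop") %in% names(regions)))
    regions <- attach_flanks(regions, flank_bp)
  if (nrow(regions) &&
      !any(unique(regions$chrom) %in% unique(genes$chrom)))
    stop("namespace error: no shared chromosome labels between regions (",
         paste(utils::head(unique(regions$chrom), 3), collapse = ","),
         ") and annotation (",
         paste(utils::head(unique(genes$chrom), 3), collapse = ","), ")")
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start_bp, genes$stop_bp))
  overlap_names <- function(chrom, lo, hi) {
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(lo, hi))
    hits <- GenomicRanges::findOverlaps(q, gr_genes)
    genes$name[S4Vectors::subjectHits(hits)]
  }
  peak <- vector("list", nrow(regions))
  flank <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    in_peak <- overlap_names(regions$chrom[i], regions$start_bp[i],
                             regions$stop_bp[i])
    in_ext <- overlap_names(regions$chrom[i], regions$flank_start[i],
                            regions$flank_stop[i])
    peak[[i]] <- in_peak
    flank[[i]] <- setdiff(in_ext, in_peak)
  }
  regions$genes_peak <- peak
  regions$genes_flank <- flank
  regions$n_genes_peak <- lengths(peak)
  regions$n_genes_flank <- lengths(flank)
  regions
}

#' Write the region report and BED intervals
#'
#' Emits a tab-separated report (one row per region: coordinates, SNP
#' counts, peak CSS, rank, gene lists) and a BED file with two lines per
#' region (peak and flank intervals). Internal coordinates are 1-based
#' closed; BED output is 0-based half-open.
#'
#' @param regions ranked (and optionally gene-annotated) regions.
#' @param out_prefix path prefix; writes `<prefix>_regions.tsv` and
#'   `<prefix>_regions.bed`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_report <- function(regions, out_prefix) {
  tsv <- paste0(out_prefix, "_regions.tsv")
  bed <- paste0(out_prefix, "_regions.bed")
  flat <- regions
  for (col in c("genes_peak", "genes_flank"))
    if (col %in% names(flat))
      flat[[col]] <- vapply(flat[[col]], paste, "", collapse = ",")
  utils::write.table(flat, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bed_lines <- character()
  for (i in seq_len(nrow(regions))) {
    nm <- paste0("region", if ("rank" %in% names(regions))
      regions$rank[i] else i)
    bed_lines <- c(bed_lines,
      paste(regions$chrom[i], regions$start_bp[i] - 1L, regions$stop_bp[i],
            paste0(nm, "_peak"), sep = "\t"))
    if (all(c("flank_start", "flank_stop") %in% names(regions)))
      bed_lines <- c(bed_lines,
        paste(regions$chrom[i], regions$flank_start[i] - 1L,
              regions$flank_stop[i], paste0(nm, "_flank"), sep = "\t"))
  }
  writeLines(c("#chrom\tstart\tend\tname", bed_lines), bed)
  invisible(c(tsv = tsv, bed = bed))
}
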