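#' Aggregate decoded fragments into a per-CpG methylation track
#'
#' Counts each fragment's Viterbi call once per reference CpG site and
#' computes the continuous methylation level `n_methylated / n_total` at
#' every covered site.
#'
#' @param decoded a `decoded_fragments` object.
#' @return data.table (class `cpg_track`): chrom, pos, n_meth, n_total, level;
#'   sites with zero coverage are absent.
#' @export
aggregate_track <- function(decoded) {
  stopifnot(inherits(decoded, "decoded_fragments"))
  if (nrow(decoded$obs) == 0) {
    tr <- data.table(chrom = character(), pos = integer(),
                     n_meth = integer(), n_total = integer(), level = numeric())
  } else {
    tr <- decoded$obs[, .(n_meth = sum(state == "M"), n_total = .N),
                      by = .(chrom, pos)]
    tr[, level := n_meth / n_total]
    setorder(tr, chrom, pos)
  }
  setattr(tr, "class", c("cpg_track", class(tr)))
  tr[]
}

#' Build a CpG track directly from per-site truth probabilities
#'
#' Convenience for evaluation: converts a per-CpG methylome (probability of
#' methylation per site) or truth-state observations into the same track
#' shape as [aggregate_track()].
#'
#' @param x data.frame with chrom, pos and either `level` or counts
#'   n_meth/n_total.
#' @return a `cpg_track`.
#' @export
as_cpg_track <- function(x) {
  tr <- as.data.table(x)
  if (!"level" %in% names(tr)) tr[, level := n_meth / n_total]
  if (!"n_total" %in% names(tr)) tr[, n_total := 1L]
  if (!"n_meth" %in% names(tr)) tr[, n_meth := as.integer(round(level * n_total))]
  tr <- tr[, .(chrom, pos, n_meth, n_total, level)]
  setorder(tr, chrom, pos)
  setattr(tr, "class", c("cpg_track", class(tr)))
  tr[]
}

#' Write a track as bedGraph plus a count TSV
#'
#' The bedGraph holds (chrom, start, start+2, level) with the level rounded
#' to 4 decimals; the TSV carries exact counts.
#'
#' @param track a `cpg_track`.
#' @param bedgraph,tsv output paths (either may be `NULL` to skip).
#' @export
write_track <- function(track, bedgraph = NULL, tsv = NULL) {
  if (!is.null(bedgraph)) {
    bg <- track[, .(chrom, start = pos, end = pos + 2L,
                    level = round(level, 4))]
    fwrite(bg, bedgraph, sep = "\t", col.names = FALSE)
  }
  if (!is.null(tsv)) fwrite(track, tsv, sep = "\t")
  invisible(track)
}

#' Non-overlapping genome tiling
#'
#' @param seqlengths named vector of chromosome lengths.
#' @param width tile width in bp (default 1000).
#' @return data.table: chrom, start, end, window_id (0-based half-open).
#' @export
tile_windows <- function(seqlengths, width = 1000L) {
  out <- rbindlist(lapply(names(seqlengths), function(ch) {
    s <- seq(0L, as.integer(seqlengths[[ch]]) - 1L, by = width)
    data.table(chrom = ch, start = s,
               end = pmin(s + width, as.integer(seqlengths[[ch]])))
  }))
  out[, window_id := paste0(chrom, ":", start, "-", end)]
  out[]
}

#' CpG-island shore windows
#'
#' Shores are the 2 kb flanks on each side of a CpG island, minus any
#' overlap with islands themselves.
#'
#' @param cgi data.table/data.frame of islands (chrom, start, end, 0-based
#'   half-open).
#' @param flank shore width in bp (default 2000).
#' @param seqlengths optional named lengths for clipping.
#' @return data.table of shore intervals.
#' @export
cgi_shores <- function(cgi, flank = 2000L, seqlengths = NULL) {
  cgi <- as.data.table(cgi)[, 1:3]
  setnames(cgi, c("chrom", "start", "end"))
  gr_cgi <- GenomicRanges::GRanges(cgi$chrom,
    IRanges::IRanges(cgi$start + 1L, cgi$end))
  fl <- GenomicRanges::reduce(c(
    GenomicRanges::flank(gr_cgi, flank, start = TRUE),
    GenomicRanges::flank(gr_cgi, flank, start = FALSE)))
  sh <- GenomicRanges::setdiff(fl, GenomicRanges::reduce(gr_cgi))
  out <- data.table(chrom = as.character(GenomicRanges::seqnames(sh)),
                    start = BiocGenerics::start(sh) - 1L,
                    end = BiocGenerics::end(sh))
  out <- out[start >= 0]
  if (!is.null(seqlengths))
    out[, end := pmin(end, as.integer(seqlengths[chrom]))]
  out[]
}

#' Summarize a CpG track over windows
#'
#' Pooled methylation density per window: sum of methylated calls over sum of
#' total calls across the CpGs inside each window; windows with no covered
#' CpG get `NA`.
#'
#' @param track a `cpg_track`.
#' @param windows data.table with chrom, start, end (and optionally
#'   window_id).
#' @return the windows with n_meth, n_total, density columns.
#' @export
window_summarize <- function(track, windows) {
  w <- as.data.table(windows)
  if (!"window_id" %in% names(w))
    w[, window_id := paste0(chrom, ":", start, "-", end)]
  tr <- as.data.table(track)[, .(chrom, pos, n_meth, n_total)]
  tr[, `:=`(start = pos, end = pos)]
  # half-open windows: the C position must satisfy start <= pos < end
  wi <- w[, .(chrom, start, end = end - 1L, window_id)]
  setkey(wi, chrom, start, end)
  ov <- foverlaps(tr, wi, by.x = c("chrom", "start", "end"), nomatch = NULL)
  agg <- ov[, .(n_meth = sum(n_meth), n_total = sum(n_total)), by = window_id]
  out <- merge(w, agg, by = "window_id", all.x = TRUE)
  out[is.na(n_meth), `:=`(n_meth = 0L, n_total = 0L)]
  out[, density := ifelse(n_total > 0, n_meth / n_total, NA_real_)]
  setorder(out, chrom, start)
  out[]
}

#' Mean methylation profile around oriented anchors
#'
#' Averages track levels in fixed-size offset bins around a set of stranded
#' reference points (e.g. CpG-island promoter TSSs); minus-strand anchors are
#' orientation-flipped so upstream/downstream are comparable.
#'
#' @param track a `cpg_track`.
#' @param anchors data.table with chrom, pos, strand ("+"/"-").
#' @param flank half-window in bp (default 2000).
#' @param bin bin width in bp (default 100).
#' @return data.table: bin_start (offset of bin left edge relative to the
#'   anchor), mean_level, n_sites.
#' @export
anchor_profile <- function(track, anchors, flank = 2000L, bin = 100L) {
  stopifnot(flank > 0, bin > 0)
  an <- as.data.table(anchors)
  if (!"strand" %in% names(an)) an[, strand := "+"]
  tr <- as.data.table(track)[, .(chrom, pos, level)]
  an[, `:=`(start = pos - flank, end = pos + flank)]
  tr[, `:=`(start = pos, end = pos)]
  setkey(an, chrom, start, end)
  ov <- foverlaps(tr, an[, .(chrom, start, end, apos = pos, strand)],
                  by.x = c("chrom", "start", "end"), nomatch = NULL)
  if (nrow(ov) == 0)
    return(data.table(bin_start = integer(), mean_level = numeric(),
                      n_sites = integer()))
  ov[, offset := ifelse(strand == "-", apos - pos, pos - apos)]
  ov <- ov[offset >= -flank & offset < flank]
  ov[, bin := (floor((offset + flank) / bin)) * bin - flank]
  out <- ov[, .(mean_level = mean(level), n_sites = .N), by = .(bin_start = bin)]
  setorder(out, bin_start)
  out[]
}
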