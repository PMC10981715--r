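#' Fragment-level quality filters
#'
#' Container for the preprocessing thresholds applied to cfDNA read pairs:
#' fragment length bounds, the per-position coverage cap, mapping and base
#' quality minima, pairing/duplicate requirements, exclusion-list intervals,
#' and the z-score cap applied to the coverage feature.
#'
#' @param min_len,max_len fragment length bounds in bp (inclusive).
#' @param max_region_coverage per-position coverage cap (x); a fragment
#'   overlapping any position above the cap is dropped.
#' @param min_mapq minimum mapping quality required of both mates.
#' @param min_baseq minimum base quality (carried for completeness; synthetic
#'   and pre-called inputs have no per-base qualities to filter on).
#' @param require_proper_pair,require_unique,drop_duplicates booleans.
#'   "Unique" is operationalized as MAPQ >= `min_mapq` and absence of
#'   secondary/supplementary flags.
#' @param blacklist `NULL`, a BED file path, or a data.frame/data.table with
#'   columns chrom, start, end (0-based half-open) of excluded intervals.
#' @param autosomes_only drop chrX/chrY/chrM-style sequence names.
#' @param cov_outlier z-score cap on the normalized-coverage feature.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(min_len = 30L, max_len = 500L,
                          max_region_coverage = 250, min_mapq = 30L,
                          min_baseq = 5L, require_proper_pair = TRUE,
                          require_unique = TRUE, drop_duplicates = TRUE,
                          blacklist = NULL, autosomes_only = TRUE,
                          cov_outlier = 3) {
  stopifnot(min_len < max_len, min_len >= 0, max_region_coverage > 0,
            min_mapq >= 0, cov_outlier > 0)
  if (is.character(blacklist)) blacklist <- read_bed3(blacklist)
  if (!is.null(blacklist)) {
    blacklist <- as.data.table(blacklist)[, 1:3]
    setnames(blacklist, c("chrom", "start", "end"))
  }
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 max_region_coverage = max_region_coverage,
                 min_mapq = as.integer(min_mapq), min_baseq = as.integer(min_baseq),
                 require_proper_pair = require_proper_pair,
                 require_unique = require_unique, drop_duplicates = drop_duplicates,
                 blacklist = blacklist, autosomes_only = autosomes_only,
                 cov_outlier = cov_outlier),
            class = "filter_config")
}

read_bed3 <- function(path) {
  bed <- fread(path, header = FALSE, select = 1:3,
               col.names = c("chrom", "start", "end"))
  bed
}

is_autosome <- function(chrom) {
  !grepl("(chr)?(X|Y|M|MT)$", chrom, ignore.case = TRUE)
}

#' Extract filtered cfDNA fragments and their fragmentation features
#'
#' Reads proper read pairs from a coordinate-sorted, indexed BAM, applies the
#' quality filters, locates reference CpG sites on each fragment, and computes
#' the three raw fragmentation features per CpG observation: fragment length
#' (bp), normalized coverage (fragments overlapping the site per million
#' high-quality fragments), and the absolute distance of the CpG to the
#' fragment center (bp).
#'
#' Filtering order: pairing/duplicate/MAPQ flags and length bounds, then
#' autosome restriction, then exclusion-list overlap, then the per-position
#' coverage cap (evaluated on the coverage of the fragments surviving the
#' earlier filters: a fragment is dropped if any position it overlaps exceeds
#' the cap). Fragments containing zero CpGs are dropped last; the
#' fragments-per-million denominator counts all fragments surviving the
#' quality filters regardless of CpG content.
#'
#' @param bam path to a coordinate-sorted BAM with index.
#' @param index a [build_cpg_index()] result for the matching reference.
#' @param cfg a [filter_config()].
#' @param sample_id sample label stored on the fragments.
#' @return object of class `fragment_set`: list with
#'   \describe{
#'     \item{fragments}{data.table: frag_id, chrom, start, end, length, n_cpg}
#'     \item{obs}{data.table: frag_id, chrom, pos, offset, dist_prev,
#'       len_raw, cov_raw, d2c_raw (and later len_z, cov_z, d2c_z, truth)}
#'     \item{stats}{`NULL` until [zscore_features()] is applied}
#'     \item{sample_id, n_hq_fragments}{bookkeeping}
#'   }
#' @export
extract_fragments <- function(bam, index, cfg = filter_config(),
                              sample_id = basename(bam)) {
  stopifnot(inherits(index, "cpg_index"), inherits(cfg, "filter_config"))
  if (!file.exists(bam)) stop("BAM not found: ", bam)
  bai <- paste0(bam, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM must be coordinate-sorted and indexed (missing .bai): ", bam)

  flags <- Rsamtools::scanBamFlag(
    isPaired = TRUE,
    isProperPair = if (cfg$require_proper_pair) TRUE else NA,
    isDuplicate = if (cfg$drop_duplicates) FALSE else NA,
    isSecondaryAlignment = if (cfg$require_unique) FALSE else NA,
    isSupplementaryAlignment = if (cfg$require_unique) FALSE else NA,
    isUnmappedQuery = FALSE, hasUnmappedMate = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags, what = "mapq")
  pairs <- GenomicAlignments::readGAlignmentPairs(bam, param = param)
  if (length(pairs) == 0 && length(GenomicAlignments::readGAlignments(bam)) > 0 &&
      !any(S4Vectors::mcols(GenomicAlignments::readGAlignments(
        bam, param = Rsamtools::ScanBamParam(
          flag = Rsamtools::scanBamFlag(isPaired = TRUE))))$flag))
    stop("single-end data: paired-end BAM required")

  mq1 <- S4Vectors::mcols(GenomicAlignments::first(pairs))$mapq
  mq2 <- S4Vectors::mcols(GenomicAlignments::second(pairs))$mapq
  gr <- GenomicRanges::granges(pairs, on.discordant.seqnames = "drop")
  ft <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,   # to 0-based half-open
                   end = BiocGenerics::end(gr),
                   mq1 = mq1, mq2 = mq2)
  ft[, length := end - start]
  keep <- ft$mq1 >= cfg$min_mapq & ft$mq2 >= cfg$min_mapq &
          ft$length >= cfg$min_len & ft$length <= cfg$max_len
  if (cfg$autosomes_only) keep <- keep & is_autosome(ft$chrom)
  ft <- ft[keep & !is.na(keep)]

  # exclusion list, then per-position coverage cap on surviving coverage
  frag_gr <- function(d) GenomicRanges::GRanges(
    d$chrom, IRanges::IRanges(start = d$start + 1L, end = d$end))
  if (!is.null(cfg$blacklist) && nrow(cfg$blacklist) > 0 && nrow(ft) > 0) {
    bl <- GenomicRanges::GRanges(cfg$blacklist$chrom,
      IRanges::IRanges(start = cfg$blacklist$start + 1L, end = cfg$blacklist$end))
    hit <- GenomicRanges::countOverlaps(frag_gr(ft), bl) > 0
    ft <- ft[!hit]
  }
  if (nrow(ft) > 0) {
    cvg <- GenomicRanges::coverage(frag_gr(ft))
    mx <- frag_max_coverage(ft, cvg)
    ft <- ft[mx <= cfg$max_region_coverage]
  }
  n_hq <- nrow(ft)
  if (n_hq == 0)
    return(empty_fragment_set(sample_id))

  # CpG observations per fragment; CpG must lie wholly inside the fragment
  setorder(ft, chrom, start, end)
  ft[, frag_id := .I]
  cvg <- GenomicRanges::coverage(frag_gr(ft))
  obs <- locate_cpgs(ft, index)
  if (nrow(obs) > 0) {
    obs[, cov_raw := coverage_at(cvg, chrom, pos) / n_hq * 1e6]
  }
  ft[, n_cpg := 0L]
  if (nrow(obs) > 0) {
    cnt <- obs[, .N, by = frag_id]
    ft[cnt, n_cpg := i.N, on = "frag_id"][is.na(n_cpg), n_cpg := 0L]
  }
  ft <- ft[n_cpg > 0L]
  obs <- obs[frag_id %in% ft$frag_id]
  new_fragment_set(ft, obs, sample_id, n_hq)
}

empty_fragment_set <- function(sample_id) {
  new_fragment_set(
    data.table(frag_id = integer(), chrom = character(), start = integer(),
               end = integer(), length = integer(), n_cpg = integer()),
    data.table(frag_id = integer(), chrom = character(), pos = integer(),
               offset = integer(), dist_prev = integer(), len_raw = numeric(),
               cov_raw = numeric(), d2c_raw = numeric()),
    sample_id, 0L)
}

new_fragment_set <- function(ft, obs, sample_id, n_hq) {
  structure(list(
    fragments = ft[, .(frag_id, chrom, start, end, length, n_cpg)],
    obs = obs, stats = NULL, sample_id = sample_id,
    n_hq_fragments = n_hq), class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set '%s': %d fragments with CpGs (%d high-quality), %d CpG observations%s\n",
              x$sample_id, nrow(x$fragments), x$n_hq_fragments, nrow(x$obs),
              if (is.null(x$stats)) " (raw features)" else " (z-scored)"))
  invisible(x)
}

# max fragment-coverage over each fragment span
frag_max_coverage <- function(ft, cvg) {
  mx <- numeric(nrow(ft))
  for (ch in unique(ft$chrom)) {
    i <- which(ft$chrom == ch)
    v <- IRanges::Views(cvg[[ch]],
                        IRanges::IRanges(start = ft$start[i] + 1L, end = ft$end[i]))
    mx[i] <- IRanges::viewMaxs(v)
  }
  mx
}

coverage_at <- function(cvg, chrom, pos0) {
  out <- numeric(length(pos0))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    out[i] <- as.numeric(cvg[[ch]][pos0[i] + 1L])
  }
  out
}

# all CpGs wholly inside [start, end): C at pos, G at pos+1 -> pos >= start,
# pos + 2 <= end
locate_cpgs <- function(ft, index) {
  res <- vector("list", length(unique(ft$chrom)))
  k <- 0L
  for (ch in unique(ft$chrom)) {
    p <- index$positions[[ch]]
    sub <- ft[chrom == ch]
    if (is.null(p) || length(p) == 0L || nrow(sub) == 0L) next
    lo <- findInterval(sub$start - 1L, p) + 1L          # first index with p >= start
    hi <- findInterval(sub$end - 2L, p)                 # last index with p <= end-2
    n_each <- pmax(hi - lo + 1L, 0L)
    if (sum(n_each) == 0L) next
    idx <- sequence(n_each) - 1L +
      rep(lo, n_each)
    k <- k + 1L
    res[[k]] <- data.table(
      frag_id = rep(sub$frag_id, n_each),
      chrom = ch,
      pos = p[idx],
      f_start = rep(sub$start, n_each),
      f_end = rep(sub$end, n_each),
      len = rep(sub$length, n_each))
  }
  if (k == 0L)
    return(data.table(frag_id = integer(), chrom = character(), pos = integer(),
                      offset = integer(), dist_prev = integer(),
                      len_raw = numeric(), cov_raw = numeric(), d2c_raw = numeric()))
  obs <- rbindlist(res[seq_len(k)])
  setorder(obs, frag_id, pos)
  obs[, offset := pos - f_start]
  obs[, dist_prev := c(NA_integer_, diff(pos)), by = frag_id]
  obs[, len_raw := as.numeric(len)]
  obs[, d2c_raw := abs(pos - (f_start + f_end) / 2)]
  obs[, c("f_start", "f_end", "len") := NULL]
  obs[, cov_raw := NA_real_]
  obs[]
}

#' z-score the fragmentation features within a sample
#'
#' Transforms each raw feature to a z-score using the mean and standard
#' deviation over all surviving observations of the same sample; the coverage
#' z-score is additionally clipped to `[-cov_outlier, +cov_outlier]`. Raw
#' values are retained. Standard deviations are floored at 1e-6 (raw scale) to
#' avoid division by zero on degenerate inputs, with a warning.
#'
#' @param frags a `fragment_set` from [extract_fragments()].
#' @param stats optional precomputed stats (as stored in `frags$stats` or a
#'   serialized model) to apply to a new sample; default computes them from
#'   `frags` itself.
#' @param cov_outlier z-score cap for the coverage feature (default 3).
#' @return the `fragment_set` with `len_z`, `cov_z`, `d2c_z` columns and
#'   `stats` filled in.
#' @export
zscore_features <- function(frags, stats = NULL, cov_outlier = 3) {
  stopifnot(inherits(frags, "fragment_set"))
  obs <- frags$obs
  if (nrow(obs) == 0) { frags$stats <- stats; return(frags) }
  raw <- c("len_raw", "cov_raw", "d2c_raw")
  if (is.null(stats)) {
    mu <- vapply(raw, function(c) mean(obs[[c]]), 0)
    sdv <- vapply(raw, function(c) sd(obs[[c]]), 0)
    if (any(is.na(sdv) | sdv < 1e-6)) {
      warning("zero-variance feature(s): standard deviation floored at 1e-6")
      sdv[is.na(sdv) | sdv < 1e-6] <- 1e-6
    }
    stats <- list(total_high_quality_fragments = frags$n_hq_fragments,
                  mean = mu, sd = sdv, cov_outlier = cov_outlier)
  }
  mu <- unlist(stats$mean)[raw]; sdv <- unlist(stats$sd)[raw]
  obs[, len_z := (len_raw - mu[["len_raw"]]) / sdv[["len_raw"]]]
  obs[, cov_z := pmin(pmax((cov_raw - mu[["cov_raw"]]) / sdv[["cov_raw"]],
                           -cov_outlier), cov_outlier)]
  obs[, d2c_z := (d2c_raw - mu[["d2c_raw"]]) / sdv[["d2c_raw"]]]
  frags$obs <- obs
  frags$stats <- stats
  frags
}

#' Attach fragment-level ground-truth methylation states
#'
#' Accepts pre-called per-fragment CpG states (e.g. from bisulfite data or the
#' simulator) and matches them to the extracted observations. Two layouts are
#' supported: compact (chrom, start, end, states string over U/M/`.` — one
#' character per CpG in fragment order) and long (chrom, start, end, pos,
#' state). Observations without a matching record, and `.` characters, become
#' missing.
#'
#' @param frags a `fragment_set`.
#' @param truth a TSV path or data.frame in either layout.
#' @return the `fragment_set` with a `truth` column on `obs` (values "U", "M",
#'   or `NA`).
#' @export
attach_truth <- function(frags, truth) {
  stopifnot(inherits(frags, "fragment_set"))
  tt <- if (is.character(truth)) fread(truth) else as.data.table(truth)
  obs <- frags$obs
  obs[, truth := NA_character_]
  if (nrow(tt) == 0 || nrow(obs) == 0) { frags$obs <- obs; return(frags) }
  long <- "pos" %in% names(tt) && "state" %in% names(tt)
  fr <- frags$fragments
  if (long) {
    need <- c("chrom", "start", "end", "pos", "state")
    if (!all(need %in% names(tt)))
      stop("long-format truth needs columns: ", paste(need, collapse = ", "))
    key <- merge(obs[, .(frag_id, chrom, pos)],
                 fr[, .(frag_id, chrom, start, end)], by = c("frag_id", "chrom"))
    m <- merge(key, tt[, ..need], by = c("chrom", "start", "end", "pos"),
               all.x = TRUE)
    m[!state %in% c("U", "M"), state := NA_character_]
    obs[m, truth := i.state, on = c("frag_id", "pos")]
  } else {
    setnames(tt, 1:4, c("chrom", "start", "end", "states"))
    # distinct fragments can share coordinates; truth is matched by
    # coordinates, so keep one record per locus
    tt <- unique(tt, by = c("chrom", "start", "end"))
    m <- merge(fr, tt, by = c("chrom", "start", "end"), all.x = TRUE,
               all.y = FALSE)
    unmatched <- nrow(tt[!fr, on = c("chrom", "start", "end")])
    if (unmatched > 0)
      warning(sprintf("%d truth record(s) have no matching fragment; ignored",
                      unmatched))
    bad <- m[!is.na(states) & nchar(states) != n_cpg]
    if (nrow(bad) > 0) {
      warning(sprintf("%d truth record(s) with CpG-count mismatch; states set to missing",
                      nrow(bad)))
      m[nchar(states) != n_cpg, states := NA_character_]
    }
    m <- m[!is.na(states)]
    if (nrow(m) > 0) {
      ch <- m[, .(truth_chr = strsplit(states, "")[[1]],
                  idx = seq_len(n_cpg)), by = frag_id]
      obs[, idx := seq_len(.N), by = frag_id]
      ch[!truth_chr %in% c("U", "M"), truth_chr := NA_character_]
      obs[ch, truth := i.truth_chr, on = c("frag_id", "idx")]
      obs[, idx := NULL]
    }
  }
  frags$obs <- obs
  frags
}

#' Export a fragment set as a TSV for inspection
#'
#' @param frags a `fragment_set`.
#' @param path output TSV.
#' @export
write_fragment_tsv <- function(frags, path) {
  tab <- merge(frags$obs, frags$fragments[, .(frag_id, start, end, n_cpg)],
               by = "frag_id")
  fwrite(tab, path, sep = "\t")
  invisible(path)
}
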