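# trapezoidal ROC from scores and 0/1 labels; ties handled by grouping
roc_points <- function(score, label) {
  o <- order(score, decreasing = TRUE)
  s <- score[o]; y <- label[o]
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / sum(y))
  fpr <- c(0, fp[last] / sum(1 - y))
  data.table(fpr = fpr, tpr = tpr)
}

trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

#' Per-CpG binary classification performance against ground truth
#'
#' Compares per-CpG posterior methylation probabilities with fragment-level
#' ground-truth states. Restricted to fragments carrying at least
#' `min_cpgs_per_fragment` CpGs; the two truth classes are balanced by random
#' downsampling before the threshold sweep, and the ROC/auROC is computed
#' over the per-CpG posterior `Pr(M)`.
#'
#' @param decoded a `decoded_fragments` with `truth` on the observations.
#' @param min_cpgs_per_fragment minimum CpGs per fragment (1, 3, or 5 in the
#'   standard evaluation).
#' @param seed RNG seed for the balanced downsampling.
#' @return list of class `evaluation_report`: `auroc`, `roc` (data.table of
#'   fpr/tpr), `n_compared`, `min_cpgs`.
#' @export
evaluate_binary <- function(decoded, min_cpgs_per_fragment = 5L, seed = 1L) {
  stopifnot(inherits(decoded, "decoded_fragments"))
  obs <- decoded$obs
  if (!"truth" %in% names(obs)) stop("ground-truth states required")
  keep_ids <- decoded$fragments[n_cpg >= min_cpgs_per_fragment, frag_id]
  d <- obs[frag_id %in% keep_ids & truth %in% c("U", "M")]
  nm <- sum(d$truth == "M"); nu <- sum(d$truth == "U")
  if (nm == 0 || nu == 0) stop("one truth class is empty; cannot balance")
  n <- min(nm, nu)
  set.seed(seed)
  im <- sample(which(d$truth == "M"), n)
  iu <- sample(which(d$truth == "U"), n)
  d <- d[sort(c(im, iu))]
  roc <- roc_points(d$post_m, as.integer(d$truth == "M"))
  structure(list(auroc = trapezoid_auc(roc), roc = roc,
                 n_compared = nrow(d), min_cpgs = min_cpgs_per_fragment),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("per-CpG evaluation (fragments with >= %d CpGs): auROC = %.4f over %d balanced CpGs\n",
              x$min_cpgs, x$auroc, x$n_compared))
  invisible(x)
}

#' Continuous-level agreement between two CpG tracks
#'
#' Pearson and Spearman correlation of methylation levels at single CpGs
#' present in both tracks, stratified by minimum coverage (required in both
#' tracks), optionally restricted to regions; plus window-level correlation
#' on a non-overlapping tiling.
#'
#' @param predicted,truth `cpg_track` objects on the same coordinates.
#' @param regions optional data.table (chrom, start, end) restricting the
#'   site-level comparison.
#' @param min_coverage integer vector of coverage strata (default
#'   `c(1, 3, 5, 10)`).
#' @param seqlengths named lengths used for the window tiling; default spans
#'   the covered territory.
#' @param window_width tiling width (default 1000).
#' @return data.table: one row per stratum plus one `windows` row, with
#'   pearson, spearman, n. Strata with fewer than 3 comparable sites report
#'   `NA`.
#' @export
correlate_tracks <- function(predicted, truth, regions = NULL,
                             min_coverage = c(1L, 3L, 5L, 10L),
                             seqlengths = NULL, window_width = 1000L) {
  p <- as.data.table(predicted); t <- as.data.table(truth)
  m <- merge(p, t, by = c("chrom", "pos"), suffixes = c(".x", ".y"))
  if (!is.null(regions)) {
    rg <- as.data.table(regions)[, 1:3]
    setnames(rg, c("chrom", "start", "end"))
    m[, `:=`(start = pos, end = pos)]
    rg <- rg[, .(chrom, start, end = end - 1L)]
    setkey(rg, chrom, start, end)
    m <- foverlaps(m, rg, by.x = c("chrom", "start", "end"), nomatch = NULL)
  }
  row_for <- function(x, y, label, n_min = 3L) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < n_min || sd(x) == 0 || sd(y) == 0)
      return(data.table(stratum = label, pearson = NA_real_,
                        spearman = NA_real_, n = length(x)))
    data.table(stratum = label, pearson = cor(x, y),
               spearman = cor(x, y, method = "spearman"), n = length(x))
  }
  out <- rbindlist(lapply(min_coverage, function(cv) {
    s <- m[n_total.x >= cv & n_total.y >= cv]
    row_for(s$level.x, s$level.y, sprintf("cpg_cov>=%d", cv))
  }))
  if (is.null(seqlengths)) {
    seqlengths <- p[, max(pos) + 2L, by = chrom]
    seqlengths <- setNames(seqlengths$V1, seqlengths$chrom)
  }
  w <- tile_windows(seqlengths, window_width)
  wp <- window_summarize(predicted, w)
  wt <- window_summarize(truth, w)
  wm <- merge(wp[!is.na(density), .(window_id, density)],
              wt[!is.na(density), .(window_id, density)], by = "window_id",
              suffixes = c(".x", ".y"))
  out <- rbind(out, row_for(wm$density.x, wm$density.y,
                            sprintf("windows_%dbp", window_width)))
  out[]
}
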