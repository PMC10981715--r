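#' Differentially methylated windows by rank-sum test (sparse-data mode)
#'
#' For sparse, noisy low-pass data, compares per-window methylation densities
#' between two groups of samples with a two-sided Wilcoxon rank-sum test and
#' flags windows below the p-value cut-off. P-values are exact for group
#' sizes up to 10 without ties, and use the normal approximation with
#' tie-corrected variance (no continuity correction) otherwise; windows
#' where every value is tied get p = 1.
#' Benjamini-Hochberg q-values are reported alongside for transparency, but
#' flagging follows the raw p cut-off.
#'
#' @param case,control numeric matrices (windows x samples) of window
#'   methylation densities, same rows; `NA` entries are dropped per test.
#' @param p_cutoff raw two-sided p-value cut-off (default 0.01).
#' @param min_per_group windows need at least this many non-missing values in
#'   each group (default 2); others are skipped.
#' @return data.table: window (rownames or index), p_value, q_value,
#'   direction ("hyper" = case median higher, "hypo" lower, "none"), flagged.
#' @export
wilcoxon_dmr <- function(case, control, p_cutoff = 0.01, min_per_group = 2L) {
  case <- as.matrix(case); control <- as.matrix(control)
  stopifnot(nrow(case) == nrow(control))
  ids <- if (!is.null(rownames(case))) rownames(case) else
    as.character(seq_len(nrow(case)))
  res <- lapply(seq_len(nrow(case)), function(i) {
    x <- case[i, ]; y <- control[i, ]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < min_per_group || length(y) < min_per_group)
      return(data.table(window = ids[i], p_value = NA_real_,
                        direction = NA_character_))
    if (length(unique(c(x, y))) == 1L)
      return(data.table(window = ids[i], p_value = 1,
                        direction = "none"))
    has_ties <- anyDuplicated(c(x, y)) > 0
    exact <- length(x) <= 10 && length(y) <= 10 && !has_ties
    p <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = exact,
                  correct = FALSE)$p.value)
    md <- median(x) - median(y)
    data.table(window = ids[i], p_value = p,
               direction = if (md > 0) "hyper" else if (md < 0) "hypo" else "none")
  })
  out <- rbindlist(res)
  out[, q_value := p.adjust(p_value, method = "BH")]
  out[, flagged := !is.na(p_value) & p_value < p_cutoff]
  out[]
}
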