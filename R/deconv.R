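#' Reference methylome panel
#'
#' Holds per-window methylation density and informative-call counts for a set
#' of reference cell types, on a shared window coordinate system (typically
#' 1 kb autosomal tiles intersecting CpG islands and shores).
#'
#' @param windows data.table/data.frame with chrom, start, end (0-based
#'   half-open) or a window_id column.
#' @param density numeric matrix (windows x cell types), entries in `[0,1]`
#'   or `NA`.
#' @param bases matrix of informative call counts (Cs + Ts in bisulfite
#'   terms; total fragment calls for predicted tracks), same shape.
#' @return object of class `methylome_panel`.
#' @export
methylome_panel <- function(windows, density, bases) {
  w <- as.data.table(windows)
  if (!"window_id" %in% names(w))
    w[, window_id := paste0(chrom, ":", start, "-", end)]
  density <- as.matrix(density); bases <- as.matrix(bases)
  stopifnot(nrow(density) == nrow(w), all(dim(density) == dim(bases)))
  if (is.null(colnames(density))) stop("cell types must be named")
  if (anyDuplicated(colnames(density))) stop("duplicate cell-type names")
  rng <- range(density, na.rm = TRUE)
  stopifnot(rng[1] >= 0, rng[2] <= 1)
  structure(list(windows = w, density = density, bases = bases,
                 cell_types = colnames(density)),
            class = "methylome_panel")
}

#' Read a panel TSV (window_id then <cell>.density / <cell>.bases columns)
#' @param path TSV written by [write_panel()].
#' @return a `methylome_panel`.
#' @export
read_panel <- function(path) {
  tt <- fread(path)
  dcol <- grep("\\.density$", names(tt), value = TRUE)
  bcol <- grep("\\.bases$", names(tt), value = TRUE)
  cts <- sub("\\.density$", "", dcol)
  stopifnot(identical(cts, sub("\\.bases$", "", bcol)))
  d <- as.matrix(tt[, ..dcol]); b <- as.matrix(tt[, ..bcol])
  colnames(d) <- colnames(b) <- cts
  wid <- tt$window_id
  parts <- data.table(window_id = wid)
  parts[, chrom := sub(":.*", "", wid)]
  parts[, start := as.integer(sub(".*:(\\d+)-\\d+", "\\1", wid))]
  parts[, end := as.integer(sub(".*-", "", wid))]
  methylome_panel(parts, d, b)
}

#' @rdname read_panel
#' @param panel a `methylome_panel`.
#' @export
write_panel <- function(panel, path) {
  tt <- data.table(window_id = panel$windows$window_id)
  for (ct in panel$cell_types) {
    tt[[paste0(ct, ".density")]] <- panel$density[, ct]
    tt[[paste0(ct, ".bases")]] <- panel$bases[, ct]
  }
  fwrite(tt, path, sep = "\t")
  invisible(path)
}

sample_vectors <- function(sample_windows) {
  s <- as.data.table(sample_windows)
  if (!"window_id" %in% names(s))
    s[, window_id := paste0(chrom, ":", start, "-", end)]
  if (!"density" %in% names(s)) s[, density := n_meth / n_total]
  bases <- if ("bases" %in% names(s)) s$bases else s$n_total
  list(window_id = s$window_id, density = s$density, bases = bases)
}

binarize01 <- function(x, threshold = 0.1) {
  # strict less-than maps to 0, otherwise 1; NA stays NA
  ifelse(is.na(x), NA_real_, ifelse(x < threshold, 0, 1))
}

#' Prepare a deep-coverage deconvolution problem
#'
#' Windows are restricted to those with at least `min_bases` informative
#' calls in every reference methylome, ranked by across-cell-type variance of
#' (real-valued) density, the top `top_frac` retained, and both panel and
#' sample binarized at `bin_threshold` (density < threshold -> 0, else 1).
#'
#' @param panel a `methylome_panel`.
#' @param sample_windows the sample's window summary ([window_summarize()]
#'   output or a data.table with window_id, density, bases).
#' @param min_bases minimum informative calls per window per reference
#'   (default 10).
#' @param top_frac fraction of most-variable windows kept (default 0.01).
#' @param bin_threshold binarization threshold (default 0.1).
#' @param binarize set `FALSE` for a real-valued diagnostic mode.
#' @return list of class `deconvolution_problem`: `A` (windows x cell types),
#'   `b` (sample vector), `window_id`, `mode`.
#' @export
prepare_deep <- function(panel, sample_windows, min_bases = 10L,
                         top_frac = 0.01, bin_threshold = 0.1,
                         binarize = TRUE) {
  sv <- sample_vectors(sample_windows)
  idx <- match(panel$windows$window_id, sv$window_id)
  ok <- !is.na(idx) &
    rowSums(panel$bases >= min_bases) == ncol(panel$bases) &
    rowSums(is.na(panel$density)) == 0 &
    !is.na(sv$density[idx])
  if (sum(ok) < 10) stop("fewer than 10 usable windows after coverage filter")
  D <- panel$density[ok, , drop = FALSE]
  b <- sv$density[idx[ok]]
  wid <- panel$windows$window_id[ok]
  v <- apply(D, 1, var)
  n_keep <- max(ceiling(top_frac * length(v)), min(10L, length(v)))
  keep <- order(v, decreasing = TRUE)[seq_len(n_keep)]
  keep <- sort(keep)
  A <- D[keep, , drop = FALSE]; b <- b[keep]; wid <- wid[keep]
  if (binarize) { A <- binarize01(A, bin_threshold); b <- binarize01(b, bin_threshold) }
  structure(list(A = A, b = b, window_id = wid, mode = "deep"),
            class = "deconvolution_problem")
}

# k-nearest-neighbor imputation over windows (rows) of a windows x columns
# density matrix; distance = Euclidean over pairwise-complete columns, ties
# broken by row order.
knn_impute_rows <- function(M, k = 5L) {
  miss <- which(is.na(M), arr.ind = TRUE)
  if (nrow(miss) == 0) return(M)
  out <- M
  for (i in unique(miss[, 1])) {
    target <- M[i, ]
    cand <- setdiff(seq_len(nrow(M)), i)
    d <- vapply(cand, function(j) {
      shared <- !is.na(target) & !is.na(M[j, ])
      if (!any(shared)) return(Inf)
      sqrt(sum((target[shared] - M[j, shared])^2) / sum(shared) * length(target))
    }, 0)
    ord <- cand[order(d, cand)]
    for (jc in which(is.na(M[i, ]))) {
      donors <- ord[!is.na(M[ord, jc])]
      donors <- head(donors, k)
      if (length(donors) > 0) out[i, jc] <- mean(M[donors, jc])
    }
  }
  # any still-missing entry falls back to the column mean
  still <- which(is.na(out), arr.ind = TRUE)
  if (nrow(still) > 0) {
    cm <- colMeans(out, na.rm = TRUE)
    out[still] <- cm[still[, 2]]
  }
  out
}

#' Prepare an ultra-low-pass deconvolution problem
#'
#' Relaxed window preparation for sparse data: entries (reference or cfDNA)
#' with fewer than `min_bases` informative calls are marked `NA`; windows
#' with more than `max_na_frac` missing across the panel are dropped, and a
#' sample missing more than `max_na_frac` of the remaining windows is
#' rejected as insufficient coverage. The top `top_frac` most variable
#' windows are kept, remaining missing entries are imputed by k-nearest
#' neighbors over windows, and everything is binarized.
#'
#' @inheritParams prepare_deep
#' @param min_bases minimum informative calls per entry (default 5).
#' @param top_frac fraction of most-variable windows kept (default 0.25).
#' @param max_na_frac missingness tolerance (default 0.8, exclusive).
#' @param k neighbors for imputation (default 5).
#' @return a `deconvolution_problem` with `mode = "ulp"`.
#' @export
prepare_ulp <- function(panel, sample_windows, min_bases = 5L,
                        top_frac = 0.25, max_na_frac = 0.8, k = 5L,
                        bin_threshold = 0.1, binarize = TRUE) {
  sv <- sample_vectors(sample_windows)
  idx <- match(panel$windows$window_id, sv$window_id)
  D <- panel$density
  D[panel$bases < min_bases] <- NA_real_
  b <- sv$density[idx]
  bb <- sv$bases[idx]
  b[is.na(idx) | is.na(bb) | bb < min_bases] <- NA_real_
  # drop windows with >80% NA across the panel
  na_frac <- rowMeans(is.na(D))
  keep <- na_frac <= max_na_frac
  D <- D[keep, , drop = FALSE]; b <- b[keep]
  wid <- panel$windows$window_id[keep]
  if (mean(is.na(b)) > max_na_frac)
    stop("insufficient coverage: sample exceeds the missingness tolerance")
  v <- apply(D, 1, var, na.rm = TRUE)
  v[is.na(v)] <- -Inf
  n_keep <- max(ceiling(top_frac * length(v)), min(10L, length(v)))
  keep2 <- sort(order(v, decreasing = TRUE)[seq_len(n_keep)])
  D <- D[keep2, , drop = FALSE]; b <- b[keep2]; wid <- wid[keep2]
  M <- cbind(D, .sample = b)
  M <- knn_impute_rows(M, k = k)
  A <- M[, seq_len(ncol(D)), drop = FALSE]
  b <- M[, ncol(M)]
  if (binarize) { A <- binarize01(A, bin_threshold); b <- binarize01(b, bin_threshold) }
  structure(list(A = A, b = b, window_id = wid, mode = "ulp"),
            class = "deconvolution_problem")
}

#' Solve the constrained deconvolution
#'
#' Minimizes `||A w - b||^2` subject to `w >= 0` and `sum(w) = 1`, so the
#' weights are interpretable as tissue contributions to the cfDNA pool.
#' Solved as a quadratic program; a tiny ridge (1e-8) keeps the Gram matrix
#' positive definite for rank-deficient panels (e.g. duplicated cell types,
#' whose individual split is then non-identifiable but whose sum is).
#'
#' @param problem a `deconvolution_problem` (or any list with `A`, `b`).
#' @return list of class `deconvolution_result`: `weights` (named), `residual`
#'   (L2 norm of `A w - b`), `n_windows`.
#' @export
solve_qp <- function(problem) {
  A <- as.matrix(problem$A); b <- as.numeric(problem$b)
  stopifnot(nrow(A) == length(b))
  p <- ncol(A)
  if (nrow(A) < p)
    warning("fewer windows than cell types; weights may be unstable")
  G <- crossprod(A) + 1e-8 * diag(p)
  d <- as.vector(crossprod(A, b))
  Amat <- cbind(rep(1, p), diag(p))
  sol <- quadprog::solve.QP(G, d, Amat, c(1, rep(0, p)), meq = 1)
  w <- sol$solution
  w[w < 0] <- 0
  w <- w / sum(w)
  names(w) <- colnames(A)
  structure(list(weights = w, residual = sqrt(sum((A %*% w - b)^2)),
                 n_windows = nrow(A)),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("tissue-of-origin weights over %d windows (residual %.4f):\n",
              x$n_windows, x$residual))
  print(round(x$weights, 4))
  invisible(x)
}

#' One-call deconvolution
#'
#' @param panel a `methylome_panel`.
#' @param sample_windows sample window summary.
#' @param mode `"deep"` or `"ulp"`.
#' @param ... passed to [prepare_deep()] / [prepare_ulp()].
#' @return a `deconvolution_result`.
#' @export
deconvolve <- function(panel, sample_windows, mode = c("deep", "ulp"), ...) {
  mode <- match.arg(mode)
  prob <- if (mode == "deep") prepare_deep(panel, sample_windows, ...)
          else prepare_ulp(panel, sample_windows, ...)
  solve_qp(prob)
}
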