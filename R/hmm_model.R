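#' Non-homogeneous two-state HMM for cfDNA methylation
#'
#' Constructs the model object holding offset-binned initiation vectors,
#' distance-binned transition matrices, and per-state per-feature
#' two-component Gaussian mixture emissions over z-scored fragmentation
#' features. States are `"U"` (unmethylated) and `"M"` (methylated); the three
#' features are fragment length, normalized coverage, and distance of the CpG
#' to the fragment center.
#'
#' Transition probabilities depend on the genomic distance to the previous CpG
#' (binned by `dist_edges`); initiation probabilities depend on the offset of a
#' fragment's first CpG from the fragment start (binned by `offset_edges`),
#' reflecting that CpG spacing in the genome is highly non-uniform.
#'
#' @param dist_edges upper bin edges (bp) for the distance to the previous CpG;
#'   the last bin is open-ended. Default `c(10, 20, 50, 100, 200, 500, Inf)`.
#' @param offset_edges upper bin edges (bp) for the first-CpG offset from the
#'   fragment start. Default `c(25, 50, 75, 100, 150, Inf)`.
#' @param init matrix (offset bins x 2), rows summing to one. Defaults uniform.
#' @param trans array (distance bins x 2 x 2), each `trans[b, , ]` row-stochastic.
#'   Defaults uniform.
#' @param emis list of five (2 x 3) matrices `pi`, `mu1`, `mu2`, `var1`, `var2`:
#'   mixture weight of the second component, component means and variances, per
#'   state (rows, U then M) and feature (columns). Defaults to standard normal
#'   single components.
#' @return object of class `nhmm`.
#' @export
nhmm <- function(dist_edges = c(10, 20, 50, 100, 200, 500, Inf),
                 offset_edges = c(25, 50, 75, 100, 150, Inf),
                 init = NULL, trans = NULL, emis = NULL) {
  stopifnot(all(diff(dist_edges) > 0), all(diff(offset_edges) > 0))
  nb <- length(dist_edges)
  no <- length(offset_edges)
  if (is.null(init)) init <- matrix(0.5, no, 2)
  if (is.null(trans)) trans <- array(0.5, dim = c(nb, 2, 2))
  if (is.null(emis)) {
    z <- function(v) matrix(v, 2, 3)
    emis <- list(pi = z(0.5), mu1 = z(-0.5), mu2 = z(0.5),
                 var1 = z(1), var2 = z(1))
  }
  m <- structure(list(
    states = c("U", "M"),
    feature_names = c("fragment_length", "normalized_coverage", "distance_to_center"),
    dist_edges = dist_edges, offset_edges = offset_edges,
    init = init, trans = trans, emis = emis,
    trained_iterations = 0L, converged = FALSE, convergence_reason = NA_character_,
    loglik_trace = numeric(0), kl_trace = numeric(0)
  ), class = "nhmm")
  validate_nhmm(m)
  m
}

validate_nhmm <- function(m, tol = 1e-9) {
  stopifnot(inherits(m, "nhmm"), length(m$states) == 2L)
  if (any(abs(rowSums(m$init) - 1) > tol))
    stop("initiation vectors must sum to 1")
  rs <- apply(m$trans, c(1, 2), sum)
  if (any(abs(rs - 1) > tol))
    stop("transition rows must sum to 1")
  with(m$emis, stopifnot(all(pi >= 0 & pi <= 1), all(var1 > 0), all(var2 > 0)))
  invisible(m)
}

#' @export
print.nhmm <- function(x, ...) {
  cat("Non-homogeneous 2-state HMM (states U/M)\n")
  cat(sprintf("  %d distance bins, %d offset bins, features: %s\n",
              length(x$dist_edges), length(x$offset_edges),
              paste(x$feature_names, collapse = ", ")))
  cat(sprintf("  trained iterations: %d; converged: %s%s\n",
              x$trained_iterations, x$converged,
              if (is.na(x$convergence_reason)) "" else
                sprintf(" (%s)", x$convergence_reason)))
  invisible(x)
}

# map distances / offsets to 1-based bins; edges are upper-inclusive bounds
# (e.g. edges c(10, 20, Inf): x = 10 -> bin 1, x = 11 -> bin 2)
bin_of <- function(x, edges) {
  findInterval(x, c(-Inf, edges[-length(edges)]), left.open = TRUE)
}

#' Swap the U and M labels of a model
#'
#' Relabels every parameter block so that U becomes M and vice versa. Fragment
#' likelihoods are invariant under this relabeling.
#' @param m an `nhmm`.
#' @return the relabeled `nhmm`.
#' @export
swap_states <- function(m) {
  m$init <- m$init[, 2:1, drop = FALSE]
  m$trans <- m$trans[, 2:1, 2:1, drop = FALSE]
  m$emis <- lapply(m$emis, function(a) a[2:1, , drop = FALSE])
  m
}

#' Serialize a model to versioned JSON
#'
#' Writes every parameter (bin edges, initiation, transitions, mixtures) plus
#' the feature z-scoring statistics needed to apply the model to another
#' sample, as self-describing JSON with a format-version field. A model
#' trained on one high-coverage sample can thus be applied decode-only to
#' low-coverage samples.
#'
#' @param m an `nhmm`.
#' @param path output file.
#' @param stats optional `SampleFeatureStats`-style list stored alongside.
#' @export
write_nhmm <- function(m, path, stats = NULL) {
  validate_nhmm(m)
  obj <- list(
    format = "finaleme-nhmm", version = 1L,
    states = m$states, feature_names = m$feature_names,
    dist_edges = m$dist_edges, offset_edges = m$offset_edges,
    init = m$init, trans = as.vector(m$trans),
    trans_dim = dim(m$trans),
    emis = lapply(m$emis, identity),
    trained_iterations = m$trained_iterations, converged = m$converged,
    convergence_reason = m$convergence_reason,
    loglik_trace = m$loglik_trace, kl_trace = m$kl_trace,
    feature_stats = stats
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a model serialized by [write_nhmm()]
#' @param path JSON file written by [write_nhmm()].
#' @return list with elements `model` (an `nhmm`) and `stats` (or `NULL`).
#' @export
read_nhmm <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) NULL)
  if (!identical(obj$format, "finaleme-nhmm"))
    stop("not a finaleme model file: ", path)
  m <- nhmm(dist_edges = obj$dist_edges, offset_edges = obj$offset_edges,
            init = matrix(unlist(obj$init), ncol = 2),
            trans = array(obj$trans, dim = obj$trans_dim),
            emis = lapply(obj$emis, function(a) matrix(unlist(a), nrow = 2)))
  m$trained_iterations <- as.integer(obj$trained_iterations)
  m$converged <- isTRUE(obj$converged)
  m$convergence_reason <- obj$convergence_reason
  m$loglik_trace <- as.numeric(obj$loglik_trace)
  m$kl_trace <- as.numeric(obj$kl_trace)
  stats <- obj$feature_stats
  list(model = m, stats = stats)
}
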