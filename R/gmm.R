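# Two-component diagonal-covariance Gaussian mixture over the three z-scored
# fragmentation features, fit by EM. Used only to initialize the HMM.

fit_diag_gmm <- function(x, max_iter = 10000, tol = 1e-8, seed = 1L,
                         retries = 5L) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  if (nrow(unique(x)) < 2) stop("degenerate input: all observations identical")
  set.seed(seed)
  for (attempt in seq_len(retries)) {
    init <- x[sample.int(nrow(x), 2L), , drop = FALSE]
    mu <- init
    vr <- matrix(rep(pmax(apply(x, 2, var), 1e-2), each = 2), 2)
    w <- c(0.5, 0.5)
    ll_old <- -Inf
    ok <- TRUE
    for (it in seq_len(max_iter)) {
      lg <- sapply(1:2, function(k)
        log(w[k]) + rowSums(dnorm(x, rep(mu[k, ], each = nrow(x)),
                                  rep(sqrt(vr[k, ]), each = nrow(x)), log = TRUE)))
      m <- pmax(lg[, 1], lg[, 2])
      lse <- m + log(exp(lg[, 1] - m) + exp(lg[, 2] - m))
      r <- exp(lg - lse)           # responsibilities, n x 2
      nk <- colSums(r)
      if (any(nk < 1e-8)) { ok <- FALSE; break }
      w <- nk / nrow(x)
      for (k in 1:2) {
        mu[k, ] <- colSums(r[, k] * x) / nk[k]
        vr[k, ] <- pmax(colSums(r[, k] * sweep(x, 2, mu[k, ])^2) / nk[k], 1e-2)
      }
      ll <- sum(lse)
      if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
      ll_old <- ll
    }
    if (ok) {
      assign <- max.col(lg)
      if (length(unique(assign)) == 2L)
        return(list(weights = w, mu = mu, var = vr, assign = assign,
                    resp = r, loglik = ll_old, iterations = it))
      ok <- FALSE
    }
  }
  stop("GMM initialization degenerate: one component empty after ", retries,
       " restarts")
}

#' Initialize the HMM from a Gaussian-mixture hard clustering
#'
#' Fits a two-component diagonal-covariance Gaussian mixture to the z-scored
#' feature triples of every CpG observation (EM, up to `max_iter` iterations),
#' hard-assigns each observation to its most probable component, and builds
#' the initial HMM: initiation probabilities counted per first-CpG offset bin,
#' transition matrices counted per inter-CpG distance bin (pseudocount 1 on
#' all counts), and per-state per-feature two-component emission mixtures fit
#' to each component's observations.
#'
#' Components are anonymous (state 1/2) until [assign_state_labels()] names
#' them U/M.
#'
#' @param frags a z-scored `fragment_set`.
#' @param model skeleton `nhmm` carrying the bin edges (default [nhmm()]).
#' @param max_iter EM iteration cap (default 10000).
#' @param seed RNG seed for the EM starts.
#' @return list: `model` (initialized `nhmm`), `assign` (component index per
#'   observation, in `frags$obs` row order), `gmm` (the fitted mixture).
#' @export
gmm_initialize <- function(frags, model = nhmm(), max_iter = 10000, seed = 1L) {
  stopifnot(inherits(frags, "fragment_set"))
  obs <- frags$obs
  if (!"len_z" %in% names(obs)) stop("features must be z-scored first")
  x <- as.matrix(obs[, .(len_z, cov_z, d2c_z)])
  g <- fit_diag_gmm(x, max_iter = max_iter, seed = seed)
  model <- hmm_from_assignments(frags, g$assign, model)
  list(model = model, assign = g$assign, gmm = g)
}

# count-based parameter estimates given a hard state assignment (1/2 per obs)
hmm_from_assignments <- function(frags, assign, model) {
  obs <- frags$obs
  stopifnot(length(assign) == nrow(obs))
  no <- length(model$offset_edges); nb <- length(model$dist_edges)
  first <- obs[, .I[1], by = frag_id]$V1
  ob <- bin_of(obs$offset[first], model$offset_edges)
  init_counts <- matrix(1, no, 2)   # pseudocount
  for (s in 1:2) init_counts[, s] <- init_counts[, s] +
    tabulate(ob[assign[first] == s], nbins = no)
  model$init <- init_counts / rowSums(init_counts)

  nid <- obs$frag_id
  not_first <- which(!is.na(obs$dist_prev))
  db <- bin_of(obs$dist_prev[not_first], model$dist_edges)
  from <- assign[not_first - 1L]
  # guard: previous row belongs to same fragment by construction (dist_prev NA at first)
  to <- assign[not_first]
  trans_counts <- array(1, dim = c(nb, 2, 2))
  for (i in seq_along(not_first))
    trans_counts[db[i], from[i], to[i]] <- trans_counts[db[i], from[i], to[i]] + 1
  denom <- apply(trans_counts, c(1, 2), sum)
  for (s in 1:2) trans_counts[, , s] <- trans_counts[, , s] / denom
  model$trans <- trans_counts

  x <- as.matrix(obs[, .(len_z, cov_z, d2c_z)])
  em <- list(pi = matrix(0.5, 2, 3), mu1 = matrix(0, 2, 3), mu2 = matrix(0, 2, 3),
             var1 = matrix(1, 2, 3), var2 = matrix(1, 2, 3))
  for (s in 1:2) for (f in 1:3) {
    v <- x[assign == s, f]
    q <- quantile(v, c(0.2, 0.8), names = FALSE)
    vr <- max(var(v) / 2, 1e-2)
    pars <- list(pi = 0.5, mu1 = q[1], mu2 = q[2], var1 = vr, var2 = vr)
    # short weighted-EM refinement within the hard-assigned state
    for (i in 1:30) pars <- mix1d_update(v, rep(1, length(v)), pars)
    em$pi[s, f] <- pars$pi
    em$mu1[s, f] <- pars$mu1; em$mu2[s, f] <- pars$mu2
    em$var1[s, f] <- pars$var1; em$var2[s, f] <- pars$var2
  }
  model$emis <- em
  validate_nhmm(model)
  model
}

#' Name the mixture components U and M
#'
#' After [gmm_initialize()], decides which anonymous component is the
#' methylated state. In `"wgs"` mode the component with the larger mean
#' z-scored distance-to-center is labeled M (methylated DNA is
#' nucleosome-protected, so its CpGs sit farther from fragment ends'
#' cleavage-driven center). In `"wgbs"` mode the component with the larger
#' mean ground-truth methylation is labeled M. Exact ties fall back to the
#' mean fragment length (longer mean is M), with a message.
#'
#' @param init result of [gmm_initialize()].
#' @param frags the `fragment_set` used for initialization (must carry `truth`
#'   in wgbs mode).
#' @param mode `"wgs"` or `"wgbs"`.
#' @return the `nhmm` with state 1 = U and state 2 = M (parameters swapped if
#'   needed), plus attribute `m_component` (which anonymous component became M).
#' @export
assign_state_labels <- function(init, frags, mode = c("wgs", "wgbs")) {
  mode <- match.arg(mode)
  obs <- frags$obs
  assign <- init$assign
  crit <- if (mode == "wgs") {
    vapply(1:2, function(s) mean(obs$d2c_z[assign == s]), 0)
  } else {
    if (!"truth" %in% names(obs) || all(is.na(obs$truth)))
      stop("wgbs mode requires ground-truth states on the fragments")
    vapply(1:2, function(s) mean(obs$truth[assign == s] == "M", na.rm = TRUE), 0)
  }
  if (isTRUE(all.equal(crit[1], crit[2]))) {
    message("state-labeling tie; falling back to mean fragment length")
    crit <- vapply(1:2, function(s) mean(obs$len_z[assign == s]), 0)
    if (identical(crit[1], crit[2])) crit <- c(0, 1)  # deterministic last resort
  }
  m_comp <- which.max(crit)
  model <- init$model
  if (m_comp == 1L) model <- swap_states(model)
  attr(model, "m_component") <- m_comp
  model
}
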