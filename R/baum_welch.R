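# Build the concatenated-chain representation consumed by the C++ recursions:
# observations ordered by fragment, fragment start pointers, per-fragment
# offset bin and per-observation distance bin.
build_chain <- function(frags, model, frag_ids = NULL) {
  obs <- if (is.null(frag_ids)) copy(frags$obs) else
    frags$obs[frag_id %in% frag_ids]
  if (nrow(obs) == 0) stop("no observations to build chain from")
  setorder(obs, frag_id, pos)
  n_per <- obs[, .N, by = frag_id]
  frag_ptr <- c(0L, cumsum(n_per$N))
  first <- cumsum(c(1L, head(n_per$N, -1L)))
  off_bin <- bin_of(obs$offset[first], model$offset_edges)
  dist_bin <- rep(1L, nrow(obs))
  nf <- !is.na(obs$dist_prev)
  dist_bin[nf] <- bin_of(obs$dist_prev[nf], model$dist_edges)
  list(x = as.matrix(obs[, .(len_z, cov_z, d2c_z)]),
       frag_ptr = as.integer(frag_ptr), off_bin = as.integer(off_bin),
       dist_bin = as.integer(dist_bin), frag_id = n_per$frag_id,
       n_per = n_per$N, obs = obs)
}

chain_logemis <- function(chain, model) {
  nhmm_logemis(chain$x, model$emis$pi, model$emis$mu1, model$emis$mu2,
               model$emis$var1, model$emis$var2)
}

chain_estep <- function(chain, model, logemis = NULL) {
  if (is.null(logemis)) logemis <- chain_logemis(chain, model)
  nhmm_estep(logemis, chain$frag_ptr, chain$off_bin, chain$dist_bin,
             log(model$init), log(as.vector(model$trans)),
             length(model$dist_edges))
}

#' Per-fragment forward log-likelihood
#'
#' @param frags a z-scored `fragment_set`.
#' @param model a (trained or hand-set) `nhmm`.
#' @return data.table with frag_id, n_cpg, loglik.
#' @export
fragment_loglik <- function(frags, model) {
  chain <- build_chain(frags, model)
  e <- chain_estep(chain, model)
  data.table(frag_id = chain$frag_id, n_cpg = chain$n_per,
             loglik = as.numeric(e$ll_frag))
}

#' Sampled symmetrized Kullback-Leibler divergence between two models
#'
#' Computes the per-CpG-normalized mean log-likelihood difference over a
#' common sample of fragments, `D = |mean_f (logL_new(f) - logL_old(f)) /
#' n_cpg(f)|` (a sampled, symmetrized Juang-Rabiner approximation). `D` is
#' zero for identical models and non-negative by construction; it is the
#' convergence statistic of [baum_welch()].
#'
#' @param hmm_old,hmm_new two `nhmm` objects over the same bins/features.
#' @param frags a z-scored `fragment_set` holding the sampled fragments.
#' @param frag_ids optional fragment ids restricting the sample.
#' @return non-negative scalar.
#' @export
kl_divergence <- function(hmm_old, hmm_new, frags, frag_ids = NULL) {
  chain <- build_chain(frags, hmm_old, frag_ids = frag_ids)
  if (length(chain$frag_id) == 0) stop("empty KL sample")
  ll_old <- as.numeric(chain_estep(chain, hmm_old)$ll_frag)
  ll_new <- as.numeric(chain_estep(chain, hmm_new)$ll_frag)
  abs(mean((ll_new - ll_old) / chain$n_per))
}

# one weighted EM update of a 1-d two-component mixture; params is
# list(pi, mu1, mu2, var1, var2); w are observation weights
mix1d_update <- function(xi, w, params, var_floor = 1e-2) {
  p <- params$pi
  l1 <- if (p >= 1) rep(-Inf, length(xi)) else log(1 - p) +
    dnorm(xi, params$mu1, sqrt(params$var1), log = TRUE)
  l2 <- if (p <= 0) rep(-Inf, length(xi)) else log(p) +
    dnorm(xi, params$mu2, sqrt(params$var2), log = TRUE)
  m <- pmax(l1, l2)
  r2 <- exp(l2 - (m + log(exp(l1 - m) + exp(l2 - m))))
  sw <- sum(w)
  n2 <- sum(w * r2); n1 <- sw - n2
  if (n2 <= 1e-8 || n1 <= 1e-8) {
    params$pi <- min(max(n2 / sw, 1e-6), 1 - 1e-6)
    return(params)
  }
  mu2 <- sum(w * r2 * xi) / n2
  mu1 <- sum(w * (1 - r2) * xi) / n1
  list(pi = n2 / sw, mu1 = mu1, mu2 = mu2,
       var1 = max(sum(w * (1 - r2) * (xi - mu1)^2) / n1, var_floor),
       var2 = max(sum(w * r2 * (xi - mu2)^2) / n2, var_floor))
}

# responsibility-weighted EM updates of every state-feature mixture; a few
# inner iterations per M-step (generalized EM: the Q function still increases)
mstep_emissions <- function(model, x, gamma, inner = 3L) {
  em <- model$emis
  for (s in 1:2) {
    w <- gamma[, s]
    for (f in 1:3) {
      pars <- list(pi = em$pi[s, f], mu1 = em$mu1[s, f], mu2 = em$mu2[s, f],
                   var1 = em$var1[s, f], var2 = em$var2[s, f])
      for (i in seq_len(inner)) pars <- mix1d_update(x[, f], w, pars)
      em$pi[s, f] <- pars$pi
      em$mu1[s, f] <- pars$mu1; em$mu2[s, f] <- pars$mu2
      em$var1[s, f] <- pars$var1; em$var2[s, f] <- pars$var2
    }
  }
  em
}

#' Baum-Welch estimation of the non-homogeneous HMM
#'
#' Runs expectation-maximization on all fragments carrying at least
#' `min_cpgs_train` CpGs. The E-step is the forward-backward recursion
#' without any methylation prior (the prior enters only at decoding); the
#' M-step re-estimates initiation probabilities per offset bin and transition
#' matrices per distance bin from expected counts (pseudocount 1), and each
#' state-feature emission mixture by one responsibility-weighted EM update.
#' Training stops at `max_iter` iterations or when the sampled KL divergence
#' between successive models falls below `kl_tol`, or changes by less than
#' `kl_rel_tol` relative to the previous iteration's divergence.
#'
#' @param frags a z-scored `fragment_set`.
#' @param model an initialized, labeled `nhmm` (see [gmm_initialize()] and
#'   [assign_state_labels()]).
#' @param max_iter iteration cap (default 50).
#' @param min_cpgs_train minimum CpGs per training fragment (default 7).
#' @param kl_sample number of fragments (minimum 5 CpGs) sampled once per run
#'   for the KL statistic (default 10000).
#' @param kl_tol absolute KL convergence threshold (default 1e-4).
#' @param kl_rel_tol relative KL-change threshold (default 0.01).
#' @param seed RNG seed for the KL fragment sample.
#' @param verbose print per-iteration diagnostics.
#' @return the trained `nhmm`, with `loglik_trace`, `kl_trace`,
#'   `trained_iterations`, `converged`, and `convergence_reason` filled in.
#' @export
baum_welch <- function(frags, model, max_iter = 50L, min_cpgs_train = 7L,
                       kl_sample = 10000L, kl_tol = 1e-4, kl_rel_tol = 0.01,
                       seed = 1L, verbose = FALSE) {
  stopifnot(inherits(frags, "fragment_set"), inherits(model, "nhmm"))
  train_ids <- frags$fragments[n_cpg >= min_cpgs_train, frag_id]
  if (length(train_ids) == 0)
    stop(sprintf(paste0("no fragment has >= %d CpGs; reduce min_cpgs_train"),
                 min_cpgs_train))
  chain <- build_chain(frags, model, frag_ids = train_ids)

  kl_pool <- frags$fragments[n_cpg >= 5L, frag_id]
  if (length(kl_pool) == 0) kl_pool <- train_ids
  set.seed(seed)
  kl_ids <- if (length(kl_pool) > kl_sample)
    sort(sample(kl_pool, kl_sample)) else kl_pool
  kl_frags <- frags
  kl_chain_ids <- kl_ids

  model$loglik_trace <- numeric(0)
  model$kl_trace <- numeric(0)
  model$converged <- FALSE
  model$convergence_reason <- NA_character_
  model$trained_iterations <- 0L
  if (max_iter == 0L) return(model)

  d_prev <- NA_real_
  for (it in seq_len(max_iter)) {
    e <- chain_estep(chain, model)
    if (!is.finite(e$loglik))
      stop("non-finite training log-likelihood at iteration ", it)
    model$loglik_trace <- c(model$loglik_trace, e$loglik)

    new_model <- model
    ic <- e$init_counts + 1
    new_model$init <- ic / rowSums(ic)
    tc <- e$trans_counts + 1
    denom <- apply(tc, c(1, 2), sum)
    for (s in 1:2) tc[, , s] <- tc[, , s] / denom
    new_model$trans <- tc
    new_model$emis <- mstep_emissions(model, chain$x, e$gamma)

    d <- kl_divergence(model, new_model, kl_frags, frag_ids = kl_chain_ids)
    new_model$loglik_trace <- model$loglik_trace
    new_model$kl_trace <- c(model$kl_trace, d)
    new_model$trained_iterations <- it
    model <- new_model
    if (verbose)
      message(sprintf("iter %d: loglik %.4f, KL %.3g", it,
                      tail(model$loglik_trace, 1), d))
    if (d < kl_tol) {
      model$converged <- TRUE
      model$convergence_reason <- sprintf("KL %.3g < %.0e", d, kl_tol)
      break
    }
    if (!is.na(d_prev) && d_prev > 0 && abs(d - d_prev) / d_prev < kl_rel_tol) {
      model$converged <- TRUE
      model$convergence_reason <-
        sprintf("KL change %.3g%% < %.3g%%",
                100 * abs(d - d_prev) / d_prev, 100 * kl_rel_tol)
      break
    }
    d_prev <- d
  }
  validate_nhmm(model, tol = 1e-8)
  model
}
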