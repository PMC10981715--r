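#' Per-CpG methylation prior track
#'
#' Wraps a per-CpG prior probability of methylation (typically from healthy
#' buffy-coat bisulfite data). CpGs absent from the track receive `default_k`
#' (by default the track's genome-wide mean). The prior is applied only at
#' decoding, blended with an uninformative prior by weight `w`:
#' `k' = w * k + (1 - w) * 0.5`, so `w = 0` disables it entirely.
#'
#' @param track a data.frame/data.table with columns chrom, pos (0-based C
#'   position), k in `[0,1]`; or a path to a TSV/bedGraph (chrom, start, end,
#'   value) file.
#' @param default_k prior for unlisted CpGs; default mean of `k`.
#' @param w prior weight in `[0,1]` (default 1: pure prior).
#' @return object of class `methylation_prior`.
#' @export
methylation_prior <- function(track, default_k = NULL, w = 1) {
  stopifnot(w >= 0, w <= 1)
  if (is.character(track)) {
    tt <- fread(track)
    if (ncol(tt) >= 4) tt <- tt[, c(1, 2, 4)]
    setnames(tt, c("chrom", "pos", "k"))
  } else {
    tt <- as.data.table(track)
    if (!all(c("chrom", "pos", "k") %in% names(tt)))
      setnames(tt, 1:3, c("chrom", "pos", "k"))
    tt <- tt[, .(chrom, pos, k)]
  }
  if (nrow(tt) > 0 && (min(tt$k) < 0 || max(tt$k) > 1))
    stop("prior values must lie in [0, 1]")
  tt <- unique(tt, by = c("chrom", "pos"))
  if (is.null(default_k))
    default_k <- if (nrow(tt) > 0) mean(tt$k) else 0.5
  setkey(tt, chrom, pos)
  structure(list(track = tt, default_k = default_k, w = w),
            class = "methylation_prior")
}

prior_at <- function(prior, chrom, pos) {
  if (is.null(prior)) return(rep(0.5, length(pos)))
  q <- data.table(chrom = chrom, pos = pos)
  k <- prior$track[q, k, on = c("chrom", "pos"), mult = "first"]
  k[is.na(k)] <- prior$default_k
  k
}

#' Prior-adjusted posterior emission probability
#'
#' Combines the state-conditional emission likelihoods with the per-CpG
#' methylation prior: with effective prior `k' = w*k + (1-w)*0.5`,
#' `Pr(M | e) = L_m * k' / (L_m * k' + L_u * (1 - k'))` and `Pr(U | e)` its
#' complement. Computed in log space so simultaneous underflow of both
#' likelihoods cannot produce 0/0.
#'
#' @param lik_m,lik_u emission likelihoods (or any positive multiples of
#'   them) under the methylated and unmethylated state; vectors allowed.
#' @param k per-CpG prior probability of methylation in `[0,1]`.
#' @param w prior weight in `[0,1]`.
#' @param log_input if `TRUE`, `lik_m`/`lik_u` are log-likelihoods.
#' @return matrix with columns `M` and `U`, rows summing to one.
#' @export
posterior_emission <- function(lik_m, lik_u, k, w = 1, log_input = FALSE) {
  stopifnot(all(k >= 0 & k <= 1), w >= 0, w <= 1)
  kp <- w * k + (1 - w) * 0.5
  lm <- if (log_input) lik_m else log(lik_m)
  lu <- if (log_input) lik_u else log(lik_u)
  a <- lm + log(kp)
  b <- lu + log1p(-kp)
  # resolve degenerate priors exactly
  a[kp == 0] <- -Inf; b[kp == 1] <- -Inf
  mx <- pmax(a, b)
  lse <- mx + log(exp(a - mx) + exp(b - mx))
  pm <- exp(a - lse)
  cbind(M = pm, U = 1 - pm)
}

#' Viterbi decoding of fragment methylation states
#'
#' Computes, per fragment, the most probable U/M path using offset-binned
#' initiation, distance-binned transitions, and the prior-adjusted emission
#' posteriors of [posterior_emission()], all in log space; the per-CpG
#' posterior `Pr(M)` from the analogous forward-backward recursion is stored
#' alongside, as is the fragment log-likelihood. There is no minimum CpG
#' count at decoding.
#'
#' @param frags a z-scored `fragment_set`.
#' @param model a trained `nhmm`.
#' @param prior a [methylation_prior()] or `NULL` (uniform prior).
#' @return object of class `decoded_fragments`: list with `obs` (adds `state`
#'   in U/M and `post_m`), `fragments` (adds `loglik`), `sample_id`.
#' @export
viterbi_decode <- function(frags, model, prior = NULL) {
  stopifnot(inherits(frags, "fragment_set"), inherits(model, "nhmm"))
  chain <- build_chain(frags, model)
  le <- chain_logemis(chain, model)           # columns: U, M
  k <- prior_at(prior, chain$obs$chrom, chain$obs$pos)
  w <- if (is.null(prior)) 0 else prior$w
  post <- posterior_emission(le[, 2], le[, 1], k, w = w, log_input = TRUE)
  le_adj <- cbind(log(post[, "U"]), log(post[, "M"]))
  path <- nhmm_viterbi(le_adj, chain$frag_ptr, chain$off_bin, chain$dist_bin,
                       log(model$init), log(as.vector(model$trans)),
                       length(model$dist_edges))
  e <- nhmm_estep(le_adj, chain$frag_ptr, chain$off_bin, chain$dist_bin,
                  log(model$init), log(as.vector(model$trans)),
                  length(model$dist_edges))
  obs <- chain$obs
  obs[, state := c("U", "M")[path]]
  obs[, post_m := e$gamma[, 2]]
  fr <- copy(frags$fragments)[frag_id %in% chain$frag_id]
  fr[data.table(frag_id = chain$frag_id, ll = as.numeric(e$ll_frag)),
     loglik := i.ll, on = "frag_id"]
  structure(list(obs = obs, fragments = fr, sample_id = frags$sample_id),
            class = "decoded_fragments")
}

#' @export
print.decoded_fragments <- function(x, ...) {
  cat(sprintf("decoded_fragments '%s': %d fragments, %d CpG calls (%.1f%% M)\n",
              x$sample_id, nrow(x$fragments), nrow(x$obs),
              100 * mean(x$obs$state == "M")))
  invisible(x)
}
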