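suppressPackageStartupMessages(library(data.table))

# small simulated dataset shared across test files; built once per test run
small_sim <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(genome_length = 2e5, n_islands = 6, n_fragments = 4000,
                      seed = 101)
    dir <- file.path(tempdir(), "finaleme-small-sim")
    genome <- simulate_genome(cfg, dir = dir)
    methylomes <- simulate_methylomes(cfg, genome)
    wts <- c(0.5, 0.2, 0.1, 0.1, 0.05, 0.05)
    sim <- simulate_fragments(cfg, genome,
                              list(meth = methylomes$meth, weights = wts),
                              dir = dir)
    frags <- extract_fragments(sim$bam, genome$index)
    frags <- zscore_features(frags)
    frags <- suppressWarnings(attach_truth(frags, sim$truth))
    cache <<- list(cfg = cfg, genome = genome, methylomes = methylomes,
                   weights = wts, sim = sim, frags = frags)
    cache
  }
})

# a hand-set, well-conditioned model for decoding/likelihood tests
toy_model <- function() {
  m <- nhmm()
  nb <- length(m$dist_edges); no <- length(m$offset_edges)
  m$init <- cbind(seq(0.35, 0.6, length.out = no))
  m$init <- cbind(m$init, 1 - m$init)
  stay <- seq(0.9, 0.6, length.out = nb)
  m$trans <- array(0, c(nb, 2, 2))
  for (b in seq_len(nb))
    m$trans[b, , ] <- matrix(c(stay[b], 1 - stay[b], 1 - stay[b], stay[b]),
                             2, byrow = TRUE)
  m$emis$pi <- matrix(c(0.3, 0.4, 0.25, 0.35, 0.3, 0.45), 2, 3, byrow = TRUE)
  m$emis$mu1 <- matrix(c(-1.5, -1.2, -1.8, 0.3, 0.2, 0.1), 2, 3, byrow = TRUE)
  m$emis$mu2 <- matrix(c(-0.2, 0.3, -0.3, 1.7, 1.5, 1.9), 2, 3, byrow = TRUE)
  m$emis$var1 <- matrix(0.4, 2, 3)
  m$emis$var2 <- matrix(0.6, 2, 3)
  m
}

# generating model for parameter-recovery runs: distinct per-bin transitions
# and well-separated mixture components (identifiable at moderate n)
recovery_model <- function() {
  m <- nhmm()
  nb <- length(m$dist_edges); no <- length(m$offset_edges)
  m$init <- cbind(seq(0.3, 0.55, length.out = no))
  m$init <- cbind(m$init, 1 - m$init)
  stay <- seq(0.95, 0.6, length.out = nb)
  m$trans <- array(0, c(nb, 2, 2))
  for (b in seq_len(nb))
    m$trans[b, , ] <- matrix(c(stay[b], 1 - stay[b], 1 - stay[b], stay[b]),
                             2, byrow = TRUE)
  m$emis$pi <- matrix(c(0.3, 0.4, 0.25, 0.35, 0.3, 0.45), 2, 3, byrow = TRUE)
  m$emis$mu1 <- matrix(c(-1.8, -1.5, -2.0, 0.3, 0.2, 0.1), 2, 3, byrow = TRUE)
  m$emis$mu2 <- matrix(c(-0.2, 0.2, -0.4, 2.0, 1.9, 2.2), 2, 3, byrow = TRUE)
  m$emis$var1 <- matrix(0.25, 2, 3)
  m$emis$var2 <- matrix(0.35, 2, 3)
  m
}

# reference (plain R) emission log-density: two-component mixture per feature
ref_emission_loglik <- function(model, x, s) {
  sum(vapply(1:3, function(f) {
    p <- model$emis$pi[s, f]
    log((1 - p) * dnorm(x[f], model$emis$mu1[s, f], sqrt(model$emis$var1[s, f])) +
        p * dnorm(x[f], model$emis$mu2[s, f], sqrt(model$emis$var2[s, f])))
  }, 0))
}

# brute-force fragment likelihood and best path by enumeration over all 2^L
# state sequences; obs rows are one fragment's observations in order
ref_enumerate <- function(model, x, offset, dists, prior_k = NULL, w = 0) {
  L <- nrow(x)
  # independent binning: first upper edge that is >= the value
  ob <- 1L + sum(offset > head(model$offset_edges, -1))
  db <- if (L > 1) vapply(dists, function(d)
    1L + sum(d > head(model$dist_edges, -1)), 0L) else integer(0)
  le <- matrix(0, L, 2)
  for (t in seq_len(L)) for (s in 1:2)
    le[t, s] <- ref_emission_loglik(model, x[t, ], s)
  if (!is.null(prior_k)) {
    kp <- w * prior_k + (1 - w) * 0.5
    for (t in seq_len(L)) {
      a <- le[t, 2] + log(kp[t]); b <- le[t, 1] + log(1 - kp[t])
      mx <- max(a, b); lse <- mx + log(exp(a - mx) + exp(b - mx))
      le[t, 2] <- a - lse; le[t, 1] <- b - lse
    }
  }
  grid <- as.matrix(expand.grid(rep(list(1:2), L)))
  lp <- apply(grid, 1, function(path) {
    v <- log(model$init[ob, path[1]]) + le[1, path[1]]
    if (L > 1) for (t in 2:L)
      v <- v + log(model$trans[db[t - 1], path[t - 1], path[t]]) + le[t, path[t]]
    v
  })
  mx <- max(lp)
  list(loglik = mx + log(sum(exp(lp - mx))),
       best_path = grid[which.max(lp), ],
       best_lp = max(lp))
}

# random single-fragment observation sets for oracle comparisons
random_fragment <- function(model, L, seed) {
  set.seed(seed)
  list(x = matrix(rnorm(L * 3, sd = 1.5), L, 3),
       offset = sample(c(3L, 30L, 60L, 90L, 130L, 200L), 1),
       dists = if (L > 1) sample(c(4L, 15L, 35L, 80L, 150L, 300L, 700L),
                                 L - 1, replace = TRUE) else integer(0))
}

# wrap a single fragment as a fragment_set
as_fragment_set <- function(x, offset, dists, truth = NULL) {
  L <- nrow(x)
  pos <- cumsum(c(1000L + offset, dists))
  obs <- data.table(frag_id = 1L, chrom = "chr1", pos = as.integer(pos),
                    offset = c(offset, offset + cumsum(dists))[seq_len(L)],
                    dist_prev = c(NA_integer_, dists),
                    len_raw = NA_real_, cov_raw = NA_real_, d2c_raw = NA_real_,
                    len_z = x[, 1], cov_z = x[, 2], d2c_z = x[, 3])
  if (!is.null(truth)) obs[, truth := truth]
  ft <- data.table(frag_id = 1L, chrom = "chr1", start = 1000L,
                   end = as.integer(max(pos) + 50L),
                   length = as.integer(max(pos) + 50L - 1000L), n_cpg = L)
  structure(list(fragments = ft, obs = obs, stats = list(),
                 sample_id = "test", n_hq_fragments = 1L),
            class = "fragment_set")
}

# exhaustive active-set QP oracle for min ||Aw-b||^2, w>=0, sum(w)=1
ref_simplex_ls <- function(A, b) {
  p <- ncol(A)
  best <- NULL; best_obj <- Inf
  for (mask in seq_len(2^p - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    As <- A[, S, drop = FALSE]
    K <- rbind(cbind(2 * crossprod(As), rep(1, length(S))),
               c(rep(1, length(S)), 0))
    rhs <- c(2 * crossprod(As, b), 1)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    ws <- sol[seq_along(S)]
    if (any(ws < -1e-9)) next
    w <- numeric(p); w[S] <- pmax(ws, 0); w <- w / sum(w)
    obj <- sum((A %*% w - b)^2)
    if (obj < best_obj - 1e-12) { best_obj <- obj; best <- w }
  }
  best
}
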