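test_that("emission log-density matches a directly coded mixture formula", {
  m <- toy_model()
  set.seed(4)
  x <- matrix(rnorm(30), 10, 3)
  le <- finaleme:::nhmm_logemis(x, m$emis$pi, m$emis$mu1, m$emis$mu2,
                                m$emis$var1, m$emis$var2)
  for (t in 1:10) for (s in 1:2)
    expect_equal(le[t, s], ref_emission_loglik(m, x[t, ], s),
                 tolerance = 1e-12)
  # mixture weight 0 collapses to the first component
  m0 <- m
  m0$emis$pi[] <- 0
  le0 <- finaleme:::nhmm_logemis(x, m0$emis$pi, m0$emis$mu1, m0$emis$mu2,
                                 m0$emis$var1, m0$emis$var2)
  ref <- sapply(1:2, function(s) sapply(1:10, function(t)
    sum(dnorm(x[t, ], m0$emis$mu1[s, ], sqrt(m0$emis$var1[s, ]), log = TRUE))))
  expect_equal(unname(le0), unname(ref), tolerance = 1e-12)
  expect_error(finaleme:::nhmm_logemis(matrix(c(NA, 1, 1), 1, 3),
                                       m$emis$pi, m$emis$mu1, m$emis$mu2,
                                       m$emis$var1, m$emis$var2),
               "non-finite")
})

test_that("forward log-likelihood equals brute-force enumeration over paths", {
  m <- toy_model()
  for (i in 1:25) {
    L <- sample(1:10, 1)
    rf <- random_fragment(m, L, seed = 1000 + i)
    fr <- as_fragment_set(rf$x, rf$offset, rf$dists)
    ll <- fragment_loglik(fr, m)$loglik
    ref <- ref_enumerate(m, rf$x, rf$offset, rf$dists)
    expect_equal(ll, ref$loglik, tolerance = 1e-8)
  }
})

test_that("Viterbi path equals the exhaustive argmax over state sequences", {
  m <- toy_model()
  for (i in 1:25) {
    L <- sample(1:10, 1)
    rf <- random_fragment(m, L, seed = 2000 + i)
    fr <- as_fragment_set(rf$x, rf$offset, rf$dists)
    dec <- viterbi_decode(fr, m)
    ref <- ref_enumerate(m, rf$x, rf$offset, rf$dists)
    expect_equal(match(dec$obs$state, c("U", "M")), unname(ref$best_path))
  }
})

test_that("decoding with a prior matches prior-adjusted enumeration", {
  m <- toy_model()
  for (i in 1:10) {
    L <- sample(2:8, 1)
    rf <- random_fragment(m, L, seed = 3000 + i)
    fr <- as_fragment_set(rf$x, rf$offset, rf$dists)
    set.seed(i)
    k <- runif(L)
    pr <- methylation_prior(data.frame(chrom = "chr1", pos = fr$obs$pos,
                                       k = k), w = 1)
    dec <- viterbi_decode(fr, m, pr)
    ref <- ref_enumerate(m, rf$x, rf$offset, rf$dists, prior_k = k, w = 1)
    expect_equal(match(dec$obs$state, c("U", "M")), unname(ref$best_path))
    expect_equal(unique(dec$fragments$loglik), ref$loglik, tolerance = 1e-8)
  }
})

test_that("posterior emission follows the stated closed forms", {
  # uniform prior: normalized likelihood ratio
  expect_equal(posterior_emission(0.3, 0.1, 0.5)[, "M"],
               c(M = 0.3 / 0.4))
  # degenerate prior forces the methylated state
  expect_equal(posterior_emission(0.3, 0.1, 1)[, "M"], c(M = 1))
  expect_equal(posterior_emission(0.3, 0.1, 0)[, "M"], c(M = 0))
  # worked value: L_m=0.3, L_u=0.1, k'=0.25 -> 0.5
  expect_equal(posterior_emission(0.3, 0.1, 0.25)[, "M"], c(M = 0.5))
  # rows sum to one; log input agrees with linear input
  set.seed(8)
  lm <- runif(50); lu <- runif(50); k <- runif(50)
  p <- posterior_emission(lm, lu, k)
  expect_equal(rowSums(p), rep(1, 50))
  p2 <- posterior_emission(log(lm), log(lu), k, log_input = TRUE)
  expect_equal(p, p2)
  # prior weight 0 makes the prior irrelevant
  expect_equal(posterior_emission(lm, lu, k, w = 0)[, "M"], lm / (lm + lu))
  # deep log-space underflow never yields 0/0
  p3 <- posterior_emission(-2000, -2001, 0.5, log_input = TRUE)
  expect_equal(unname(p3[, "M"]), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_true(all(is.finite(p3)))
})

test_that("with zero prior weight the decode ignores the prior contents", {
  m <- toy_model()
  rf <- random_fragment(m, 6, seed = 77)
  fr <- as_fragment_set(rf$x, rf$offset, rf$dists)
  pr1 <- methylation_prior(data.frame(chrom = "chr1", pos = fr$obs$pos,
                                      k = rep(0.99, 6)), w = 0)
  pr2 <- methylation_prior(data.frame(chrom = "chr1", pos = fr$obs$pos,
                                      k = rep(0.01, 6)), w = 0)
  d1 <- viterbi_decode(fr, m, pr1)
  d2 <- viterbi_decode(fr, m, pr2)
  d0 <- viterbi_decode(fr, m, NULL)
  expect_equal(d1$obs$post_m, d2$obs$post_m)
  expect_equal(d1$obs$post_m, d0$obs$post_m)
  expect_equal(d1$obs$state, d0$obs$state)
})

test_that("relabeling U and M leaves fragment likelihoods unchanged", {
  m <- toy_model()
  for (i in 1:5) {
    rf <- random_fragment(m, 7, seed = 500 + i)
    fr <- as_fragment_set(rf$x, rf$offset, rf$dists)
    expect_equal(fragment_loglik(fr, m)$loglik,
                 fragment_loglik(fr, swap_states(m))$loglik,
                 tolerance = 1e-12)
  }
})

test_that("an uninformative emission with an all-methylated prior decodes all-M", {
  m <- toy_model()
  m$emis$mu1[2, ] <- m$emis$mu1[1, ]; m$emis$mu2[2, ] <- m$emis$mu2[1, ]
  m$emis$var1[2, ] <- m$emis$var1[1, ]; m$emis$var2[2, ] <- m$emis$var2[1, ]
  m$emis$pi[2, ] <- m$emis$pi[1, ]
  rf <- random_fragment(m, 8, seed = 91)
  fr <- as_fragment_set(rf$x, rf$offset, rf$dists)
  pr <- methylation_prior(data.frame(chrom = "chr1", pos = fr$obs$pos,
                                     k = rep(1, 8)), w = 1)
  dec <- viterbi_decode(fr, m, pr)
  expect_true(all(dec$obs$state == "M"))
  expect_equal(dec$obs$post_m, rep(1, 8), tolerance = 1e-12)
})

test_that("single-CpG fragments decode to the initiation-posterior argmax", {
  m <- toy_model()
  rf <- random_fragment(m, 1, seed = 55)
  fr <- as_fragment_set(rf$x, rf$offset, rf$dists)
  dec <- viterbi_decode(fr, m)
  le <- finaleme:::nhmm_logemis(rf$x, m$emis$pi, m$emis$mu1, m$emis$mu2,
                                m$emis$var1, m$emis$var2)
  ob <- 1L + sum(rf$offset > head(m$offset_edges, -1))
  sc <- log(m$init[ob, ]) + le[1, ] - log(sum(exp(le[1, ])))
  expect_equal(dec$obs$state, c("U", "M")[which.max(sc)])
})

test_that("GMM initialization recovers well-separated clusters and is deterministic", {
  set.seed(12)
  n <- 100
  x <- rbind(matrix(rnorm(n * 3, -2, 0.5), n, 3),
             matrix(rnorm(n * 3, 2, 0.5), n, 3))
  lab <- rep(1:2, each = n)
  g1 <- finaleme:::fit_diag_gmm(x, seed = 3)
  g2 <- finaleme:::fit_diag_gmm(x, seed = 3)
  expect_identical(g1$assign, g2$assign)
  agreement <- max(mean(g1$assign == lab), mean(g1$assign != lab))
  expect_equal(agreement, 1)
  # identical observations cannot be split
  expect_error(finaleme:::fit_diag_gmm(matrix(1, 50, 3)), "degenerate")
})

test_that("state labeling follows distance-to-center (wgs) or truth (wgbs)", {
  s <- small_sim()
  init <- gmm_initialize(s$frags, seed = 101)
  m_wgs <- assign_state_labels(init, s$frags, mode = "wgs")
  obs <- s$frags$obs
  d2c_means <- sapply(1:2, function(k) mean(obs$d2c_z[init$assign == k]))
  expect_equal(attr(m_wgs, "m_component"), unname(which.max(d2c_means)))
  m_wgbs <- assign_state_labels(init, s$frags, mode = "wgbs")
  meth_means <- sapply(1:2, function(k)
    mean(obs$truth[init$assign == k] == "M", na.rm = TRUE))
  expect_equal(attr(m_wgbs, "m_component"), unname(which.max(meth_means)))
  # the two criteria agree here: methylated fragments sit farther from center
  expect_equal(attr(m_wgs, "m_component"), attr(m_wgbs, "m_component"))
})

test_that("labeling tie falls back to fragment length deterministically", {
  x <- matrix(rnorm(60), 20, 3)
  fr <- as_fragment_set(x[1:10, ], offset = 10L,
                        dists = rep(20L, 9))
  fr$obs$d2c_z <- rep(0, 10)                  # equal means across components
  fr$obs$len_z <- rep(c(2, -2), 5)
  init <- list(model = toy_model(), assign = rep(1:2, 5))
  expect_message(m <- assign_state_labels(init, fr, mode = "wgs"), "tie")
  expect_equal(attr(m, "m_component"), 1L)    # longer mean length wins
})

test_that("model JSON serialization round-trips to identical decodes", {
  s <- small_sim()
  init <- gmm_initialize(s$frags, seed = 101)
  mod <- baum_welch(s$frags, assign_state_labels(init, s$frags, "wgs"),
                    max_iter = 5L, seed = 101)
  path <- tempfile(fileext = ".json")
  write_nhmm(mod, path, stats = s$frags$stats)
  back <- read_nhmm(path)
  expect_equal(back$model$init, mod$init, tolerance = 1e-12)
  expect_equal(back$model$trans, mod$trans, tolerance = 1e-12)
  expect_equal(back$model$emis, mod$emis, tolerance = 1e-12)
  d1 <- viterbi_decode(s$frags, mod)
  d2 <- viterbi_decode(s$frags, back$model)
  expect_identical(d1$obs$state, d2$obs$state)
  expect_equal(d1$obs$post_m, d2$obs$post_m, tolerance = 1e-12)
  expect_error(read_nhmm(s$sim$truth), "not a finaleme model")
})
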