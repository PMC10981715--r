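make_decoded <- function(obs) {
  structure(list(obs = as.data.table(obs),
                 fragments = as.data.table(obs)[, .(n_cpg = .N), by = frag_id],
                 sample_id = "test"),
            class = "decoded_fragments")
}

test_that("track aggregation counts each fragment call once per site", {
  obs <- data.table(frag_id = c(1, 2, 3, 1, 2),
                    chrom = "chr1", pos = c(10L, 10L, 10L, 50L, 50L),
                    state = c("M", "M", "U", "U", "U"), post_m = 0.5)
  tr <- aggregate_track(make_decoded(obs))
  expect_equal(tr[pos == 10, level], 2 / 3)
  expect_equal(tr[pos == 50, c(n_meth, n_total)], c(0L, 2L))
  # uncovered sites are absent
  expect_equal(nrow(tr), 2L)
  # empty input
  expect_equal(nrow(aggregate_track(make_decoded(obs[0]))), 0L)
})

test_that("track equals a hand-enumerated table on random decoded calls", {
  set.seed(14)
  obs <- data.table(frag_id = rep(1:100, each = 3),
                    chrom = "chr1",
                    pos = as.integer(sample(seq(10, 100, 10), 300, TRUE)),
                    state = sample(c("U", "M"), 300, TRUE), post_m = 0.5)
  obs <- unique(obs, by = c("frag_id", "pos"))
  tr <- aggregate_track(make_decoded(obs))
  for (p in unique(tr$pos)) {
    sub <- obs[pos == p]
    expect_equal(tr[pos == p, n_meth], sum(sub$state == "M"))
    expect_equal(tr[pos == p, n_total], nrow(sub))
  }
})

test_that("window summaries pool counts and flag empty windows", {
  tr <- as_cpg_track(data.table(chrom = "chr1", pos = c(100L, 150L, 900L),
                                n_meth = c(2L, 1L, 0L), n_total = c(3L, 1L, 4L)))
  w <- data.table(chrom = "chr1", start = c(0L, 200L, 800L),
                  end = c(200L, 800L, 1000L))
  out <- window_summarize(tr, w)
  expect_equal(out[start == 0, density], 3 / 4)
  expect_true(is.na(out[start == 200, density]))
  expect_equal(out[start == 800, density], 0)
  # half-open: a site exactly at a window end belongs to the next window
  tr2 <- as_cpg_track(data.table(chrom = "chr1", pos = 200L, n_meth = 1L,
                                 n_total = 1L))
  out2 <- window_summarize(tr2, w)
  expect_true(is.na(out2[start == 0, density]))
  expect_equal(out2[start == 200, density], 1)
})

test_that("window counts over a tiling conserve site counts", {
  s <- small_sim()
  init <- gmm_initialize(s$frags, seed = 101)
  mod <- baum_welch(s$frags, assign_state_labels(init, s$frags, "wgs"),
                    max_iter = 3L, seed = 101)
  dec <- viterbi_decode(s$frags, mod)
  tr <- aggregate_track(dec)
  w <- tile_windows(s$genome$seqlengths, 1000L)
  ws <- window_summarize(tr, w)
  expect_equal(sum(ws$n_total), sum(tr$n_total))
  expect_equal(sum(ws$n_meth), sum(tr$n_meth))
})

test_that("correlations hit the closed-form extremes and a direct oracle", {
  set.seed(3)
  pos <- sort(sample.int(10000, 60))
  lv <- runif(60)
  a <- as_cpg_track(data.table(chrom = "chr1", pos = pos, level = lv,
                               n_total = 10L))
  expect_equal(correlate_tracks(a, a, min_coverage = 1L)[1, pearson], 1)
  b <- as_cpg_track(data.table(chrom = "chr1", pos = pos, level = 1 - lv,
                               n_total = 10L))
  cc <- correlate_tracks(a, b, min_coverage = 1L)
  expect_equal(cc[1, pearson], -1)
  expect_equal(cc[1, spearman], -1)
  # direct-formula oracle on another pair
  lv2 <- runif(60)
  d <- as_cpg_track(data.table(chrom = "chr1", pos = pos, level = lv2,
                               n_total = 10L))
  cd <- correlate_tracks(a, d, min_coverage = 1L)
  expect_equal(cd[1, pearson], cor(lv, lv2), tolerance = 1e-12)
  expect_equal(cd[1, spearman], cor(lv, lv2, method = "spearman"),
               tolerance = 1e-12)
  expect_equal(cd[1, n], 60L)
})

test_that("coverage strata require the minimum in both tracks", {
  a <- as_cpg_track(data.table(chrom = "chr1", pos = c(1L, 11L, 21L, 31L),
                               level = c(0.1, 0.4, 0.6, 0.9),
                               n_total = c(1L, 5L, 5L, 5L)))
  b <- as_cpg_track(data.table(chrom = "chr1", pos = c(1L, 11L, 21L, 31L),
                               level = c(0.2, 0.5, 0.5, 0.8),
                               n_total = c(5L, 5L, 1L, 5L)))
  cc <- correlate_tracks(a, b, min_coverage = c(1L, 5L))
  expect_equal(cc[stratum == "cpg_cov>=1", n], 4L)
  expect_equal(cc[stratum == "cpg_cov>=5", n], 2L)
  # fewer than 3 comparable sites -> missing
  expect_true(is.na(cc[stratum == "cpg_cov>=5", pearson]))
})

test_that("balanced ROC evaluation behaves at the extremes", {
  set.seed(2)
  n <- 2000
  truth <- sample(c("U", "M"), n, TRUE)
  obs <- data.table(frag_id = rep(1:(n / 5), each = 5), chrom = "chr1",
                    pos = seq_len(n), truth = truth)
  perfect <- copy(obs)[, `:=`(state = truth, post_m = as.numeric(truth == "M"))]
  ev <- evaluate_binary(make_decoded(perfect), min_cpgs_per_fragment = 1L,
                        seed = 1)
  expect_equal(ev$auroc, 1)
  # uninformative posteriors give chance-level performance
  null <- copy(obs)[, `:=`(state = "U", post_m = runif(n))]
  ev0 <- evaluate_binary(make_decoded(null), min_cpgs_per_fragment = 1L,
                         seed = 1)
  expect_lt(abs(ev0$auroc - 0.5), 0.03)
  # ROC curve is monotone and anchored
  expect_true(all(diff(ev0$roc$fpr) >= 0))
  expect_true(all(diff(ev0$roc$tpr) >= 0))
  # balance: equal class counts after downsampling
  expect_equal(ev0$n_compared %% 2, 0)
  # one empty class errors
  allm <- copy(obs)[, `:=`(truth = "M", state = "M", post_m = 0.9)]
  expect_error(evaluate_binary(make_decoded(allm), 1L, seed = 1), "empty")
})

test_that("auROC is invariant under strictly monotone transforms of the score", {
  set.seed(4)
  n <- 500
  obs <- data.table(frag_id = rep(1:100, each = 5), chrom = "chr1",
                    pos = seq_len(n),
                    truth = sample(c("U", "M"), n, TRUE))
  obs[, post_m := runif(n) * 0.5 + 0.5 * (truth == "M")]
  obs[, state := ifelse(post_m > 0.5, "M", "U")]
  e1 <- evaluate_binary(make_decoded(obs), 1L, seed = 9)
  obs2 <- copy(obs)[, post_m := plogis(5 * post_m - 2)]
  e2 <- evaluate_binary(make_decoded(obs2), 1L, seed = 9)
  expect_equal(e1$auroc, e2$auroc, tolerance = 1e-12)
})

test_that("the min-CpG restriction drops fragments below the threshold", {
  obs <- data.table(frag_id = c(rep(1L, 6), rep(2L, 2)), chrom = "chr1",
                    pos = 1:8, truth = rep(c("U", "M"), 4),
                    state = "U", post_m = seq(0.1, 0.8, 0.1))
  ev <- evaluate_binary(make_decoded(obs), min_cpgs_per_fragment = 5L,
                        seed = 1)
  expect_equal(ev$n_compared, 6L)
})

test_that("the rank-sum window test matches exact enumeration and extremes", {
  case <- matrix(c(0.9, 0.95, 0.92, 0.88), 1)
  ctrl <- matrix(c(0.1, 0.12, 0.08, 0.15), 1)
  out <- wilcoxon_dmr(case, ctrl, p_cutoff = 0.05)
  # fully separated 4 vs 4: exact two-sided p = 2/choose(8,4) = 0.0286
  expect_equal(out$p_value, 2 / choose(8, 4), tolerance = 1e-12)
  expect_true(out$flagged)
  expect_equal(out$direction, "hyper")
  # identical groups are never flagged; all-tied values give p = 1
  same <- matrix(rep(0.5, 4), 1)
  out2 <- wilcoxon_dmr(same, same)
  expect_equal(out2$p_value, 1)
  expect_false(out2$flagged)
  # agreement with stats::wilcox.test on random data with ties
  set.seed(6)
  ca <- matrix(round(runif(40), 1), 5)
  co <- matrix(round(runif(40), 1), 5)
  out3 <- wilcoxon_dmr(ca, co)
  for (i in 1:5) {
    x <- ca[i, ]; y <- co[i, ]
    has_ties <- anyDuplicated(c(x, y)) > 0
    ref <- suppressWarnings(wilcox.test(x, y, exact = !has_ties,
                                        correct = FALSE)$p.value)
    expect_equal(out3$p_value[i], ref, tolerance = 1e-12)
  }
  # under-sized groups are skipped
  out4 <- wilcoxon_dmr(matrix(c(0.5, NA, NA, NA), 1), matrix(runif(4), 1))
  expect_true(is.na(out4$p_value))
})

test_that("rank-sum false-positive rate is calibrated under the null", {
  # group size 12 uses the (continuous) normal approximation, so the
  # attainable level is close to the nominal cut-off
  set.seed(11)
  n_win <- 4000
  case <- matrix(rnorm(n_win * 12), n_win)
  ctrl <- matrix(rnorm(n_win * 12), n_win)
  out <- wilcoxon_dmr(case, ctrl, p_cutoff = 0.05)
  fpr <- mean(out$flagged)
  ci <- qbinom(c(0.025, 0.975), n_win, 0.05) / n_win
  expect_gte(fpr, ci[1] - 0.005)
  expect_lte(fpr, ci[2] + 0.005)
})

test_that("anchor profiles average correctly and mirror minus-strand anchors", {
  tr <- as_cpg_track(data.table(chrom = "chr1",
                                pos = as.integer(seq(100, 4000, 50)),
                                level = 0.42, n_total = 5L))
  an <- data.table(chrom = "chr1", pos = 2000L, strand = "+")
  prof <- anchor_profile(tr, an, flank = 1000L, bin = 200L)
  expect_true(all(abs(prof$mean_level - 0.42) < 1e-12))
  # hand-checked single anchor
  tr2 <- as_cpg_track(data.table(chrom = "chr1",
                                 pos = c(1900L, 1950L, 2100L),
                                 level = c(0.2, 0.4, 0.9), n_total = 1L))
  # bins cover [bin_start, bin_start + bin): offsets -100 and -50 share one bin
  p2 <- anchor_profile(tr2, an, flank = 200L, bin = 100L)
  expect_equal(p2[bin_start == -100, mean_level], mean(c(0.2, 0.4)))
  expect_equal(p2[bin_start == 100, mean_level], 0.9)
  expect_false(-200 %in% p2$bin_start)
  # a minus-strand anchor sees the mirrored profile
  an_m <- data.table(chrom = "chr1", pos = 2000L, strand = "-")
  p3 <- anchor_profile(tr2, an_m, flank = 200L, bin = 100L)
  expect_equal(p3[bin_start == 100, mean_level], 0.2)
  expect_equal(p3[bin_start == 0, mean_level], 0.4)
  expect_equal(p3[bin_start == -100, mean_level], 0.9)
})

test_that("CGI shores are the 2 kb flanks minus the islands", {
  cgi <- data.table(chrom = "chr1", start = c(10000L, 13000L),
                    end = c(11000L, 14000L))
  sh <- cgi_shores(cgi, flank = 2000L)
  gr_sh <- GenomicRanges::GRanges(sh$chrom, IRanges::IRanges(sh$start + 1, sh$end))
  gr_ci <- GenomicRanges::GRanges(cgi$chrom, IRanges::IRanges(cgi$start + 1, cgi$end))
  expect_equal(sum(GenomicRanges::width(GenomicRanges::intersect(gr_sh, gr_ci))), 0)
  # the gap 11000-13000 lies within 2 kb of both islands -> entirely shore
  expect_true(any(sh$start <= 11000 & sh$end >= 13000))
  # outer shores extend 2 kb
  expect_equal(min(sh$start), 8000L)
  expect_equal(max(sh$end), 16000L)
})

test_that("track export writes bedGraph with 4-decimal levels and exact counts", {
  tr <- as_cpg_track(data.table(chrom = "chr1", pos = c(5L, 9L),
                                n_meth = c(1L, 2L), n_total = c(3L, 3L)))
  bg <- tempfile(fileext = ".bedGraph"); tsv <- tempfile(fileext = ".tsv")
  write_track(tr, bedgraph = bg, tsv = tsv)
  out <- fread(bg)
  expect_equal(out$V2, c(5L, 9L))
  expect_equal(out$V3, c(7L, 11L))
  expect_equal(out$V4, round(c(1 / 3, 2 / 3), 4))
  back <- fread(tsv)
  expect_equal(back$n_meth, c(1L, 2L))
})

test_that("trapezoidal auROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  n <- 800
  obs <- data.table(frag_id = rep(1:160, each = 5), chrom = "chr1",
                    pos = seq_len(n),
                    truth = sample(c("U", "M"), n, TRUE))
  obs[, post_m := runif(n) * 0.6 + 0.4 * (truth == "M")]
  obs[, state := ifelse(post_m > 0.5, "M", "U")]
  ev <- evaluate_binary(make_decoded(obs), 1L, seed = 3)
  # rebuild the balanced sample exactly as evaluate_binary does
  d <- obs[truth %in% c("U", "M")]
  nmin <- min(sum(d$truth == "M"), sum(d$truth == "U"))
  set.seed(3)
  im <- sample(which(d$truth == "M"), nmin)
  iu <- sample(which(d$truth == "U"), nmin)
  d <- d[sort(c(im, iu))]
  ref <- as.numeric(pROC::auc(pROC::roc(d$truth == "M", d$post_m,
                                        quiet = TRUE, direction = "<")))
  expect_equal(ev$auroc, ref, tolerance = 1e-12)
})
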