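#' Sample fragments directly from a non-homogeneous HMM
#'
#' Generates observation sequences from known model parameters: per fragment,
#' a first-CpG offset and inter-CpG distances are drawn from the supplied
#' pools, the state sequence follows the offset-binned initiation and
#' distance-binned transition probabilities, and each feature is drawn from
#' its state's two-component Gaussian mixture. Used to verify that training
#' recovers the generating parameters.
#'
#' @param model the generating `nhmm`.
#' @param n_fragments number of fragments.
#' @param n_cpgs integer vector; CpG count per fragment is sampled uniformly
#'   from it (default 7:15).
#' @param offset_pool,dist_pool values sampled (with replacement) for
#'   first-CpG offsets and inter-CpG distances; defaults cover every bin.
#' @param seed RNG seed.
#' @return a z-scored-feature `fragment_set` with `truth` states; feature
#'   values are emitted directly on the z scale (`stats` marked identity).
#' @export
sample_nhmm <- function(model, n_fragments, n_cpgs = 7:15,
                        offset_pool = c(5L, 30L, 60L, 90L, 120L, 200L),
                        dist_pool = c(5L, 15L, 30L, 75L, 150L, 300L, 600L),
                        seed = 1L) {
  stopifnot(inherits(model, "nhmm"), n_fragments > 0)
  set.seed(seed)
  ncp <- sample(rep(n_cpgs, 2), n_fragments, replace = TRUE)
  total <- sum(ncp)
  frag_id <- rep(seq_len(n_fragments), ncp)
  first <- cumsum(c(1L, head(ncp, -1L)))
  is_first <- seq_len(total) %in% first

  offset <- integer(total)
  offset[is_first] <- sample(offset_pool, n_fragments, replace = TRUE)
  dist <- rep(NA_integer_, total)
  dist[!is_first] <- sample(dist_pool, total - n_fragments, replace = TRUE)

  ob <- bin_of(offset[is_first], model$offset_edges)
  db <- integer(total)
  db[!is_first] <- bin_of(dist[!is_first], model$dist_edges)

  state <- integer(total)
  u <- runif(total)
  for (t in seq_len(total)) {
    state[t] <- if (is_first[t]) {
      f <- sum(is_first[seq_len(t)])
      1L + (u[t] < model$init[ob[f], 2])
    } else {
      1L + (u[t] < model$trans[db[t], state[t - 1L], 2])
    }
  }
  # emissions: component then value, per feature
  x <- matrix(0, total, 3)
  for (f in 1:3) {
    comp2 <- runif(total) < model$emis$pi[cbind(state, f)]
    mu <- ifelse(comp2, model$emis$mu2[cbind(state, f)],
                 model$emis$mu1[cbind(state, f)])
    vr <- ifelse(comp2, model$emis$var2[cbind(state, f)],
                 model$emis$var1[cbind(state, f)])
    x[, f] <- rnorm(total, mu, sqrt(vr))
  }

  # positions consistent with offsets/distances (fragment starts spaced out)
  within <- offset
  for (t in seq_len(total)) if (!is_first[t]) within[t] <- within[t - 1L] + dist[t]
  fstart <- cumsum(c(0L, rep(2000L, n_fragments - 1L)))[frag_id]
  pos <- fstart + within
  flen <- rep(tapply(within, frag_id, max), ncp) + 50L

  obs <- data.table(frag_id = frag_id, chrom = "chr1", pos = as.integer(pos),
                    offset = within, dist_prev = dist,
                    len_raw = NA_real_, cov_raw = NA_real_, d2c_raw = NA_real_,
                    len_z = x[, 1], cov_z = x[, 2], d2c_z = x[, 3],
                    truth = c("U", "M")[state])
  ft <- data.table(frag_id = seq_len(n_fragments),
                   chrom = "chr1",
                   start = as.integer(cumsum(c(0L, rep(2000L, n_fragments - 1L)))),
                   end = 0L, length = as.integer(tapply(within, frag_id, max) + 50L),
                   n_cpg = ncp)
  ft[, end := start + length]
  structure(list(fragments = ft, obs = obs,
                 stats = list(total_high_quality_fragments = n_fragments,
                              mean = c(len_raw = 0, cov_raw = 0, d2c_raw = 0),
                              sd = c(len_raw = 1, cov_raw = 1, d2c_raw = 1),
                              cov_outlier = Inf),
                 sample_id = "nhmm-sample", n_hq_fragments = n_fragments),
            class = "fragment_set")
}

#' Build a reference methylome panel from simulated methylomes
#'
#' Summarizes each cell type's per-CpG methylation probabilities into window
#' densities over 1 kb tiles restricted to CpG islands and shores, with a
#' constant sequencing depth per CpG providing the informative-call counts.
#'
#' @param genome a [simulate_genome()] result.
#' @param methylomes a [simulate_methylomes()] result.
#' @param window_width tile width (default 1000).
#' @param bases_per_cpg informative calls contributed per CpG (default 50).
#' @param restrict_cgi keep only tiles overlapping islands or shores
#'   (default TRUE).
#' @return a `methylome_panel`.
#' @export
build_reference_panel <- function(genome, methylomes, window_width = 1000L,
                                  bases_per_cpg = 50L, restrict_cgi = TRUE) {
  w <- tile_windows(genome$seqlengths, window_width)
  if (restrict_cgi && nrow(genome$cgi) > 0) {
    sh <- cgi_shores(genome$cgi, seqlengths = genome$seqlengths)
    terr <- rbind(genome$cgi[, .(chrom, start, end)],
                  sh[, .(chrom, start, end)])
    tg <- GenomicRanges::reduce(GenomicRanges::GRanges(
      terr$chrom, IRanges::IRanges(terr$start + 1L, terr$end)))
    wg <- GenomicRanges::GRanges(w$chrom, IRanges::IRanges(w$start + 1L, w$end))
    w <- w[GenomicRanges::countOverlaps(wg, tg) > 0]
  }
  pos <- genome$index$positions$chr1
  d <- matrix(NA_real_, nrow(w), length(methylomes$cell_types),
              dimnames = list(NULL, methylomes$cell_types))
  b <- matrix(0L, nrow(w), length(methylomes$cell_types),
              dimnames = list(NULL, methylomes$cell_types))
  for (i in seq_len(nrow(w))) {
    inw <- pos >= w$start[i] & pos < w$end[i]
    nc <- sum(inw)
    b[i, ] <- nc * bases_per_cpg
    if (nc > 0) d[i, ] <- colMeans(methylomes$meth[inw, , drop = FALSE])
  }
  keep <- rowSums(b) > 0
  methylome_panel(w[keep], d[keep, , drop = FALSE], b[keep, , drop = FALSE])
}
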