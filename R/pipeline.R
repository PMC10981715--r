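#' Resolve a pipeline run configuration
#'
#' Centralizes every tunable of the staged pipeline with its default, so the
#' parameter set of a run is auditable in one place. Values supplied in
#' `...` (or as a flat key-value YAML-style config file) override defaults;
#' explicit arguments win over the file.
#'
#' @param config_file optional flat `key: value` text file.
#' @param ... overrides.
#' @return list of class `run_config`.
#' @export
run_config <- function(config_file = NULL, ...) {
  defaults <- list(
    seed = 1L,
    # simulation
    genome_length = 1e6, n_islands = 20L, n_fragments = 50000L,
    mixture_weights = NULL,
    # filters
    min_len = 30L, max_len = 500L, max_region_coverage = 250,
    min_mapq = 30L, cov_outlier = 3,
    # training
    max_iter = 50L, min_cpgs_train = 7L, kl_sample = 10000L,
    kl_tol = 1e-4, kl_rel_tol = 0.01, gmm_max_iter = 10000L,
    # decoding
    prior_weight = 1,
    # deconvolution
    deconv_mode = "deep",
    format_version = 1L)
  cfg <- defaults
  if (!is.null(config_file)) {
    for (ln in readLines(config_file)) {
      ln <- sub("#.*", "", ln)
      if (!grepl(":", ln)) next
      key <- trimws(sub(":.*", "", ln))
      val <- trimws(sub("^[^:]*:", "", ln))
      if (nchar(key) == 0 || nchar(val) == 0) next
      num <- suppressWarnings(as.numeric(val))
      cfg[[key]] <- if (!is.na(num)) num else val
    }
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

log_msg <- function(...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(...)))
}

#' Run the staged pipeline on synthetic data
#'
#' Executes simulate -> feature extraction -> GMM initialization -> Baum-Welch
#' training -> prior-informed Viterbi decoding -> track aggregation ->
#' evaluation -> deconvolution, writing every stage artifact plus a
#' machine-readable JSON run manifest (resolved configuration, seed,
#' convergence diagnostics, artifact checksums) into `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param decode_only optional path to a serialized model ([write_nhmm()]);
#'   skips GMM initialization and training and decodes with the loaded model.
#' @return (invisibly) list with the in-memory results: `model`, `decoded`,
#'   `track`, `evaluation`, `deconvolution`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir, decode_only = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  log_msg("stage simulate: genome + methylomes + fragments (seed %d)", seed)
  scfg <- sim_config(genome_length = as.integer(config$genome_length),
                     n_islands = as.integer(config$n_islands),
                     n_fragments = as.integer(config$n_fragments),
                     seed = seed)
  genome <- simulate_genome(scfg, dir = file.path(out_dir, "sim"))
  methylomes <- simulate_methylomes(scfg, genome)
  wts <- config$mixture_weights
  if (is.null(wts)) {
    wts <- c(0.55, 0.15, 0.1, 0.08, 0.07, 0.05)[seq_along(methylomes$cell_types)]
    wts <- wts / sum(wts)
  }
  sample_meth <- simulate_sample_mixture(scfg, methylomes, wts)
  sim <- simulate_fragments(scfg, genome,
                            list(meth = methylomes$meth, weights = wts),
                            dir = file.path(out_dir, "sim"))

  log_msg("stage features: extract + z-score")
  fcfg <- filter_config(min_len = config$min_len, max_len = config$max_len,
                        max_region_coverage = config$max_region_coverage,
                        min_mapq = config$min_mapq,
                        cov_outlier = config$cov_outlier)
  frags <- extract_fragments(sim$bam, genome$index, fcfg)
  frags <- zscore_features(frags, cov_outlier = config$cov_outlier)
  frags <- attach_truth(frags, sim$truth)
  write_fragment_tsv(frags, file.path(out_dir, "fragments.tsv"))

  if (is.null(decode_only)) {
    log_msg("stage train: GMM initialization + Baum-Welch")
    init <- gmm_initialize(frags, max_iter = as.integer(config$gmm_max_iter),
                           seed = seed)
    model0 <- assign_state_labels(init, frags, mode = "wgs")
    model <- baum_welch(frags, model0,
                        max_iter = as.integer(config$max_iter),
                        min_cpgs_train = as.integer(config$min_cpgs_train),
                        kl_sample = as.integer(config$kl_sample),
                        kl_tol = config$kl_tol,
                        kl_rel_tol = config$kl_rel_tol, seed = seed)
  } else {
    log_msg("stage train: skipped (decode-only, model %s)", decode_only)
    model <- read_nhmm(decode_only)$model
  }
  write_nhmm(model, file.path(out_dir, "model.json"), stats = frags$stats)

  log_msg("stage decode: prior-informed Viterbi")
  prior <- if (config$prior_weight > 0)
    methylation_prior(methylomes$prior, w = config$prior_weight) else NULL
  decoded <- viterbi_decode(frags, model, prior)

  log_msg("stage aggregate: per-CpG track")
  track <- aggregate_track(decoded)
  write_track(track, bedgraph = file.path(out_dir, "track.bedGraph"),
              tsv = file.path(out_dir, "track.tsv"))

  log_msg("stage evaluate: balanced per-CpG auROC")
  evalr <- lapply(c(1L, 3L, 5L), function(mc)
    evaluate_binary(decoded, min_cpgs_per_fragment = mc, seed = seed))
  names(evalr) <- paste0("min_cpgs_", c(1, 3, 5))
  truth_track <- as_cpg_track(data.table(
    chrom = "chr1", pos = genome$index$positions$chr1, level = sample_meth,
    n_total = 1000L))
  corr <- correlate_tracks(track, truth_track,
                           seqlengths = genome$seqlengths)

  log_msg("stage deconvolve: %s mode", config$deconv_mode)
  panel <- build_reference_panel(genome, methylomes)
  wsum <- window_summarize(track, panel$windows)
  dec <- tryCatch(
    deconvolve(panel, wsum, mode = config$deconv_mode),
    error = function(e) { log_msg("deconvolution failed: %s", conditionMessage(e)); NULL })
  if (!is.null(dec))
    fwrite(data.table(cell_type = names(dec$weights), weight = dec$weights,
                      truth = wts),
           file.path(out_dir, "weights.tsv"), sep = "\t")

  arts <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest <- list(
    format_version = config$format_version,
    seed = seed,
    config = unclass(config),
    convergence = list(iterations = model$trained_iterations,
                       converged = model$converged,
                       reason = model$convergence_reason,
                       final_kl = if (length(model$kl_trace)) tail(model$kl_trace, 1) else NA,
                       loglik_trace = model$loglik_trace,
                       kl_trace = model$kl_trace),
    auroc = lapply(evalr, function(e) e$auroc),
    mixture_truth = as.list(setNames(wts, methylomes$cell_types)),
    weights = if (!is.null(dec)) as.list(dec$weights) else NULL,
    checksums = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, sort(arts)))), sort(arts))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(model = model, frags = frags, decoded = decoded,
                 track = track, evaluation = evalr, correlations = corr,
                 deconvolution = dec, manifest = manifest,
                 genome = genome, methylomes = methylomes,
                 mixture_truth = wts))
}
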