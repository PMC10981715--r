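#' Simulation configuration
#'
#' Defines the study conditions for the fully synthetic test-bed: a toy
#' genome with CpG-dense islands in a CpG-poor open sea, cell-type
#' methylomes with marker islands, and cfDNA fragments whose length,
#' placement, and regional coverage are coupled to the underlying
#' methylation state. Methylated DNA is modeled as nucleosome-bound:
#' mono-nucleosomal fragment lengths and CpGs drawn farther from the
#' fragment center; unmethylated (open-chromatin, island) DNA yields shorter
#' fragments, higher local coverage, and CpGs nearer the center.
#'
#' @param genome_length toy genome length in bp (single chromosome "chr1").
#' @param n_islands number of CpG islands, evenly spaced.
#' @param island_length island width (bp).
#' @param island_cpg_density,open_sea_cpg_density probability of starting a
#'   CpG at each emission step inside/outside islands.
#' @param cell_types reference cell-type names; all but the last are treated
#'   as blood cell types when building the prior.
#' @param meth_island,meth_open_sea,meth_marker per-CpG methylation
#'   probability in islands, open sea, and a cell type's own marker islands.
#' @param n_fragments fragments per simulated sample.
#' @param frag_len_meth,frag_len_unmeth mean/sd (bp) of fragment length for
#'   methylated (mono-nucleosomal) and unmethylated anchors.
#' @param d2c_meth,d2c_unmeth mean/sd (bp) of the anchor CpG's distance to
#'   the fragment center by anchor state.
#' @param island_coverage_mult relative fragment sampling intensity of
#'   island CpGs versus open sea, on top of the methylation coupling.
#' @param open_coverage_boost methylation coupling of fragment release: a
#'   site with methylation probability p is sampled with intensity
#'   `1 + open_coverage_boost * (1 - p)`, so nucleosome-depleted
#'   (unmethylated) loci shed proportionally more fragments.
#' @param noise_scale multiplier on all feature standard deviations.
#' @param read_length read length used when emitting alignments.
#' @param seed mandatory RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6L, n_islands = 20L,
                       island_length = 1000L, island_cpg_density = 0.15,
                       open_sea_cpg_density = 0.008,
                       cell_types = c("Neutrophil", "Bcell", "Tcell",
                                      "Macrophage", "Erythroblast",
                                      "Hepatocyte"),
                       meth_island = 0.05, meth_open_sea = 0.9,
                       meth_marker = 0.85, n_fragments = 50000L,
                       frag_len_meth = c(167, 20), frag_len_unmeth = c(110, 30),
                       d2c_meth = c(45, 15), d2c_unmeth = c(15, 10),
                       island_coverage_mult = 1, open_coverage_boost = 0,
                       noise_scale = 1,
                       read_length = 50L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  probs <- c(island_cpg_density, open_sea_cpg_density, meth_island,
             meth_open_sea, meth_marker)
  stopifnot(all(probs >= 0 & probs <= 1), n_fragments >= 0,
            noise_scale >= 0, island_coverage_mult > 0)
  gap <- floor(genome_length / (n_islands + 1))
  if (n_islands > 0 && gap <= island_length)
    stop("island layout exceeds genome length")
  structure(as.list(environment()), class = "sim_config")
}

# CpG placement by a sequential emission process: at each step place "CG"
# (consuming 2 bp) with probability p, else one non-CG base (1 bp). The
# number of CpGs in a segment is Binomial(n_steps, p).
segment_cpg_offsets <- function(seg_len, p) {
  if (seg_len < 2 || p <= 0) return(integer(0))
  draws <- runif(seg_len) < p
  width <- ifelse(draws, 2L, 1L)
  cum <- cumsum(width)
  n_take <- findInterval(seg_len, cum) # decisions fully inside segment
  if (n_take < 1) return(integer(0))
  starts <- c(0L, cum[-length(cum)])[seq_len(n_take)]
  starts[draws[seq_len(n_take)] & (starts + 2L <= seg_len)]
}

#' Simulate the toy genome
#'
#' Generates a deterministic (seeded) genome with CpG-dense islands and a
#' CpG-poor open sea; CG dinucleotides occur only where the placement
#' process put them. Island and promoter annotations are returned and
#' optionally written as FASTA + BED.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory for `genome.fa` (+ `.fai`),
#'   `cgi.bed`, `promoters.bed`.
#' @return object of class `sim_genome`: `seqs` (DNAStringSet), `index`
#'   (a `cpg_index`), `cgi`, `promoters` (data.tables), `cpg_region`
#'   (factor "island"/"sea" per indexed CpG), `paths`.
#' @export
simulate_genome <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- as.integer(cfg$genome_length)
  gap <- floor(L / (cfg$n_islands + 1))
  # island starts aligned to 1 kb boundaries so fixed tilings yield pure
  # island and pure open-sea windows
  isl_start <- if (cfg$n_islands > 0)
    as.integer((seq_len(cfg$n_islands) * gap) %/% 1000L * 1000L) else integer(0)
  cgi <- data.table(chrom = "chr1", start = isl_start,
                    end = isl_start + as.integer(cfg$island_length))
  if (nrow(cgi) > 0 && max(cgi$end) > L)
    stop("island layout exceeds genome length")

  # per-segment CpG placement
  seg_bounds <- sort(unique(c(0L, cgi$start, cgi$end, L)))
  cpg_pos <- integer(0); cpg_isl <- logical(0)
  for (i in seq_len(length(seg_bounds) - 1)) {
    a <- seg_bounds[i]; b <- seg_bounds[i + 1]
    in_island <- nrow(cgi) > 0 && any(a >= cgi$start & b <= cgi$end)
    p <- if (in_island) cfg$island_cpg_density else cfg$open_sea_cpg_density
    off <- segment_cpg_offsets(b - a, p)
    cpg_pos <- c(cpg_pos, a + off)
    cpg_isl <- c(cpg_isl, rep(in_island, length(off)))
  }
  # fill non-CpG positions with random bases, then scrub accidental CGs
  s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  s[cpg_pos + 1L] <- "C"; s[cpg_pos + 2L] <- "G"
  acc <- which(s[-L] == "C" & s[-1L] == "G")       # 1-based C positions
  acc <- setdiff(acc, cpg_pos + 1L)
  while (length(acc) > 0) {
    s[acc + 1L] <- "A"                              # G -> A cannot create CG
    acc <- setdiff(which(s[-L] == "C" & s[-1L] == "G"), cpg_pos + 1L)
  }
  seqs <- Biostrings::DNAStringSet(paste(s, collapse = ""))
  names(seqs) <- "chr1"
  index <- build_cpg_index(seqs)
  stopifnot(identical(index$positions$chr1, as.integer(cpg_pos)))

  promoters <- if (nrow(cgi) > 0) data.table(
    chrom = "chr1",
    start = pmax(cgi$start - 500L, 0L), end = pmin(cgi$start + 500L, L),
    pos = cgi$start,
    strand = rep(c("+", "-"), length.out = nrow(cgi))) else
    data.table(chrom = character(), start = integer(), end = integer(),
               pos = integer(), strand = character())

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(seqs, fa)
    Rsamtools::indexFa(fa)
    fwrite(cgi, file.path(dir, "cgi.bed"), sep = "\t", col.names = FALSE)
    fwrite(promoters, file.path(dir, "promoters.bed"), sep = "\t",
           col.names = FALSE)
    paths <- list(fasta = fa, cgi = file.path(dir, "cgi.bed"),
                  promoters = file.path(dir, "promoters.bed"))
  }
  structure(list(seqs = seqs, index = index, cgi = cgi,
                 promoters = promoters,
                 cpg_region = factor(ifelse(cpg_isl, "island", "sea")),
                 seqlengths = setNames(L, "chr1"), paths = paths),
            class = "sim_genome")
}

#' Simulate reference cell-type methylomes and the blood prior
#'
#' Every cell type shares the canonical landscape (methylated open sea,
#' unmethylated islands) but each island is a marker for one cell type, in
#' which it is methylated instead. The methylation prior is the mean of the
#' blood cell types (all but the last configured type).
#'
#' @param cfg a [sim_config()].
#' @param genome a [simulate_genome()] result.
#' @return list: `meth` (CpG x cell-type probability matrix), `prior`
#'   (data.table chrom/pos/k), `marker_island` (cell-type index per island),
#'   `cell_types`.
#' @export
simulate_methylomes <- function(cfg, genome) {
  pos <- genome$index$positions$chr1
  n <- length(pos)
  cts <- cfg$cell_types
  base <- ifelse(genome$cpg_region == "island", cfg$meth_island,
                 cfg$meth_open_sea)
  meth <- matrix(base, n, length(cts), dimnames = list(NULL, cts))
  marker <- integer(0)
  if (nrow(genome$cgi) > 0) {
    marker <- ((seq_len(nrow(genome$cgi)) - 1L) %% length(cts)) + 1L
    for (j in seq_len(nrow(genome$cgi))) {
      in_isl <- pos >= genome$cgi$start[j] & pos < genome$cgi$end[j]
      meth[in_isl, marker[j]] <- cfg$meth_marker
    }
  }
  blood <- head(cts, -1)
  prior <- data.table(chrom = "chr1", pos = pos,
                      k = rowMeans(meth[, blood, drop = FALSE]))
  list(meth = meth, prior = prior, marker_island = marker, cell_types = cts)
}

#' Mix cell-type methylomes into a sample methylome
#'
#' @param cfg a [sim_config()].
#' @param methylomes a [simulate_methylomes()] result.
#' @param weights non-negative mixture weights summing to one, one per cell
#'   type.
#' @return per-CpG methylation probability vector.
#' @export
simulate_sample_mixture <- function(cfg, methylomes, weights) {
  if (length(weights) != ncol(methylomes$meth))
    stop("weight length must match the number of cell types")
  if (abs(sum(weights) - 1) > 1e-8) stop("mixture weights must sum to 1")
  as.vector(methylomes$meth %*% weights)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate cfDNA fragments as an aligned, indexed BAM plus truth TSV
#'
#' Fragments are anchored at CpG sites (island sites oversampled by
#' `island_coverage_mult`); the anchor's methylation state drives the
#' fragment length and the anchor's displacement from the fragment center
#' (methylated: longer fragments, CpG farther from center). Other CpGs
#' falling inside the fragment take states drawn from the sample methylome.
#' Reads are emitted as a coordinate-sorted, indexed BAM whose sequences
#' come from the toy genome, with flags/MAPQ passing the default filters;
#' `decoys` injects known filter violations for testing.
#'
#' Each fragment descends from a single cell: a cell type is drawn from the
#' mixture weights, and the fragment's CpG states follow that cell's
#' methylome with a shared fragment-level quantile (comonotone coupling), so
#' CpGs with equal methylation probability are coherently methylated or
#' unmethylated on the same molecule, while the per-CpG marginal probability
#' still equals the methylome value.
#'
#' @param cfg a [sim_config()].
#' @param genome a [simulate_genome()] result.
#' @param sample_methylome either a per-CpG methylation probability vector
#'   (single methylome), or a list with `meth` (CpG x cell-type matrix) and
#'   `weights` (mixture proportions) for a mixed cfDNA sample.
#' @param dir output directory.
#' @param n_fragments overrides `cfg$n_fragments`.
#' @param seed overrides `cfg$seed`.
#' @param decoys named integer vector with any of `short`, `long`,
#'   `low_mapq`, `duplicate`, `improper`, `blacklist`, `pileup`; `blacklist`
#'   decoys are placed inside `blacklist_region` (chrom,start,end list), and
#'   `pileup` emits that many identical stacked fragments at one CpG.
#' @param blacklist_region interval used for blacklist decoys.
#' @param prefix file name prefix (default "sample").
#' @return list: `bam`, `truth` (TSV path), `fragments` (data.table with the
#'   generated truth), `n_decoys`.
#' @export
simulate_fragments <- function(cfg, genome, sample_methylome, dir,
                               n_fragments = NULL, seed = NULL,
                               decoys = NULL, blacklist_region = NULL,
                               prefix = "sample") {
  stopifnot(inherits(cfg, "sim_config"), inherits(genome, "sim_genome"))
  n_frag <- if (is.null(n_fragments)) cfg$n_fragments else n_fragments
  if (n_frag <= 0) stop("zero fragments configured")
  set.seed(if (is.null(seed)) cfg$seed + 1L else seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pos <- genome$index$positions$chr1
  L <- as.integer(genome$seqlengths[["chr1"]])
  if (is.list(sample_methylome)) {
    meth <- sample_methylome$meth
    mix <- sample_methylome$weights
    stopifnot(nrow(meth) == length(pos), length(mix) == ncol(meth),
              abs(sum(mix) - 1) < 1e-8)
  } else {
    meth <- matrix(sample_methylome, ncol = 1)
    mix <- 1
    stopifnot(nrow(meth) == length(pos))
  }
  cell <- sample.int(ncol(meth), n_frag, replace = TRUE, prob = mix)
  uq <- runif(n_frag)                                # fragment epiallele quantile

  # anchor sampling: uniform per bp (not per CpG) so island coverage exceeds
  # open sea by island_coverage_mult, not by the CpG density ratio
  is_isl <- genome$cpg_region == "island"
  isl_bp <- sum(genome$cgi$end - genome$cgi$start)
  dens_isl <- if (isl_bp > 0) max(sum(is_isl), 1) / isl_bp else 1
  dens_sea <- max(sum(!is_isl), 1) / max(L - isl_bp, 1)
  wts <- ifelse(is_isl, cfg$island_coverage_mult / dens_isl, 1 / dens_sea)
  pm_site <- as.vector(meth %*% mix)        # site-level mixture methylation
  wts <- wts * (1 + cfg$open_coverage_boost * (1 - pm_site))
  anchor <- sample.int(length(pos), n_frag, replace = TRUE, prob = wts)
  a_state <- as.integer(uq < meth[cbind(anchor, cell)])   # 1 = M
  ns <- cfg$noise_scale
  len <- ifelse(a_state == 1L,
                rnorm(n_frag, cfg$frag_len_meth[1], cfg$frag_len_meth[2] * ns),
                rnorm(n_frag, cfg$frag_len_unmeth[1], cfg$frag_len_unmeth[2] * ns))
  len <- as.integer(clamp(round(len), 30L, 500L))
  d2c <- ifelse(a_state == 1L,
                rnorm(n_frag, cfg$d2c_meth[1], cfg$d2c_meth[2] * ns),
                rnorm(n_frag, cfg$d2c_unmeth[1], cfg$d2c_unmeth[2] * ns))
  d2c <- clamp(abs(d2c), 0, len / 2 - 2)
  sgn <- sample(c(-1, 1), n_frag, replace = TRUE)
  center <- pos[anchor] + 1 + sgn * d2c              # +1: center near the CpG
  start <- as.integer(round(center - len / 2))
  start <- clamp(start, 0L, L - len)
  end <- start + len

  frag <- data.table(frag_id = seq_len(n_frag), chrom = "chr1",
                     start = start, end = end, anchor = anchor,
                     a_state = a_state, cell = cell, uq = uq)
  # coherent per-fragment CpG states: shared quantile against the
  # cell-of-origin methylome
  lo <- findInterval(frag$start - 1L, pos) + 1L
  hi <- findInterval(frag$end - 2L, pos)
  n_each <- pmax(hi - lo + 1L, 0L)
  keep <- n_each > 0L
  frag <- frag[keep]; lo <- lo[keep]; n_each <- n_each[keep]
  idx <- sequence(n_each) - 1L + rep(lo, n_each)
  fo <- data.table(frag_id = rep(frag$frag_id, n_each), cpg = idx,
                   cell = rep(frag$cell, n_each), uq = rep(frag$uq, n_each))
  fo[, state := as.integer(uq < meth[cbind(cpg, cell)])]
  truth_str <- fo[, .(states = paste(c("U", "M")[state + 1L], collapse = "")),
                  by = frag_id]
  frag <- merge(frag, truth_str, by = "frag_id")

  # reads
  rl <- as.integer(cfg$read_length)
  recs <- sam_records(frag$chrom, frag$start, frag$end,
                      sprintf("frag%07d", frag$frag_id), genome$seqs,
                      rl, mapq = 60L, proper = TRUE, dup = FALSE)

  n_decoys <- 0L
  if (!is.null(decoys)) {
    dk <- make_decoys(decoys, genome, blacklist_region, rl)
    recs <- rbind(recs, dk$recs)
    n_decoys <- dk$n
  }
  setorder(recs, chrom, pos, qname, flag)

  sam <- file.path(dir, paste0(prefix, ".sam"))
  bam0 <- file.path(dir, prefix)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome$seqlengths),
                      genome$seqlengths))
  writeLines(c(header, recs[, paste(qname, flag, chrom, pos, mapq, cigar,
                                    "=", pnext, tlen, seq, qual,
                                    sep = "\t")]), sam)
  bam <- Rsamtools::asBam(sam, bam0, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)

  truth_path <- file.path(dir, paste0(prefix, ".truth.tsv"))
  fwrite(frag[, .(chrom, start, end, states)], truth_path, sep = "\t")
  list(bam = bam, truth = truth_path,
       fragments = frag[, .(frag_id, chrom, start, end, states)],
       n_decoys = n_decoys)
}

# build paired SAM records (two rows per fragment), sequences taken from the
# reference so the BAM is self-consistent with the FASTA
sam_records <- function(chrom, start, end, qname, seqs, rl, mapq = 60L,
                        proper = TRUE, dup = FALSE) {
  chrom <- rep(chrom, length.out = length(start))
  len <- end - start
  rl1 <- pmin(rl, len)
  f1 <- 0x1 + 0x20 + 0x40 + (if (proper) 0x2 else 0) + (if (dup) 0x400 else 0)
  f2 <- 0x1 + 0x10 + 0x80 + (if (proper) 0x2 else 0) + (if (dup) 0x400 else 0)
  p1 <- start + 1L                       # SAM is 1-based
  p2 <- end - rl1 + 1L
  sq <- function(p, w, ch) {
    vapply(seq_along(p), function(i)
      as.character(Biostrings::subseq(seqs[[ch[i]]], p[i], p[i] + w[i] - 1L)),
      "")
  }
  s1 <- sq(p1, rl1, chrom); s2 <- sq(p2, rl1, chrom)
  qual <- vapply(rl1, function(w) paste(rep("I", w), collapse = ""), "")
  cig <- sprintf("%dM", rl1)
  rbind(
    data.table(qname = qname, flag = f1, chrom = chrom, pos = p1, mapq = mapq,
               cigar = cig, pnext = p2, tlen = len, seq = s1, qual = qual),
    data.table(qname = qname, flag = f2, chrom = chrom, pos = p2, mapq = mapq,
               cigar = cig, pnext = p1, tlen = -len, seq = s2, qual = qual))
}

make_decoys <- function(decoys, genome, blacklist_region, rl) {
  pos <- genome$index$positions$chr1
  L <- as.integer(genome$seqlengths[["chr1"]])
  seqs <- genome$seqs
  mid_cpg <- pos[length(pos) %/% 2]
  recs <- list(); n <- 0L
  get <- function(nm) if (nm %in% names(decoys)) as.integer(decoys[[nm]]) else 0L
  place <- function(count, len, mapq = 60L, proper = TRUE, dup = FALSE,
                    at = NULL, tag = "decoy") {
    if (count == 0L) return(NULL)
    st <- if (is.null(at)) {
      ctr <- pos[sample.int(length(pos), count, replace = TRUE)]
      as.integer(clamp(ctr - len %/% 2L, 0L, L - len))
    } else rep(as.integer(at), count)
    sam_records("chr1", st, st + as.integer(len),
                sprintf("%s%04d", tag, seq_len(count)), seqs,
                rl, mapq = mapq, proper = proper, dup = dup)
  }
  add <- function(r, k) { if (!is.null(r)) { recs[[length(recs) + 1L]] <<- r; n <<- n + k } }
  add(place(get("short"), 20L, tag = "dshort"), get("short"))
  add(place(get("long"), 520L, tag = "dlong"), get("long"))
  add(place(get("low_mapq"), 160L, mapq = 10L, tag = "dmapq"), get("low_mapq"))
  add(place(get("duplicate"), 160L, dup = TRUE, tag = "ddup"), get("duplicate"))
  add(place(get("improper"), 160L, proper = FALSE, tag = "dimp"), get("improper"))
  if (get("blacklist") > 0L) {
    if (is.null(blacklist_region)) stop("blacklist decoys need blacklist_region")
    at <- as.integer((blacklist_region$start + blacklist_region$end) / 2) - 80L
    add(place(get("blacklist"), 160L, at = at, tag = "dblk"), get("blacklist"))
  }
  if (get("pileup") > 0L)
    add(place(get("pileup"), 160L, at = clamp(mid_cpg - 80L, 0L, L - 160L),
              tag = "dpile"), get("pileup"))
  list(recs = rbindlist(recs), n = n)
}
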