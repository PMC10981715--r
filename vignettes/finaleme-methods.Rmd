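---
title: "Methylation from cfDNA fragmentation: model, assumptions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation from cfDNA fragmentation: model, assumptions, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the statistical model the package implements, the
choices made where the design was genuinely open, what the synthetic data
generator does and does not emulate, and the known limitations. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The model

Plasma cfDNA is fragmented by nucleases around nucleosomes. Because DNA
methylation and nucleosome organization are coupled, the geometry of the
fragments carries methylation information: methylated DNA tends toward
compact mono-nucleosomal fragments whose CpGs sit away from the fragment
center, while unmethylated CpG-island DNA is open chromatin that sheds
shorter fragments. The package models, for every CpG on every fragment,
the feature triple

* fragment length (bp),
* normalized coverage at the CpG position (fragments per million),
* absolute distance from the CpG to the fragment center (bp),

each z-scored against the mean and standard deviation of all retained
observations in the same sample, with the coverage z-score clipped to
±3 (`cov_outlier`, guarding against pile-up artifacts).

A two-state hidden Markov chain (U/M) runs along the CpGs of each
fragment. CpG spacing is extremely uneven (islands ~10 bp, open sea
hundreds of bp), so a homogeneous chain would either oversmooth the open
sea or undersmooth islands. The model is therefore *non-homogeneous*:

* the initiation distribution is estimated separately per bin of the
  first CpG's offset from the fragment start (default upper edges 25, 50,
  75, 100, 150, ∞ bp);
* the transition matrix is estimated separately per bin of the distance
  to the previous CpG (default upper edges 10, 20, 50, 100, 200, 500, ∞
  bp — resolving island vs open-sea spacing while keeping per-bin counts
  usable). Bin edges are upper-inclusive and configurable.

Emissions are conditionally independent across the three features given
the state; each state-feature density is a two-component Gaussian mixture
(weight π, means, variances in z units). Two components absorb the
multi-modality of real feature distributions (e.g. mono- vs
di-nucleosomal lengths) without committing to more hidden states.

### Estimation

1. **Initialization.** A two-component diagonal-covariance Gaussian
   mixture is fitted to all observation triples by EM (up to 10,000
   iterations, seeded restarts if a component empties) and observations
   are hard-assigned. Initiation and transition probabilities are counted
   within bins from the assignments with pseudocount 1; each state-feature
   mixture is initialized from the assigned observations (quantile split
   at the 20th/80th percentiles, then a short weighted-EM refinement).
2. **Labeling.** In WGS mode the component with the larger mean
   z-scored distance-to-center becomes M — the nucleosome-protection
   signature; with fragment-level ground truth (bisulfite mode) the
   component with the higher mean truth methylation becomes M. Exact ties
   fall back to mean fragment length (longer → M).
3. **Baum-Welch.** EM over all fragments with ≥ 7 CpGs
   (`min_cpgs_train`), at most 50 iterations. The E-step is the standard
   forward-backward recursion in log space, *without* the methylation
   prior. The M-step re-estimates binned initiation/transition
   probabilities from expected counts (pseudocount 1) and applies three
   inner responsibility-weighted EM updates to each state-feature mixture
   (a generalized EM step; the training log-likelihood is still
   monotone). Mixture variances are floored at 0.01 z² — see *Numerical
   choices*.
4. **Convergence.** After each iteration the sampled Kullback-Leibler
   statistic is computed on a fixed, seeded sample of up to 10,000
   fragments with ≥ 5 CpGs: `D = |mean_f (logL_new(f) − logL_old(f)) /
   n_cpg(f)|`, a per-CpG-normalized, symmetrized Juang-Rabiner
   approximation (the two directions' contributions coincide in absolute
   value on a common sample). Training stops when `D < 1e-4` or when `D`
   changes by less than 1% relative to the previous iteration (the run
   manifest records which criterion fired). The exact form of the
   divergence and its normalization are this package's own choice; `D = 0`
   holds exactly for identical models.

### Decoding with the methylation prior

Most CpGs in a genome have a strongly predictable methylation baseline
(islands low, open sea high). At decoding — and only there — a per-CpG
prior `k` (typically from healthy blood bisulfite data; the generator's
blood-average track in the synthetic study) converts the emission
likelihoods into posteriors

`Pr(M | e) = L_m k' / (L_m k' + L_u (1 − k'))`, with `k' = w·k + (1−w)/2`.

The prior weight `w` defaults to 1 (pure prior); `w = 0` provably makes
decode results independent of the prior track. Unlisted CpGs receive the
track's genome-wide mean. Viterbi paths and forward-backward posteriors
use these prior-adjusted terms in log space; there is no minimum CpG
count at decoding. Viterbi ties break toward the previous CpG's state
(first CpG and terminal ties toward M) so decodes are deterministic.

A trained model serializes to versioned JSON, including the feature
z-scoring statistics, so a model trained on one high-coverage sample can
be applied decode-only to shallow samples.

### Downstream

Viterbi calls are aggregated per reference CpG into methylated/total
counts and a continuous level; tracks are summarized over windows (pooled
counts), compared with truth tracks (balanced per-CpG ROC; Pearson and
Spearman at coverage strata and 1 kb windows), profiled around oriented
anchors, and tested for group differences per window with the two-sided
Wilcoxon rank-sum test (exact for group sizes ≤ 10 without ties; normal
approximation with tie-corrected variance and *no* continuity correction
otherwise — with the correction the attainable level at small cut-offs
falls measurably below nominal, which would bias the sparse-data DMR
screen conservative). Raw p < 0.01 flags windows, following the
sparse-data procedure; Benjamini-Hochberg q-values are reported alongside
for transparency.

Tissue-of-origin deconvolution models the sample's binarized window
vector as `A w` with `w` a probability vector, solved as a quadratic
program (`quadprog`; a 1e-8 ridge keeps the Gram matrix positive definite
when cell types are collinear — the duplicated-type split is then
non-identifiable but its sum is preserved). Deep mode: windows need ≥ 10
informative calls in every reference, are ranked by across-cell-type
variance of the real-valued density (the variability statistic is this
package's choice; ranking happens after the coverage filter), the top 1%
(floor of 10 windows) retained, then both sides binarized (density < 0.1
→ 0, else 1, strict less-than). Ultra-low-pass mode: entries with < 5
informative calls become NA, windows > 80% missing across the panel are
dropped (a sample > 80% missing is rejected), the top 25% most variable
windows are kept, and remaining gaps are imputed by k-nearest-neighbor
over windows (k = 5, Euclidean distance on pairwise-complete entries,
ties broken by window order, panel and sample imputed jointly) before
binarization. A `binarize = FALSE` diagnostic mode retains real-valued
densities for solver validation.

## The synthetic data generator

The generator exists so that every stage is testable with no external
data. It emulates:

* a toy genome (default 1 Mb, one chromosome) with CpG-dense islands in
  a CpG-poor open sea. CpGs are placed by a sequential emission process
  (place "CG" with probability p per step), so realized island CpG counts
  are exactly binomial and accidental CG dinucleotides are scrubbed.
  Island starts are aligned to 1 kb boundaries so fixed tilings contain
  pure island and pure open-sea windows — this keeps window-level tests
  interpretable, at the cost of unrealistic tidiness;
* cell-type methylomes sharing the canonical landscape (islands ~0.05,
  open sea ~0.9) with each island a *marker*, methylated (~0.85) in
  exactly one cell type — the discriminative structure deconvolution
  needs. The prior track is the blood-type average;
* cfDNA fragments, each descending from one cell of origin: a cell type
  is drawn from the mixture weights and all CpGs of the fragment share
  one methylation quantile (comonotone coupling), so molecules are
  epigenetically coherent while per-CpG marginals equal the methylome;
* state-coupled fragment geometry: methylated anchors draw
  mono-nucleosomal lengths (167 ± 20 bp) and larger center displacements
  (N(45, 15) bp); unmethylated anchors draw open-chromatin lengths
  (110 ± 30 bp — deliberately sub-nucleosomal, as open-chromatin CGI
  cfDNA fragments are markedly short) and small displacements
  (N(15, 10) bp). Fragment release is uniform per bp (anchor CpGs are
  weighted inversely by regional CpG density so coverage is not a CpG
  density artifact), with an optional regional multiplier and an optional
  methylation-coupled release boost (default off);
* alignment output: proper read pairs with reference-derived sequences,
  MAPQ 60, emitted as a coordinate-sorted, indexed BAM, plus a truth TSV
  of per-fragment CpG states. Decoy records violating each quality filter
  (length bounds, MAPQ, duplicates, improper pairs, exclusion-list
  overlap, > 250× pile-ups) can be injected in known numbers.

These defaults were fixed once so that the default pipeline sits at the
intended operating point — balanced per-CpG auROC ≥ 0.90 for fragments
with ≥ 5 CpGs, increasing from the 1- to the 3- to the 5-CpG threshold —
and were not revisited afterwards.

What the generator does **not** emulate — and hence what passing tests do
not show about real plasma: sequencing errors and mappability artifacts;
GC bias; jagged fragment ends; strand-resolved or hemimethylation;
di-nucleosomal and longer fragment modes; realistic between-individual
variation in the prior; genome-scale CpG density heterogeneity. Results
on synthetic data bound what the implementation can do under its own
assumptions, not clinical performance.

## Numerical choices

* All chain recursions run in log space with log-sum-exp; emission
  densities and the dynamic programs are implemented in C++ for the
  per-fragment scale of real samples.
* Mixture variances are floored at 0.01 z² (sd 0.1). At desk-scale depth
  the coverage feature is discrete (integer pile-ups), and with a looser
  floor a mixture component can collapse onto a single coverage value,
  producing near-infinite-confidence emissions that are immune to the
  methylation prior; the floor caps any single atom's log-likelihood
  advantage.
* Transition/initiation pseudocount 1 keeps empty bins stochastic.
* The standard-deviation floor in z-scoring is 1e-6 on the raw scale
  (degenerate fixtures only).
* The 250× coverage cap is evaluated per position on the coverage of
  fragments that already passed the quality, length, and exclusion-list
  filters; a fragment is dropped if *any* overlapped position exceeds the
  cap. The fragments-per-million denominator counts all quality-passing
  fragments regardless of CpG content.
* CpGs count as on a fragment when the full dinucleotide lies inside the
  fragment interval (0-based half-open coordinates throughout; the CpG is
  identified by its forward-strand C position, strand-collapsed).
* Truth records are matched to fragments by coordinates; distinct
  molecules at identical coordinates are indistinguishable there, so
  duplicate truth records collapse to the first (a < 1% effect at the
  simulated depths).

## Validation design and problem sizes

The test suite checks each operation against an independent oracle:
enumeration over all 2^L state paths for likelihoods and Viterbi (500
random fragments, random parameter sets), a directly coded mixture
density, exact rank-sum enumeration (the 4-vs-4 worked example,
p = 2/C(8,4)), an exhaustive active-set solver for the simplex QP, and
hand-built fixtures for filters, windows, profiles, and imputation.
Properties are tested at these sizes: EM monotonicity over the full
50-iteration run on 5,000 fragments; parameter recovery (transitions
within ±0.05 per bin, emission component means within ±0.1 z, up to label
symmetry) on 20,000 fragments from a known model; the classification
operating point on 30,000 fragments over a 600 kb toy genome; null DMR
calibration on 10,000 windows with 40-sample groups; and byte-level
determinism of the whole pipeline under a fixed seed. `scripts/acceptance.R`
recomputes the headline quantities at the same sizes.

## Known limitations

* Aggregated methylation levels are length-biased: methylated fragments
  are longer and contribute proportionally more CpG calls, inflating
  levels wherever methylation and length are coupled. The effect is
  systematic and does not shrink with depth.
* Hard Viterbi calls flip whole fragments whose length falls in the U/M
  overlap region; on islands this puts a false-positive floor on decoded
  densities. Together with epiallele sampling noise (all CpGs of a
  molecule share one draw, so window densities have fragment-limited, not
  call-limited, precision), this makes full-chain tissue-fraction
  estimates coarse: the dominant component is recovered reliably, minor
  fractions are not. The acceptance report separates the decode
  contribution by re-running the chain on true fragment states.
* The exact distance-bin edges of the original Java implementation are
  unpublished; defaults here are configurable to allow matching later.
* The relative-change convergence rule compares against the previous
  iteration's divergence (not the first iteration's), and the KL formula
  itself is this package's documented approximation, not a reconstruction
  of the original's.
* Two hidden states only; non-CpG methylation and hemimethylation are out
  of scope.
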