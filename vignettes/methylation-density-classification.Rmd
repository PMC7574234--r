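---
title: "Methylation-density classification: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-density classification: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiclassr)
```

## The model

The unit of analysis is the epiallele: one sequenced DNA molecule at a
locus, summarized by its methylation density `MD = n_meth / n_cpgs`. A
sample is a tally of epialleles keyed by `(n_meth, n_cpgs)` — the
`density_table`, the interchange object every module produces or consumes.

Classification uses two thresholds applied in sequence. A fragment *passes*
when its density is at or above `MD_min`; a sample is *positive* when the
amount of passing fragments — the epiallelic fraction `EF` — is at least
`EF_min`. Three EF measures are supported and must be chosen explicitly
(never inferred from the data):

* `fraction` — CpG-weighted: `C / C_tot`, CpGs covered by passing reads over
  all CpGs. This corrects for unequal read lengths; when every read covers
  the same number of CpGs it coincides with the read-count fraction.
* `per_ml_count` — passing fragments per mL of plasma assessed (melt-assay
  data, where absolute abundance matters).
* `normalized_read_count` — passing fragments over total fragments at the
  locus. Used for whole-genome data where per-sample depth varies. The
  denominator of this "normalized count" is not uniquely pinned down by its
  usual description; we use total reads at the marker region and flag this
  as an assumption.

Training searches `MD_min` over a fixed grid (0 to 1 in steps of 0.05,
configurable) crossed with, at each density, the full set of EF values
observed in the training samples, and maximizes Youden's `J = TPR − FPR`
over all cells. Two conventions matter:

* **Strict zero.** At `MD_min = 0` the score counts fragments with density
  strictly above zero. Otherwise the zero column would be the constant 1 and
  carry no information; under the strict rule it becomes the
  mean-methylation-style baseline (for fixed-length amplicons it is exactly
  proportional to mean locus methylation).
* **EF candidates are observed values only**, plus `+Inf`. No interpolation:
  observed values are the only thresholds at which the empirical TPR/FPR
  change, and the `+Inf` row guarantees an FPR = 0 operating point exists.

**Ties are outputs.** The argmax is typically attained on a band of `(MD,
EF)` cells; the full tie set is returned, and the canonical pair is the
smallest MD then the smallest EF among ties. Preferring small MD keeps more
heterogeneously methylated fragments in the positive count, which favors
sensitivity; a user wanting maximal stringency can take the other end of the
band from the tie table.

AUC is computed as the Mann-Whitney U statistic divided by `n1 * n2`, ties
counted one half — the exact probability that a random case outscores a
random control — rather than by trapezoid integration, so it is consistent
at any sample size. Confidence intervals use a stratified bootstrap (cases
and controls resampled independently; 2000 replicates by default; percentile
interval; a seed is a required argument).

Two optimality summaries coexist and are labelled rather than conflated: the
per-density profile reports both the ROC AUC of the score at that density
and the Youden point of its own EF sweep; the global optimum maximizes J
over the whole grid. They can disagree about the best density and both are
reported.

## Numerical choices

* Densities are held as integer pairs `(n_meth, n_cpgs)`; floating densities
  are derived output. Cutoff comparisons are evaluated as
  `n_meth >= md * n_cpgs` with a `1e-9` guard so that grid values without an
  exact binary representation (0.05, 0.6, ...) never flip a read lying
  exactly on the boundary.
* Tie tolerance for "attains the maximum J" is `1e-12`, matched to the exact
  rational arithmetic upstream.
* Region strings are parsed as 1-based fully closed intervals (the genome
  browser convention the strings are written in); internally 0-based
  half-open; BED input is converted accordingly and the conversion is
  tested.
* Read retention is a per-dataset property of the region object:
  `any_overlap` (one aligned base suffices — tag-counting style) or
  `full_containment` (reads entirely inside the region; the default, since
  it guarantees comparable CpG counts across reads). Paired mates are merged
  into one fragment, CpG calls deduplicated by reference position, because
  the molecule, not the sequencing read, is the epiallele. Methylation call
  strings are projected through the CIGAR into reference space, so bases in
  insertions are dropped and deletions contribute nothing; how indels inside
  a CpG should count is not specified anywhere authoritative, and skipping
  unaligned positions is the documented choice.

## The dilution simulator

Spike-ins draw `round(ratio * depth)` reads from the tumor sample's
CpG-weighted density distribution and the rest from the background's, with
replacement. Fixed counts (rather than binomial) make the nominal ratio
exact in every replicate and remove one variance source from an experiment
whose point is the ratio; a binomial mode exists behind `count_mode` for
sensitivity analysis. Each background sample yields one spike-in, paired
with a uniformly drawn tumor sample *with replacement* (there are fewer
tumor sources than backgrounds, so replacement is forced). Controls are the
unmodified background samples. When no depth is given, the smallest of 100 /
1,000 / 10,000 with `depth * ratio >= 1` is used. Per iteration the recorded
"density-cutoff AUC" is the best AUC over the MD grid, against the
mean-locus-methylation AUC; the per-ratio summary is the mean with a
percentile 95% CI over iterations (the iteration count, 50 in the original
design, is a parameter — the acceptance suite uses 25 at depth 10,000 to fit
its time budget). The probability that a cutoff improves on mean methylation
is itself an AUC: the two sets of per-iteration AUCs are compared with the
same U statistic.

## Melt-curve calibration

Input is per-well secondary melt-peak temperature tables — peak calling from
raw fluorescence happens in instrument software and is out of scope.
Calibration matches bisulfite-sequenced amplicon patterns (filtered at 95%
conversion efficiency; exactly 95% is retained, only *less than* the
threshold is discarded) to peak temperatures by rank: patterns sorted by
density then abundance, temperatures sorted descending, paired positionally.
Ordinary least squares then maps temperature to density. Predictions are
clipped to `[0, 1]` and rounded to the nearest multiple of `1 / n_cpgs` (14
CpGs for the ZNF154 amplicon, so one methylated CpG is one step of about
7%); exact half-way cases round up — an arbitrary but deterministic choice
within the measurement's precision. The instrument's 0.2 °C gradient step is
noted but temperatures are carried at full float precision.

Counting assumes at most one methylated molecule per well (quasi-digital
regime). The constructor warns when realized occupancy exceeds 0.3 peaks per
well, and a Poisson correction (scaling counts by
`-n_wells * log(negative fraction)`) is available as a clearly labelled
extension, off by default. Per-mL normalization divides counts by the
assessed plasma volume `(ge_loaded / ge_total) * plasma_ml`. Cutoffs may be
specified in either temperature or density space; the calibration line
converts between them.

## Multi-marker combination

Marker selection from beta matrices applies, in order: an external SNP
blocklist (no annotation is bundled — any probe list is accepted), a ceiling
of 0.2 on the maximum beta across normals, a positive median paired
tumor-minus-normal difference (which is also the ranking key), and overlap
with candidate regions. Repeated 50:50 stratified splits (10 by default) are
materialized from a required seed; per-marker MD cutoffs are learned
strictly inside each training partition (a leakage test asserts that
corrupting test labels changes nothing).

Per-marker scores are combined with a linear-kernel support-vector model.
None of the guaranteed runtime libraries provides an SVM, so the package
fits the L2-regularized squared-hinge linear SVM directly by BFGS on its
smooth, strictly convex objective — deterministic, no random state, `C = 1`
recorded in the model metadata. For ROC purposes only the continuous
decision value matters; with one marker it is a monotone transform of the
raw marker score, which the tests assert. Mean ROC curves across runs use
vertical averaging of step-interpolated TPR on a fixed 101-point FPR grid,
with an SD band; AUC sets are compared with a two-sided rank-sum test.

## The synthetic world

Generators are pure functions of a spec plus a required seed. The cohort
generator draws, per read, a CpG count (fixed 14, amplicon-like; or uniform
4–20, RRBS-like), a latent density from a three-part mixture — point mass at
0 (weight 0.9), low Beta(1, 19) noise (mean 0.05), and in cases with
probability `f` a high Beta(8.5, 1.5) tumor component (mean 0.85) — and then
`n_meth ~ Binomial(n_cpgs, d)`. These defaults are the stated world: a
dominant unmethylated background with low-density noise in everyone, and
rare densely methylated fragments only in cases; `f = 0.01` by default. They
were chosen once to match that qualitative structure and are not tuned
against test outcomes.

What the generator does *not* emulate: fragment-length and positional
structure, strand asymmetries, bisulfite conversion failure at base level
(only a global efficiency knob on sequenced patterns), batch effects, and
correlated methylation between neighbouring CpGs within a read (the binomial
draw treats sites independently, which understates the bimodality of real
single-molecule patterns). A green dilution test therefore establishes that
the classifier exploits density separation when it exists at the stated
mixture shapes — not that any particular clinical sensitivity would be
achieved; the published cohort figures depend on controlled-access data and
are shipped only as presets.

## Limitations

* The WGBS-style normalized read count divides by total region reads; if the
  original denominator was different (e.g. all mapped reads), absolute EF
  cutoffs are not transferable, though ROC/AUC results are unaffected within
  a cohort (rank-invariant).
* The melt pipeline counts one molecule per secondary peak; saturated plates
  undercount unless the Poisson correction is enabled.
* Fragment merging trusts mate information in the alignment; single-end
  duplicates of the same molecule are not collapsed (deduplication is
  upstream).
* The exhaustive grid search is O(cells × samples) and intended for
  cohort-scale training data, not genome-wide scans.
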