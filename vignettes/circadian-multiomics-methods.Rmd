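---
title: "Methods: circadian calling, trace metrics and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian calling, trace metrics and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clockworks)
```

This vignette explains the models and conventions behind `clockworks`: why
the rhythm tests are built the way they are, what every tunable parameter
means, what the synthetic-data generators do and do not emulate, and the
numerical choices a maintainer should know about.

## The one-cycle design and why the tests are permutation-based

The proteome time course this package targets has an unusual design: five
circadian timepoints (CT0, 6, 12, 18 and an independently repeated CT24/0)
with three replicates each, covering a single cycle. Slices free-run without
common registration to external time, so consecutive cycles cannot be
stitched together, and with only 15 observations per feature the asymptotic
null distributions packaged with standard rhythm detectors are not a given.
We therefore re-derive the null by permutation: observations are shuffled
across timepoint slots, the max-over-candidates statistic is recomputed for
each arrangement, and the p-value is the tail probability of that max. This
makes the candidate-lag (or candidate-apex) multiplicity part of the null
rather than an afterthought, and the test is exactly valid at any n under
exchangeability. Enumeration is exhaustive when `m! <= exact_bound`
(default 10,000, i.e. up to 7 observations) and Monte-Carlo with a required
seed otherwise (default 10,000 permutations; the analysis scripts use 2,000,
which resolves p = 0.0005 — far below the 0.05 decision threshold).

### JTK-style test

For each lag in `lags_h` (default CT 0/6/12/18) the reference is a cosine of
period `period_h` (default 24) evaluated at each observation's CT folded mod
24, so CT24 observations share the CT0 reference value but remain
independent data points. The statistic is the maximum over lags of Kendall's
tau-b between observations and reference (tau-b handles the heavy reference
ties: a cosine at 5 folded timepoints takes only 3–4 distinct values). Being
rank-based, the test is invariant to any strictly monotone transform of the
data.

### Umbrella test

The second test targets monotone-rise-then-fall alternatives, which are
sensitive to asymmetric waveforms a cosine correlation can miss. For each
candidate apex the cycle is *unfolded at the apex's antipode*: groups are
ordered by circular distance past the antipode, Mann–Whitney counts are
summed over group pairs along the rise (expecting increase) and the fall
(expecting decrease), with ties counting one half and cross-flank pairs not
scored. The unfolding matters: on a circular design a CT0-peaking waveform
is high at both ends of a linear CT axis and fits no linear umbrella — in a
simulation with planted cosines, a linear umbrella recovered none of the
CT0-peaking features while the unfolded version recovers all phases equally.
Each apex's statistic is scaled to its concordance fraction (null
expectation 0.5 for every apex) so the max over apexes compares like with
like; we deliberately avoid studentizing against the empirical permutation
ensemble, which would make the statistic itself ensemble-dependent and
inflate the Monte-Carlo variance of the p-value beyond binomial.

### The dual criterion

A feature is circadian iff both tests give p < `alpha` (default 0.05), with
no across-feature multiplicity correction — the intersection of two
conservative tests is the multiplicity control in this design. The
acceptance suite verifies the operating characteristics under the study
conditions: on a null table of 1,000 features the dual call rate is ~0.02–
0.03, and with 10% planted rhythmic features at amplitude = 4 × noise SD
sensitivity is 1.0.

## Quantification filter

A protein is quantified iff every timepoint has at least two of three
replicate ratios; the decision uses only the missingness mask, never the
values, and the filter is idempotent. Ratios must be positive (they are
log2-transformed after filtering); a non-positive cell is an error naming
the offending feature and column. Labeling efficiency is reported as the
bounded fraction heavy/(heavy+light), with the literal heavy/light ratio
alongside, because the two conventions circulate and only the fraction is
bounded by 1.

## Cell-type analyses

Conventions chosen where upstream tools defer to defaults:

- a cell *expresses* a gene iff its raw count exceeds `min_count`
  (default 0), read from the counts layer;
- cluster annotation scores a type as the mean over its markers of the
  cluster's z-scored mean expression (z across clusters); argmax wins, and
  a tie or a non-positive top score yields `"unclassified"`;
- log2 fold changes use means with pseudocount 1, which is stable on sparse
  counts; significance comes from the Wilcoxon rank-sum test (normal
  approximation, as count data are tie-heavy), BH-adjusted;
- marker ranking orders by adjusted p, then raw p, then symbol, for full
  determinism;
- symbol matching across omics layers is case-insensitive, with an optional
  protein-to-gene identifier map applied first.

## Enrichment

Over-representation uses the upper-tail hypergeometric probability with a
BH adjustment across sets. The default universe is the union of all set
genes and the query — stated explicitly because enrichment backends differ
silently on this point. `compare_clusters` reports the *deduplicated* union
of each cluster's top-2 terms, so closely related clusters sharing terms
yield fewer terms than 2 × clusters. `term_gene_network` links top terms to
their overlapping query genes with shared gene nodes, so a gene's degree
counts the terms it bridges.

## Trace metrics

All metrics that the package defines on peaks use a single detection pass:
local extrema filtered by topographic prominence (≥ `min_prominence_frac` ×
the trace's IQR, default 0.2) and minimum separation (default 16 h, about
two-thirds of a circadian period), alternation enforced by dropping the
lesser of two same-kind neighbours, and extremum times refined by a local
least-squares parabola (± 3 h). The refinement is what makes peak *times*
usable for phase arithmetic at realistic noise: on simulated recordings with
5% noise it reduces single-peak timing error from ~0.4 h to ~0.2 h. For
drug-treated recordings whose treatment interval suppresses amplitude to
~15%, the prominence fraction should be lowered (the analysis scripts use
0.05) so treatment-interval peaks remain detectable; this is a property of
the experiment, not of the algorithm.

The cycle-level definitions: period is the mean of consecutive peak
spacings within an interval; ΔPeriod is treatment minus baseline mean
period; cycle amplitude is |peak − preceding trough| normalized to the last
pre-treatment cycle, with cycles straddling the treatment onset excluded
from interval means; phase shift is `predicted − observed` at the *second*
post-treatment peak (extrapolated from the last pre-treatment peak and the
baseline period), so an advance is positive and the first-cycle waveform
transient is absorbed; B/A is the rising over falling amplitude around a
peak, 1 at steady state and < 1 while an oscillation regrows, with the
steady-state value read at the second post-washout peak.

RAE comes from a single-component fit, `offset + slope*t +
A*cos(2*pi*(t-phi)/tau)`, initialized from the discrete-Fourier component
with the largest amplitude in the period window (default 18–30 h) and
refined by Levenberg–Marquardt with tau constrained to the window. RAE is
the half-width of the 95% confidence interval on A divided by A, clipped to
[0, 1]; a diverged fit reports 1. This is a declared simplification of
multi-component FFT-NLLS suites, so its guarantees are property-based:
~0 for a noiseless cosine, saturating toward 1 on white noise (as an
ensemble property — a single noise realisation can fit a spurious in-band
component and dip to ~0.5), and monotone in noise. The Rayleigh test uses
the standard fourth-order series approximation of the p-value, adequate for
the n ≥ 8 cohorts it is applied to.

Pseudo-alignment shifts each trace so its reference peak sits at t = 0,
resamples onto a grid at the coarsest input sampling interval by linear
interpolation, and emits excluded treatment-artifact windows as gaps rather
than interpolating across them.

## The synthetic study design

The generators' defaults are the study conditions everything else is tested
under:

- **Traces**: cosine of period 24 h (24.8 h in the treatment cohort, the
  free-running period of the emulated recordings), amplitude 1, Gaussian
  noise SD 0.05 (5% of amplitude — reporter recordings are clean), dt 0.1 h
  for PMT-like and 0.5 h for imaging-like sampling; treatment epochs scale
  amplitude (0.15 in the treatment cohort), offset phase (+2 h advance /
  −3 h delay) and recover exponentially after washout (24 h half-life,
  chosen so recovery spans the 3–4 cycles the washout recordings show).
  Recordings are 288 h: 120 h baseline (enough for the 72-h detrend window
  plus margin), 72 h treatment, 96 h washout.
- **Proteome**: 5 timepoints × 3 replicates; 10% rhythmic features with
  log2 amplitude 1 and replicate noise SD 0.25 (amplitude = 4 × noise, a
  clearly-rhythmic regime); 10% missingness; CT24 simulated as an
  independent draw at the CT0 phase. Peak phases are drawn uniformly from
  CT 0/6/12/18.
- **Cells**: negative-binomial counts (dispersion 0.5), marker genes scaled
  8-fold in their type, co-expression categories sampled per cell from
  per-type probabilities with expression forced by a zero-truncated draw
  (so a planted category is recoverable from counts), day/night labels with
  a symmetric log2 fold change on flagged genes.

What the generators do *not* emulate — and hence what passing tests do not
show about real data: peptide-level quantification error that correlates
across timepoints, non-cosine waveforms, cell-to-cell correlation and
library-size variation, doublets and ambient counts, drifting baselines
with non-linear trends, and treatment artifacts other than the amplitude/
phase/level effects modelled. The acceptance checks therefore validate the
*estimators* under known truth, plus the worked-example arithmetic of the
published summary counts; they do not re-derive biology.

## Numerical conventions

- Constant rows min–max rescale to 0.5; a constant series has p = 1 and
  tau reported as 0.
- Monte-Carlo p-values use the (1 + exceedances)/(1 + B) convention;
  exhaustive enumeration uses the plain fraction (the identity arrangement
  is in the group, so p ≥ 1/m!).
- Exceedance comparisons use a 1e-9 slack so exact ties survive floating
  point.
- Features are grouped by missingness pattern; each group shares one
  permutation ensemble drawn from a single seeded RNG stream, keeping
  results deterministic for a given table and seed while p-values remain
  conditionally independent across features given the ensemble.
- k-means phase clustering uses 25 restarts under a fixed seed and
  relabels clusters by the CT of their centroid maximum.
- All problem sizes in the tests (e.g. 1,000-feature null tables, 2,000
  permutations, 6-slice cohorts, 50-seed RAE ladders) were chosen as the
  smallest sizes at which the binomial/Monte-Carlo error bands in the
  assertions are meaningful.

## Known limitations

- The umbrella test's candidate apexes default to the sampled phases; finer
  apex grids are possible but cannot be resolved by 5-timepoint data.
- The permutation null conditions on the observed missingness pattern;
  informative missingness (e.g. abundance-dependent) is not modelled.
- RAE is not numerically comparable to multi-component FFT-NLLS
  implementations; only its ordering properties are guaranteed.
- `pseudo_align` assumes a common underlying period across the cohort; it
  does not time-warp.
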