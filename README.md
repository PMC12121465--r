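# clockworks

Circadian multi-omics analysis of suprachiasmatic nucleus (SCN) explants.

The SCN keeps ~24-h time through a network of neurons and astrocytes whose
molecular state can be read out three ways: SILAC-based quantitative
proteomics over one circadian cycle, cell-type-resolved single-cell
transcriptomics, and long-term bioluminescence/fluorescence reporter
recordings under pharmacological treatment. `clockworks` implements the
computational pipeline that connects them:

- **Rhythm calling on a one-cycle design.** Features sampled at CT0/6/12/18
  plus an independently repeated CT24 (3 replicates each) are tested with
  two nonparametric algorithms and called circadian only when both reject at
  p < 0.05:
  - a JTK-style test: max over candidate lags of Kendall's tau-b between
    the observations and lagged cosine references,
  - an umbrella (Mack–Wolfe) trend test: max over candidate apexes of the
    concordance fraction of Mann–Whitney counts along the rise and fall of
    the umbrella, with the circular cycle unfolded at each apex's antipode.

  Both maxima share one permutation engine (observations permuted across
  timepoint slots; exhaustive at tiny n, Monte-Carlo otherwise), so the
  p-value of the max statistic absorbs the lag/apex multiplicity exactly.
- **Proteome assembly.** The quantified proteome retains a protein iff every
  timepoint has ≥ 2 of 3 replicate SILAC ratios; ratios are log2-transformed.
  Per-feature min–max rescaling and k-means phase clustering summarise the
  circadian set.
- **Cell-type analyses.** Marker-based cluster annotation (z-scored marker
  means), cluster-defining gene ranking (one-sided rank-sum, BH within
  cluster, top 250), two-gene co-expression partitions (neither / A-only /
  B-only / both, per cell type), interactor expression profiles (counts
  summed per type, min–max normalized per gene), day/night differential
  expression (Wilcoxon, log2 fold change of means with pseudocount 1), and
  the circadian-proteome × cell-type-transcriptome intersection.
- **Enrichment.** Hypergeometric over-representation over user-supplied GMT
  gene sets, per-cluster comparison with deduplicated top terms, and
  term–gene category networks that expose nexus genes.
- **Trace analytics.** Baseline detrending (line fit to the last 72 h of
  baseline, projected forward), 5-point moving-average smoothing,
  prominence- and separation-filtered peak/trough detection with
  sub-sample refinement, peak-to-peak period and ΔPeriod, cycle amplitudes
  normalized to the last baseline cycle, the second-peak phase shift
  (predicted − observed; advance positive), per-cycle B/A washout ratios
  with the steady state at the second post-washout peak, FFT-initialized
  cosine fits with relative amplitude error (RAE), Rayleigh circular
  statistics, circadian-time assignment, 24-h signal integration and cohort
  pseudo-alignment.
- **Synthetic data.** Generators for traces (damped cosine with treatment
  epochs: amplitude scaling, phase offsets, exponential washout recovery),
  proteome tables (cosine features on the log2 scale with replicate noise
  and missingness) and cell × gene count matrices (negative binomial with
  marker structure, planted co-expression partitions and day/night fold
  changes) — each returning its ground truth, so every estimator is tested
  against known parameters.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Running

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_proteome_rhythms.R
Rscript analysis/03_cells.R
Rscript analysis/04_enrich.R
Rscript analysis/05_traces.R
```

simulates the three datasets and prints, among others:

```
identified 500; quantified 439; excluded 61
umbrella 61 (13.9%), JTK 65 (14.8%), circadian 57 (13.0%)
sensitivity 1.00, false-positive rate 0.035
peak-phase distribution: CT0 19%, CT6 33%, CT12 23%, CT18 25%
partition of 4000 cells: 2345 neither, 255 Anxa2-only, 615 S100a10-only, 785 both
astrocytes co-expressing both: 52.6%
Aqp4 day/night log2FC -0.57 (adjusted p 2.01e-15)
advance (n=6): period 24.81 h, norm amplitude 0.15, phase shift +2.37 +- 0.14 h, steady-state B/A 0.86
delay (n=6): period 24.80 h, norm amplitude 0.15, phase shift -2.99 +- 0.18 h, steady-state B/A 0.88
```

Reading these numbers: 61 of 500 simulated proteins fail the
two-replicates-per-timepoint rule; of the 439 quantified, 57 (13.0%) pass
both rhythm tests, recovering all 50 planted rhythmic features (sensitivity
1.00) at a 3.5% false-positive rate. The cell partition recovers the planted
52% astrocytic co-expression and the −0.58 planted day/night fold change.
The trace cohort recovers the generating 24.8-h period, the 0.15 amplitude
suppression, and the imposed +2 h advance / −3 h delay with the correct
signs; the B/A ratio below 1 reflects the oscillation still growing back
after washout. Tables are written under `results/`.

In code, the core call is:

```r
library(clockworks)
sim <- simulate_proteome(proteome_sim_spec(n_proteins = 500, frac_rhythmic = 0.1, seed = 1))
calls <- call_circadian(sim$table, alpha = 0.05, n_perm = 2000, seed = 2)
head(calls[calls$is_circadian, ])
```

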