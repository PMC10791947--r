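---
title: "Population decoding: model, procedure and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population decoding: model, procedure and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(popdecode)
```

This vignette is the package's own account of the statistics it
implements: the decoding model and its assumptions, the parameters that
matter, what the synthetic generator does and does not emulate, and the
numerical choices that were genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The decoding model

A decoding analysis asks whether a categorical experimental condition
$y \in \{1, \dots, C\}$ can be predicted from a population activity
vector $x \in \mathbb{R}^S$ ($S$ = number of sites). The package's unit
of evidence is cross-validated prediction accuracy: the data are split
into $k$ parts, a classifier is trained on $k-1$ parts and evaluated on
the held-out part, and the procedure rotates through all $k$ folds.
Accuracy reliably above the chance level $1/C$ implies the population
carries information about $y$; nothing stronger (in particular, nothing
causal, and nothing about *how* downstream areas read the code) follows.

**Pseudo-populations.** Sites recorded in different sessions have no
joint trials, so population vectors are assembled by sampling: for each
site independently, $k \cdot r$ trials of every required label level are
drawn uniformly without replacement ($r$ =
`num_label_repeats_per_cv_split`, default 1) and dealt into the $k$
splits; the vectors for a given (class, split, repeat-slot) concatenate
the sites in ascending `siteID` order. This deliberately destroys
cross-site noise correlations within a trial — the classic assumption,
and limitation, of pseudo-population decoding. Each *resample run*
redraws the sample, so averaging over runs (default 50) integrates over
the sampling noise; surplus trials of a site are simply unused in a
given run.

**Temporal resolution.** Classification is repeated at every time bin,
yielding an accuracy time course. With `run_TCD = TRUE` the classifier
trained at bin $t$ is also evaluated at every other bin $t'$, giving the
train-time x test-time matrix of a temporal cross-decoding analysis: a
pronounced diagonal indicates a dynamic code (information carried by
time-varying patterns), a flat block a stationary one. Preprocessor
statistics estimated at train bin $t$ are applied unchanged to test
vectors from any $t'$, so no information flows from test data or test
times into training.

**Generalization.** `ds_generalization()` trains class $i$ on trials of
`train_label_levels[i]` and tests it on trials of
`test_label_levels[i]`. Above-chance test accuracy then demonstrates a
representation that abstracts over whatever distinguishes the paired
levels (e.g. identity across head orientations). Train-level and
test-level trials are sampled independently; when a level appears in
both lists the test sample is therefore a fresh draw, not the held-out
part of the training draw — acceptable because the interesting use case
has disjoint lists, and documented so the overlapping case is not
misread as a leakage guarantee.

## Classifiers and metrics

* **Maximum correlation**: class prototypes are mean training vectors;
  the decision value for class $c$ is the Pearson correlation across
  features between the test vector and prototype $c$. Invariant to
  positive affine maps of the test vector; undefined for one feature
  (an error) and defined as 0 when either vector is constant.
* **Poisson naive Bayes**: each feature of each class is an independent
  Poisson count with rate $\lambda_{cf} = (\text{summed training
  counts} + s)/n_c$, smoothing $s = 0.5$ by default so silent neurons
  never produce $\log 0$. The decision value is the total Poisson
  log-likelihood under equal priors. Requires `aggregate = "sum"`
  binning; mean-aggregated (non-integer) input is a configuration error
  unless rounding is explicitly acknowledged.
* **Metrics**: zero-one accuracy; normalized rank $(C - r)/(C - 1)$
  where $r$ is the actual class's rank (1 = best, ties by average rank)
  among the decision values — 1 best, 0 worst, 0.5 the chance
  expectation; and the mean decision value of the actual class
  (averaged raw, not rescaled, so classifiers with unbounded scores
  should only be compared with themselves). Records aggregate as fold
  means within a run, then means across runs; for the balanced folds
  the datasources produce this equals pooling, and per-run values are
  kept for dispersion estimates. Confusion matrices are pooled counts
  over runs and folds at train time = test time.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `bin_width` / `sampling_interval` | user-set (30 / 10 typical) | ms | bias-variance trade-off: wider bins raise counts and accuracy, blur timing; overlapping bins smooth the time course |
| `num_cv_splits` (k) | user-set (3 typical) | splits | only sites with >= k*r repetitions of every level qualify; the `repetition_curve()` ALL line makes the k-versus-sites trade-off explicit |
| `num_label_repeats_per_cv_split` (r) | 1 | pseudo-trials | >1 enlarges folds at the cost of needing k*r repetitions |
| `num_resample_runs` | 50 | runs | averages over pseudo-population sampling noise |
| `run_TCD` | TRUE | — | the full B x B grid costs B times the diagonal-only analysis |
| Poisson `smoothing` | 0.5 | spikes | keeps rates positive; any constant > 0 works, this one is fixed and documented |
| `num_parallel_workers` | half the logical CPUs | — | parallelism is across runs only; results are worker-count invariant by construction |

## Random-number discipline

Every stochastic step draws from a substream seeded by a hash of
(master seed, purpose, run, site/fold/bin indices): trial sampling per
(run, site), tie-breaking per evaluation cell, synthetic spikes per
site. Consequences: identical seeds give bit-identical results for any
worker count or scheduling; different runs draw different samples; and
prediction ties — equal maximal decision values, e.g. on silent bins —
are broken *uniformly at random* (flagged per record) rather than by
first index, because deterministic tie-breaking would bias degenerate
bins away from the $1/C$ chance level that the chance-recovery
diagnostics rely on.

## The synthetic generator: what a green test establishes

`synthetic_design()` emulates the structure of a faces x orientations
single-unit experiment: `n_orientations` x `n_people` stimuli (default
8 x 25 = 200 combined levels), ~200 ms stimulus with ~200 ms ISI,
millisecond 0/1 rasters, a ~150 ms response latency, and per-site
variation in trial counts (`trials_per_stimulus` as a range draws a
count per site x stimulus, emulating sessions of different lengths).
Spiking is an inhomogeneous Bernoulli-per-ms approximation of a Poisson
process (valid while rate x 1 ms << 1; enforced): baseline rate before
latency, a tuned rate `baseline + (peak - baseline) * similarity`
during the response window, exponential decay (`decay_tau_ms`, default
100 ms) back to baseline afterwards. Tuning similarity is a circular
Gaussian in person index (width `person_tuning_width`, default 1.5)
times, unless `orientation_invariant = TRUE`, the same in orientation
index. Defaults of 5 Hz baseline / 50 Hz peak are ordinary cortical
values.

It does **not** emulate refractoriness, bursting, cross-site noise
correlations, firing-rate drift, eye movements, or any fitted
resemblance to real recordings. A green end-to-end test therefore
establishes that the *pipeline* is correct (sampling, fold hygiene,
metric arithmetic, determinism) and that its statistical behavior
matches analytic ground truth (chance recovery, ceiling recovery,
generalization under invariant tuning) — not that any scientific claim
about real tissue would replicate.

Fixed statistical worlds used by the acceptance suite (chosen once,
stated here, not tuned per run):

* *chance recovery*: 50 sites, 25 identities at one orientation, 6
  trials per stimulus, labels shuffled independently within each site,
  30/10 binning, 3 splits, z-score + max correlation, 5 independent
  shuffle replicates x 10 resample runs. The 3-standard-error band uses
  one prediction per class per fold per run as the independent unit:
  predictions at overlapping time bins of the same run reuse the same
  pseudo-trials and are treated as perfectly correlated, which is the
  conservative direction. Shuffle replicates are averaged because a
  single finite shuffle leaves accidental label-activity structure (and
  without-replacement cross-validation is known to sit very slightly
  below chance); both effects shrink with trials and replicates.
* *ceiling / generalization / stationarity*: 60 sites, 25 identities x
  2 orientations, orientation-invariant tuning of width 1.0, 1 Hz
  baseline / 150 Hz peak, 100/50 binning — "strongly tuned, low-noise"
  made concrete. The stationarity check compares off-diagonal to
  diagonal TCD accuracy only within bins fully inside the response
  window, where the simulated code is stationary by construction.

## Numerical choices and conventions

* **Time columns** parse as `time.<start>_<end>`, integer (possibly
  negative) half-open ms windows; bins are labeled by `<start>_<start +
  bin_width>` and axes use bin starts. Incomplete trailing bins are
  dropped, never padded, so every bin averages exactly `bin_width`
  native samples. Whether a bin is a window mean (default) or a count
  (`aggregate = "sum"`) cannot change max-correlation or rank results —
  any fixed positive rescaling is absorbed by the classifier's
  invariances — but the Poisson classifier needs counts.
* **Raster contiguity** is validated; a uniform stride pattern (at
  least two equal inter-window gaps with equal widths) is downgraded to
  a warning as a down-sampled raster, a lone gap or overlap is an
  error.
* **siteID assignment** is lexicographic file-name order, recorded in a
  sidecar `*_sites.csv` manifest, so binned tables are reproducible
  regardless of directory iteration order.
* **Feature selectivity** is defined as the one-way ANOVA F statistic
  (sample-variance denominators; ties broken toward the lower feature
  index; zero within-class variance with signal ranks `Inf`, an
  all-constant feature 0). F is invariant to per-feature positive
  affine maps, so z-scoring and selection commute on the kept features.
* **Z-scoring** uses training-set mean and n-1 standard deviation; a
  zero-variance training feature maps to 0 in both sets.
* **Confusion-matrix time selection** (`plot_only_one_train_time`,
  CLI `--train-time`) picks the earliest bin starting at or after the
  requested time — the bin that "starts around" it — falling back to
  the last bin; absolute-nearest was the other candidate and is *not*
  what is implemented.
* **Result archives** are plain-text directories (CSV tables +
  `parameters.json`), so results are inspectable from any language;
  round-trips are exact to CSV text precision (~15 significant digits).
  The manifest append is write-temp-then-rename, leaving no partial row
  on a crash. The master seed is stored, so every archived result is
  re-derivable.
* **Trials are identified by 1-based file-row order** (R convention);
  the raster format carries no trial-ID column.

## Known limitations

Simultaneously recorded populations are decomposed into
pseudo-populations (trial identity across sites is not preserved);
there is no hyperparameter search, nested cross-validation,
permutation-based significance testing, or mutual-information summary;
`cl_svm()` is a thin optional adapter that requires the suggested
e1071 package and has no oracle coverage; and MATLAB-format raster
import is out of scope — write CSVs with the documented column grammar
instead.
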