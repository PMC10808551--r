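---
title: "Methods: calcium-trace analysis of hippocampal tuning and remapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium-trace analysis of hippocampal tuning and remapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippotune)
```

hippotune analyzes two-photon calcium recordings of hippocampal neurons
(PV and SOM interneurons, dentate granule cells) from head-fixed mice
running on a 4-m virtual track, together with a synthetic-session
generator that provides ground truth for every stage. This vignette is
the package's account of the underlying models, the parameters that
matter, and the design choices that were genuinely open.

## Signal model and ΔF/F

Two normalization variants are implemented, reflecting the two cell
classes the pipeline serves.

**Principal cells** (sparse, discrete transients):
`dff_sliding_percentile()` subtracts the running 8th percentile of the
fluorescence distribution in an ~8-s window around each sample (slow
drift correction), then divides by an initial baseline estimate — the
mean of all samples not exceeding 3 SD of the total signal, i.e. samples
unlikely to belong to transients. The window is truncated at trace
boundaries rather than padded; inventing data at the edges biases the
percentile less than shortening the window does.

**Interneurons** (high rates, no resolvable single transients):
`dff_segment_percentile()` divides each recording segment — one
familiar + novel block pair — by the 8th percentile of its own
fluorescence distribution. The continuous ΔF/F trace is then used
directly as a firing-rate proxy; transient detection is skipped because
interneuron firing exceeds both the 10-Hz sampling and the indicator
kinetics.

## Transient detection with false-positive calibration

For principal cells, transients are excursions crossing
`onset_threshold` baseline-SDs for at least `min_duration` seconds,
ending when the trace decays to half the onset level. The false-positive
rate is defined as the ratio of negative- to positive-going transients,
negatives being detected by the identical detector on the trace mirrored
around its baseline. `calibrate_transient_params()` searches the grid
{2, 2.5, 3, 3.5, 4} SD x {0.2, 0.3, 0.5, 1.0} s from permissive to
stringent and returns the first (least stringent) pair whose ratio is
below 5%, or fails loudly reporting the best ratio achieved. The
definitive baseline and SD are recomputed from transient-free samples
and detection is repeated once with them. All non-transient samples are
masked to zero before any spatial analysis, so baseline noise never
enters principal-cell maps.

## Movement masking and spatial maps

All spatial analyses use frames with speed >= 2 cm/s (the complement,
"immobility and very slow movement", absorbs the position jitter a
head-fixed animal produces without locomoting). Maps
(`spatial_map()`) average activity in 5-cm bins — 80 bins on the 400-cm
track — with half-open bin intervals so the wrap point is unambiguous;
population vectors use 10-cm bins. Occupancy `p_i` is the fraction of
masked frames per bin; at a fixed sampling rate the frame mean equals
the time mean, so no additional time weighting is applied. The identity
`lambda_bar = sum(p_i * lambda_i)` holds exactly by construction and is
asserted in the tests to 1e-12.

## Tuning metrics

* **Speed tuning** (`speed_tuning()`): mean ΔF/F in 1 cm/s speed bins
  (bins occupied < 1 s are dropped as unstable); a linear fit with
  offset against each bin's mean speed gives the slope. Significance
  comes from the sample-level Pearson correlation; both are reported
  because they answer different questions (magnitude vs reliability),
  and the modulation class (positive / negative / none) combines the
  slope sign with p < 0.05, two-sided.
* **Moving/immobile ratio**: mean activity while moving over mean
  activity while immobile; ratios below 1 mark immobility-preferring
  cells (a dentate SOM hallmark).
* **Spatial information**: `SI = sum_i lambda_i log2(lambda_i /
  lambda_bar) p_i` over occupied bins, `0 log 0 := 0`. ΔF/F bin means
  can be slightly negative after drift correction; the logarithm is
  undefined there, so negative means are clamped to zero and the clamped
  fraction is reported. The normalized variant divides by the cell's
  mean activity (mean ΔF/F over masked time), approximating bits per
  unit activity, the calcium analogue of bits/spike.
* **Coherence**: Pearson correlation between each bin and the mean of
  its two neighbors, wrapping across the seam on circular tracks.
* **Vector tuning**: activity-weighted circular resultant of the map;
  length in [0, 1] measures concentration, the angle the preferred
  position.
* **Stability**: zero-lag Pearson correlation between first- and
  second-half maps, halves being trial-based with the extra trial going
  to the first half. "Cross-correlation" is read as zero-lag Pearson
  throughout — the only reading that yields one number per cell.

## Circular-shuffle significance

The null destroys the activity-position alignment while preserving both
autocorrelation structures: the movement-masked position sequence is
circularly shifted against the masked activity sequence by 1000 random
intervals, and SI, coherence, vector length and stability are recomputed
per shift. Tuning is significant when the true value exceeds strictly
more than 95% of null values. Design points:

* Shifting is performed **within the masked (running) sequence**. If
  instead the full trace is shifted, positions recorded during pauses
  leak into shuffled maps but never into the true map; on 500 simulated
  untuned cells that variant produced a 1.2% type-I rate instead of the
  nominal 5%. The masked-sequence variant measures 4-7% per session.
* Shifts are uniform with replacement on `[min_shift, M - min_shift]`
  (`min_shift` = 10 s of masked frames), excluding near-zero and
  near-full shifts that replicate the true alignment. Because nearby
  shifts give correlated null values while the true value's neighborhood
  is excluded, the test is mildly anti-conservative on strongly
  autocorrelated traces (pooled ~6% across simulated null sessions);
  this is a property of the method, not of its implementation.
* One shift sequence is shared across metrics per cell, so metric nulls
  are mutually aligned.
* Per-cell shuffle results are reported uncorrected for multiplicity.

A **place cell** has shuffle-significant SI and a movement transient
rate of at least 1/min. Population-level comparisons
(`population_bootstrap_compare()`) draw one null value per cell and run
a paired two-sided Wilcoxon signed-rank test of true vs drawn values.

## Remapping

Per-cell familiar-novel field correlations use 5-cm maps over jointly
occupied bins, for cells that are place cells in at least one of the
compared conditions (10-cm bins are reserved for population vectors; the
bin width of per-cell correlations is configurable since only the
population-vector width is pinned down). Population-vector correlations
z-score each cell's 10-cm map over space (mean 0, SD 1 — removing rate
differences so the measure isolates spatial pattern) and correlate
across cells per bin; sessions with fewer than 5 place cells in either
condition are excluded. `condition_contrast()` compares field-correlation
distributions between conditions with an unpaired two-sided rank-sum
test.

## Statistical hygiene

`remove_extreme_outliers()` drops values beyond 3 IQR from the quartiles
in a single pass (fences from the original sample; with IQR = 0 nothing
is removed). `choose_and_run_test()` gates on Kolmogorov-Smirnov
normality at alpha 0.05 against a Gaussian with each sample's mean and
SD — the Lilliefors caveat applies: estimating the parameters from the
sample makes the gate conservative, which only affects the choice of
route, not the final test. All groups normal routes to t-test/ANOVA,
otherwise signed-rank / rank-sum / Kruskal-Wallis. `aggregate_by()`
moves the unit of analysis from cells to sessions or animals.

## Synthetic sessions and what they do (not) show

`simulate_session()` generates behavior, ground-truth tuning, spikes,
and fluorescence under one seed:

* **Behavior**: mean-reverting speed walk (relaxation 2 s, target
  15 cm/s, SD 5) with a two-state run/pause switch; pauses produce
  sub-threshold jitter like a head-fixed animal at rest. Context blocks
  alternate familiar/novel, either 60-s blocks (default, 20 blocks,
  ~20 min) or fixed 15-lap blocks; teleport blanks are explicit
  `recording_gap` frames.
* **Tuning**: `rate = max(0, baseline + slope * speed) * (1 + gain *
  vonMises(position)) * context_gain`. Slopes are drawn as 0.5-3% of
  baseline per cm/s so negatively modulated cells stay positive at
  typical speeds — negative modulation is a negative slope on a positive
  baseline with clipping at zero. Fields are unit-peak von Mises bumps
  parameterized by FWHM in cm (default 40-80), wrapping correctly.
  `remap_mode = "global"` draws independent novel-context field centers.
* **Fluorescence**: spikes from the inhomogeneous Poisson rate by
  thinning, convolved with a difference-of-exponentials kernel (rise
  0.1 s, decay 0.7 s, GCaMP6f-like, unit peak) at 0.1 ΔF/F per event,
  riding on a photon baseline with 5% bleaching-like drift (600-s
  timescale) plus 0.02 ΔF/F shot noise. SNR is a config axis, not a
  fixed fact.

The generator reproduces the statistical structure the analysis relies
on — lap-based occupancy, speed-rate coupling, von-Mises place fields,
context gains, calcium kernel smearing — but not motion artifacts,
neuropil contamination, segmentation errors, or non-Poisson spike
statistics (bursts, theta phase). Passing recovery tests therefore
validates the estimators against their own forward model, not against
every failure mode of real imaging data.

## Problem sizes and numerical choices

Validation runs use sizes at which the relevant uncertainty is small
enough to be decisive while keeping the suite quick: 500 cells x 1000
shuffles for type-I calibration (binomial 95% CI [0.032, 0.071]), 200
cells for slope recovery, 100 cells per remapping condition, 15-lap
sessions for place-field detection. Degenerate inputs are flagged `NA`
rather than guessed: constant maps have undefined coherence/stability,
zero immobile time leaves the moving/immobile ratio undefined, inactive
cells (`lambda_bar <= 0`) have undefined SI. Exclusions are counted and
reported, never silently zero-filled. The session container serializes
doubles as 17-significant-digit text parsed by strtod, making
write-read round trips bit-exact and pipeline re-runs byte-identical
under a fixed seed.
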