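---
title: "Detecting diel rhythms in behavior and gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting diel rhythms in behavior and gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielrhythm)
```

# Scope and model

`dielrhythm` implements a two-armed analysis of circadian (~24-h) rhythms in
a nocturnal aquatic invertebrate kept under controlled lighting:

* a **behavioral arm** that turns per-animal locomotor tracking records into
  cohort activity profiles and asks whether they oscillate, at what period,
  and how lighting perturbations shift the phase of the daily activity peak;
* an **expression arm** that screens a gene-by-time-point RNA-seq count
  matrix (samples every 4 h over two days) for transcripts with a diel
  expression cycle, clusters them by peak phase, and compares them against
  cross-species homolog tables.

Both arms are driven by seeded synthetic-data generators with known ground
truth, so every stage is testable at the desk without the original
sequencing accession.

Throughout, time of day is expressed as Zeitgeber time (ZT): hours since
lights-on, so ZT0–ZT12 is the light phase and ZT12–ZT24 the dark phase of a
12:12 light:dark (LD) cycle.

# Behavioral arm

## Binning and normalization

Raw tracking exports record a displacement per frame or second;
`bin_hourly()` sums them into hourly bins. Because absolute distances vary
strongly between individuals (size, metabolic rate), each animal is
rescaled by `normalize_to_max()` to percent of its own maximum hourly
distance before cohort averaging (`aggregate_cohort()`, mean and SE with
the n−1 sample SD; SE is defined as 0 for a single animal). Normalization
makes the cohort mean independent of per-animal scale multipliers — a
property the test suite checks by simulating the same cohort under two
scale regimes. An all-zero trace has no defined maximum; such animals raise
a typed `degenerate_trace_error` and are meant to be excluded and logged by
the caller.

## Periodogram and significance

`dft_periodogram()` evaluates spectral power on a dense grid of trial
periods (default 16–32 h in 0.01-h steps), giving sub-hour period estimates
from hourly bins. The power at each trial period is the **least-squares
sinusoid fit** (the Lomb–Scargle form with the phase offset that
diagonalizes the normal equations), scaled so that on the natural FFT grid
it equals the squared modulus of the discrete Fourier sum. The least-squares
form matters off the natural grid: the raw Fourier modulus of a real tone
is biased by interference between its positive- and negative-frequency
lobes (for a 72-h hourly cosine at 24 h the raw modulus peaks near 23.6 h),
whereas the least-squares power of a noiseless tone is maximal exactly at
the true period, because only there can the sinusoid fit the series
perfectly. The series is mean-centered first; otherwise the DC term
dominates every power ratio. The dominant period is the grid argmax, first
index on ties; a constant series is flagged degenerate with zero power.

Significance (`test_rhythmicity()`) uses a max-power permutation test:
hourly bins are randomly shuffled (destroying temporal structure while
keeping the marginal distribution), and
`p = (1 + #{permuted max ≥ observed max}) / (1 + n_permutations)`.
The default is 1000 permutations at α = 0.05. The estimator never returns
p = 0 and is exact under exchangeability, which holds for the null
(no temporal structure) the screen targets. The test suite verifies the
nominal size on white noise (rejection rate in [0.03, 0.07] over 500
replicates) and the uniformity of null p-values.

## Day/night summaries, peaks and phase shifts

`day_night_summary()` totals each animal's distance within dark versus
light schedule intervals, averages per interval (per 12-h phase across days
in a 12:12 cycle), then summarizes across animals. `daily_peaks()` finds
the ZT of the maximum of the smoothed cohort mean in each full 24-h window;
smoothing is a 3-h centered moving average (shortened at the edges) because
single daily peaks must be identified on visibly noisy means.
`phase_shift()` reports per-day circular differences from a baseline peak,
mapped to (−12, 12] with advances positive, so a peak moving from ZT16 to
ZT14 is a +2 h advance.

# Expression arm

## Read filtering and counting

The pipeline starts from a simplified aligned-record table (gene, 0-based
start, strand, mismatch count, unique-alignment flag) — native SAM parsing
is deliberately out of scope. `filter_and_dedup()` keeps uniquely aligned
records with at most two mismatches and collapses records sharing a
(gene, strand, start) triple to the first occurrence, since identical start
positions likely reflect PCR duplication. The operation is idempotent.
`tally_counts()` turns surviving records into a count-matrix column.

## Normalization

`poisson_tmm_normalize()` implements a trimmed-mean-of-M-values scaling
with Poisson weights. The pseudo-reference is the per-gene geometric mean
across samples (computed over genes positive everywhere), which avoids
privileging any one time point as "the" reference library. Per sample, the
M-values `log2(x/ref)` are trimmed to the interquartile half and averaged
with weights `1/sd`, where `sd = sqrt(1/x + 1/ref)` is the delta-method SD
of an M-value under Poisson counting noise — low-count genes, whose
log-folds are noisiest, are down-weighted. The resulting `log2 c_s` is
subtracted from the log2 matrix. Two identities pin the implementation
down: the trimmed weighted mean of adjusted log-folds is 0 to 1e-9 by
construction, and an exactly doubled two-sample library forces a factor
ratio of exactly 2. On simulated Poisson data with planted size factors in
[0.5, 2] the factors are recovered within 5% relative error up to one
global constant (only ratios of size factors are identifiable). Genes with
a zero count anywhere are excluded from factor estimation and kept in the
matrix with a 0.5 pseudocount, flagged. Log base 2 is used throughout; the
base cancels in every identity the package relies on.

`replicate_concordance()` quantifies agreement of two same-condition
libraries: conditional on a gene's total `x1 + x2`, under independent
Poisson sampling `x1 ~ Binomial(x1 + x2, N1/(N1+N2))`; a gene is concordant
when `x1` falls in the central equal-tail 99% region (0.5% per side,
realized with `qbinom`, which makes the region slightly conservative for
small totals). Under the equal-mean Poisson null the concordant fraction is
0.99 ± 0.01.

## The g-factor screen

Rhythmicity of a 12-point, 4-h-interval profile is scored by the
**g-factor**: the ratio of the FFT power at the frequency corresponding to
the 24-h period (bin 2 of a 12-point series) to the summed power over all
positive frequencies up to Nyquist. The series is mean-centered first, so
the DC term is excluded from the denominator — including it would make g
depend on expression level, contradicting its use as a rhythmicity score.
A pure 24-h cosine gives exactly g = 1; a constant series is defined as
g = 0 (degenerate). g is invariant to additive offsets and positive
scalings. The harmonics variant adds the on-grid powers of the 12-h and 8-h
harmonics to the numerator, crediting non-sinusoidal 24-h waveforms.
Genes with g above the 0.5 cutoff (strict inequality) form the diel-cycle
gene (DCG) set. The screen scores the normalized log2 matrix by default;
raw count input is also accepted — the choice of input is exposed rather
than fixed because either is defensible. Replicate columns (a duplicated
time-point library) are averaged after normalization, before scoring
(`collapse_replicates()`).

## Phase clustering and peak time

`kmeans_phase_clusters()` z-scores each DCG profile (clustering temporal
shape, not level) and runs Euclidean K-means with K = 5, keeping the best
of 50 seeded random starts by within-cluster sum of squares. Cluster labels
are then renumbered by ascending circular-mean peak ZT of their members, so
labels are reproducible and phase-ordered. With fewer distinct profiles
than K the remaining clusters are flagged empty instead of erroring.
`estimate_peak_zt()` reads the peak time from the phase of the 24-h DFT
component: a pure cosine peaking at ZT p returns exactly p, and shifting a
profile by one 4-h sample shifts the estimate by exactly 4 h.

# Comparative arm

`fold_change_filter()` applies the ≥3-fold day/night rule to homolog count
pairs, on raw printed counts without normalization (the source tables
report raw counts and no statistical test). The threshold is inclusive —
required for printed pairs like 9/3 and 1/3 to pass, as they do in the
source table — and a positive count against a zero is treated as an
infinite fold. `overlap_dcgs()` inner-joins a DCG set against a homolog
map and reports unmapped genes. Two transcribed homolog tables ship under
`inst/extdata/`; applying the filter to the 14 larval count pairs yields
6 day-upregulated and 8 night-upregulated homologs.

# Synthetic-data generators

`simulate_activity_cohort()` draws hourly traces
`scale_i × (baseline + A·cos(2π(h − peak_zt)/T)) + noise`, clipped at zero.
Defaults: 72 h, T = 24 h, peak ZT18 (mid-dark), baseline 10 cm/h,
amplitude 8 cm/h, noise SD 4 cm/h, per-animal scale multipliers uniform on
[0.5, 2]. Baseline and amplitude were chosen so that a unit-scale animal
covers roughly 190 cm per 12-h night — the magnitude reported for this kind
of tracking assay — with day/night contrast strong enough that dark-phase
totals exceed light-phase totals in ≥95% of cohorts. Animal-to-animal
heterogeneity is not characterized in published data; the uniform
scale-multiplier model is a modeling choice, and percent-of-max
normalization removes it by construction. Condition semantics: LL and
`arrhythmic` zero the rhythmic term; `dark_pulse` advances the phase by a
configurable offset (default 2 h) from the pulse onward and `light_pulse`
zeroes the rhythm from the pulse onward — deliberately phenomenological
mirrors of observed advance versus disruption, with no entrainment-dynamics
model. Clipping at zero slightly biases low means upward; tests therefore
compare cohort means against a large-cohort simulation oracle rather than
the analytic profile. Each cohort uses one RNG stream seeded from the spec;
animals consume it in fixed order, so identical specs are bit-identical.

`simulate_expression_timecourse()` draws
`x_gs ~ Poisson(c_s · μ_g · 2^{(A/2)cos(2π(zt_s − φ_g)/24)})` with μ_g
log-normal (meanlog log 100, sdlog 1 — a realistic bulk RNA-seq depth
profile where low-count genes genuinely limit detection), peak-to-trough
log2 fold change A = 2 for planted rhythmic genes, and phases recycled over
the sampled ZTs. The cosine waveform (rather than a square wave) makes the
g-factor limits analytic; a square-wave-like profile can be emulated by
adding harmonics, which is what the harmonics variant is tested against.
What the generator does **not** emulate: overdispersion beyond Poisson,
correlated genes, trends across days, or batch structure — so passing tests
demonstrate correctness of the procedures under their stated noise model,
not robustness of the screen on real overdispersed data.

# Problem sizes and numerical choices

The packaged analyses and tests use the study-scale designs: 35 LD / 20 DD
/ 30 LL animals × 72 h, 5000 genes × 12 time points with 180 planted
rhythmic genes, 500-replicate calibration runs, 1000-permutation tests
(200 where a coarser 0.1-h grid suffices, chosen to keep a full run in
seconds while leaving the statistical conclusions unchanged). Tolerances:
exact identities at 1e-9, spectral phase identities at 1e-6, stochastic
bounds at the simulation-derived thresholds stated in the tests.
Tie-breaks: periodogram and daily-peak argmax take the first (earliest)
index. Degenerate inputs (constant series, all-zero traces, all-identical
profiles, all-zero libraries) are defined explicitly rather than left to
error: p = 1, typed errors, one occupied cluster, and an explicit error,
respectively.

# Known limitations

* The permutation test shuffles hours independently; autocorrelated but
  non-rhythmic activity could inflate its size. Block permutation would be
  the extension.
* The g-factor requires the target period to sit on the natural FFT grid;
  designs whose length × interval is not a multiple of 24 h need the
  dense-grid periodogram instead.
* The Poisson noise model understates biological variance of real RNA-seq;
  the concordance check quantifies exactly this (real replicate pairs fall
  below the ~99% Poisson expectation).
* Phase estimates use only the 24-h Fourier component; strongly
  non-sinusoidal waveforms can bias peak ZT by up to the sampling interval.
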