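# dielrhythm

Detection and characterization of ~24-hour (diel) rhythms in animal
behavior and gene expression, built for circadian studies of nocturnal
aquatic invertebrates tracked under controlled lighting and profiled by
RNA-seq every 4 h over two days.

The package implements two analysis arms over seeded synthetic-data
generators with known ground truth:

* **Behavior** — hourly binning of locomotor tracking records, per-animal
  normalization to percent of maximum, cohort averaging, a dense-grid
  least-squares Fourier periodogram (sub-hour period estimates from hourly
  bins), a max-power permutation test for rhythmicity, day/night activity
  totals, and daily-peak / phase-shift reports for light- and dark-pulse
  experiments.
* **Expression** — aligned-read filtering (unique alignment, ≤2
  mismatches) with start-position de-duplication, trimmed-mean-of-M-values
  normalization weighted by inverse Poisson standard deviations, replicate
  concordance against the central 99% Poisson region, the spectral
  **g-factor** rhythmicity score, diel-cycle-gene (DCG) selection at
  g > 0.5, K-means phase clustering (K = 5), peak Zeitgeber-time
  estimation, and cross-species homolog day/night ≥3-fold filtering.

The g-factor of a profile x sampled every 4 h over two days is

    g = P(1/24 h) / Σ_{f>0} P(f)

the fraction of (mean-centered) spectral power at the 24-h frequency; a
pure 24-h cosine gives g = 1, white noise ~1/6 on average. The periodogram
power at an off-grid trial period T is the least-squares single-sinusoid
fit (Lomb–Scargle form), which coincides with the squared DFT modulus on
the natural frequency grid and peaks exactly at the true period for a
noiseless tone.

## Worked example

Simulate the study-scale light:dark cohort, normalize, average, and test
for rhythmicity:

```r
library(dielrhythm)

spec   <- activity_sim_spec(n_animals = 35, duration_h = 72,
                            condition = "LD", seed = 101)
cohort <- simulate_activity_cohort(spec)
prof   <- aggregate_cohort(lapply(cohort$traces, normalize_to_max))
pg     <- dft_periodogram(prof$mean_pct)          # grid 16-32 h, 0.01-h step
rt     <- test_rhythmicity(prof$mean_pct, seed = 1)
c(period = pg$dominant_period_h, p = rt$p_value)
#>      period           p
#> 2.40700e+01 9.99001e-04
```

The cohort's dominant period is 24.07 h — the schedule-locked circadian
period recovered to within the grid step — and the permutation p-value
0.000999 (the minimum attainable with 1000 permutations) marks the
oscillation as significant. The same procedure on a constant-light cohort
(`condition = "LL"`) finds no significant period.

The expression screen on a 5000-gene matrix with 180 planted rhythmic
genes:

```r
sim  <- simulate_expression_timecourse(
          expression_sim_spec(5000, frac_rhythmic = 180/5000,
                              phases_zt = c(1, 5, 9, 13, 17), seed = 111))
nm   <- poisson_tmm_normalize(sim$counts)
gtab <- g_factor_table(nm$normalized)
dcgs <- select_dcgs(gtab, cutoff = 0.5)
length(dcgs); sum(sim$truth$rhythmic_flag[dcgs])
#> [1] 349
#> [1] 180
```

All 180 planted genes clear the cutoff (the other 169 are null genes whose
12-point spectra exceed 0.5 by chance — the ranking itself separates
planted from null genes with AUROC 0.9997 on this simulation). `kmeans_phase_clusters()`
then recovers the five planted phase groups exactly (adjusted Rand
index 1.0 in the test suite).

A full scripted analysis — simulation, behavior, expression, comparison —
lives under `analysis/01_simulate.R` … `analysis/04_compare.R`, writing
tables under `results/`; `run_pipeline()` runs the same stages as one
call with a hash manifest for reproducibility.

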