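# Shared fixtures and independent oracles used across test files.

# cosine sampled like the diel RNA-seq design: n points every interval_h,
# first sample at start_zt, peaking at peak_zt
diel_cosine <- function(peak_zt, n = 12, interval_h = 4, start_zt = 1,
                        amplitude = 1, level = 0) {
  zt <- start_zt + interval_h * (seq_len(n) - 1)
  level + amplitude * cos(2 * pi * (zt - peak_zt) / 24)
}

# rank-based AUROC of a score against a logical truth vector
rank_auroc <- function(score, positive) {
  r <- rank(score)
  (mean(r[positive]) - (sum(positive) + 1) / 2) / sum(!positive)
}

# absolute circular distance between hour values on a 24-h clock
circ_dist_h <- function(a, b) {
  abs(((a - b + 12) %% 24) - 12)
}

# brute-force g: positive-frequency FFT power ratio, written independently
# of the package implementation
oracle_g <- function(x, k0 = 3L, include_harmonics = FALSE) {
  x <- x - mean(x)
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  posbins <- 2:(n %/% 2 + 1)
  num <- if (include_harmonics) seq(k0, n %/% 2 + 1, by = k0 - 1) else k0
  sum(P[num]) / sum(P[posbins])
}

# simulate, normalize and average an activity cohort into a mean profile
cohort_mean_profile <- function(spec) {
  co <- simulate_activity_cohort(spec)
  aggregate_cohort(lapply(co$traces, normalize_to_max))
}
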