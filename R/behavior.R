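#' Sum tracked displacements into hourly bins
#'
#' Raw tracking exports record a displacement every frame/second; the
#' behavioral analysis operates on total distance per hour. A trace already
#' holding hourly values is returned as-is.
#'
#' @param trace an \code{activity_trace} holding either raw \code{events}
#'   (\code{time_s}, \code{displacement_cm}) or precomputed
#'   \code{hourly_cm}.
#' @return Numeric vector of length \code{duration_h}: cm moved in each
#'   hour bin \code{[h, h+1)}.
#' @export
bin_hourly <- function(trace) {
  stopifnot(inherits(trace, "activity_trace"))
  if (!is.null(trace$hourly_cm)) {
    return(as.numeric(trace$hourly_cm))
  }
  ev <- trace$events
  n_h <- trace$duration_h
  if (nrow(ev) && (any(ev$time_s < 0) || any(ev$time_s >= n_h * 3600))) {
    stop("event time outside [0, duration)")
  }
  hour <- floor(ev$time_s / 3600)
  out <- numeric(n_h)
  if (nrow(ev)) {
    sums <- tapply(ev$displacement_cm, factor(hour, levels = 0:(n_h - 1L)), sum)
    out <- as.numeric(ifelse(is.na(sums), 0, sums))
  }
  out
}

#' Normalize hourly activity to percent of individual maximum
#'
#' Each animal's hourly distances are expressed as a percentage of the
#' maximum hourly distance recorded for that individual, removing
#' between-animal differences in absolute distance (size, metabolic rate).
#'
#' @param hourly per-hour distances (cm), or an \code{activity_trace}.
#' @param animal_id optional label attached to the result.
#' @return An object of class \code{normalized_activity}: list with
#'   \code{animal_id} and \code{pct_of_max} in [0, 100] (100 at the maximum).
#' @export
normalize_to_max <- function(hourly, animal_id = NA_character_) {
  if (inherits(hourly, "activity_trace")) {
    animal_id <- hourly$animal_id
    hourly <- bin_hourly(hourly)
  }
  m <- max(hourly)
  if (!is.finite(m) || m <= 0) {
    stop(structure(class = c("degenerate_trace_error", "error", "condition"),
                   list(message = paste0("degenerate trace (all-zero activity)",
                                         if (!is.na(animal_id))
                                           paste0(": ", animal_id)),
                        call = sys.call(-1))))
  }
  structure(list(animal_id = animal_id, pct_of_max = 100 * hourly / m),
            class = "normalized_activity")
}

#' Average normalized activity across a cohort
#'
#' @param traces list of \code{normalized_activity} objects (or bare numeric
#'   vectors of equal length).
#' @return An object of class \code{cohort_activity}: per-hour \code{mean_pct}
#'   and \code{se_pct} (sample SD / sqrt(n); 0 when n = 1) plus
#'   \code{n_animals}.
#' @export
aggregate_cohort <- function(traces) {
  vecs <- lapply(traces, function(x) {
    if (inherits(x, "normalized_activity")) x$pct_of_max else as.numeric(x)
  })
  if (length(vecs) < 1L) stop("need at least one animal")
  len <- lengths(vecs)
  if (length(unique(len)) != 1L) stop("traces have unequal lengths")
  m <- do.call(rbind, vecs)
  n <- nrow(m)
  se <- if (n == 1L) rep(0, ncol(m)) else apply(m, 2, stats::sd) / sqrt(n)
  structure(list(mean_pct = colMeans(m), se_pct = se, n_animals = n),
            class = "cohort_activity")
}

# least-squares spectral power of each column of X at each trial period.
# X rows are hourly bins (assumed mean-centered); returns periods x columns.
# This is the Lomb-Scargle form with the phase offset tau that diagonalizes
# the normal equations; scaled so that on the natural FFT grid (period =
# n/k) it equals the squared DFT modulus |sum x e^{-2 pi i t/T}|^2.
dft_power_matrix <- function(X, period_grid_h) {
  t <- seq_len(nrow(X)) - 1
  omega <- matrix(2 * pi / period_grid_h, nrow = 1)
  ang2 <- outer(t, 2 * drop(omega))
  tau <- atan2(colSums(sin(ang2)), colSums(cos(ang2))) / (2 * drop(omega))
  ang <- outer(t, drop(omega)) - matrix(drop(omega) * tau,
                                        nrow(X), length(tau), byrow = TRUE)
  C <- cos(ang)
  S <- sin(ang)
  cc <- colSums(C^2)
  ss <- colSums(S^2)
  xc2 <- crossprod(C, X)^2
  xs2 <- crossprod(S, X)^2
  n <- nrow(X)
  (n / 2) * (sweep(xc2, 1, cc, `/`) + sweep(xs2, 1, ss, `/`))
}

#' Dense-grid Fourier periodogram for sub-hour period estimates
#'
#' Least-squares spectral power of a mean-centered hourly series evaluated
#' on a dense grid of trial periods. At each trial period the series is fit
#' by a single sinusoid (the Lomb-Scargle formulation for evenly sampled
#' data); on the natural FFT grid this power equals the squared modulus of
#' the discrete Fourier sum, while off the grid the least-squares form
#' avoids the interference bias of the raw Fourier modulus, so a pure tone
#' peaks at its true period. Evaluating a dense period grid gives sub-hour
#' period resolution from hourly bins, which FFT bin spacing alone cannot.
#'
#' @param series per-hour values (length >= 4), e.g. a cohort mean profile.
#' @param period_grid_h strictly increasing trial periods in hours; default
#'   16 to 32 h in 0.01-h steps, bracketing the circadian range.
#' @return An object of class \code{periodogram}: \code{period_grid_h},
#'   \code{power} (>= 0), \code{dominant_period_h} (argmax; first index on
#'   ties; \code{NA} with \code{degenerate = TRUE} for a constant series).
#' @export
dft_periodogram <- function(series, period_grid_h = seq(16, 32, by = 0.01)) {
  series <- as.numeric(series)
  stopifnot(length(series) >= 4, all(diff(period_grid_h) > 0))
  x <- series - mean(series)
  degenerate <- isTRUE(all.equal(stats::sd(series), 0)) || all(x == 0)
  power <- as.numeric(dft_power_matrix(matrix(x, ncol = 1), period_grid_h))
  structure(
    list(period_grid_h = period_grid_h,
         power = if (degenerate) rep(0, length(period_grid_h)) else power,
         dominant_period_h = if (degenerate) NA_real_
                             else period_grid_h[which.max(power)],
         degenerate = degenerate),
    class = "periodogram")
}

#' Permutation test for rhythmicity of an hourly series
#'
#' Tests whether the maximum periodogram power over the trial-period grid
#' exceeds what random re-orderings of the hourly bins produce. The p-value
#' uses the add-one permutation estimator
#' \eqn{p = (1 + \#\{max\ power_{perm} \ge max\ power_{obs}\}) /
#' (1 + n_{perm})}, which is valid (never 0) and distribution-free.
#'
#' @param series per-hour values.
#' @param period_grid_h trial periods (default 16-32 h, 0.01-h step).
#' @param n_permutations number of random shuffles (>= 100; default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed for the shuffles.
#' @return An object of class \code{rhythm_test}: \code{observed_max_power},
#'   \code{dominant_period_h}, \code{p_value}, \code{n_permutations},
#'   \code{alpha}, \code{significant} (p <= alpha). A constant series gives
#'   p = 1.
#' @export
test_rhythmicity <- function(series, period_grid_h = seq(16, 32, by = 0.01),
                             n_permutations = 1000, alpha = 0.05, seed = 1L) {
  stopifnot(n_permutations >= 100)
  pg <- dft_periodogram(series, period_grid_h)
  if (pg$degenerate) {
    return(structure(list(observed_max_power = 0,
                          dominant_period_h = NA_real_, p_value = 1,
                          n_permutations = n_permutations, alpha = alpha,
                          significant = FALSE), class = "rhythm_test"))
  }
  obs <- max(pg$power)
  x <- as.numeric(series) - mean(series)
  set.seed(as.integer(seed))
  perm_mat <- vapply(seq_len(n_permutations), function(i) sample(x),
                     numeric(length(x)))
  perm_max <- apply(dft_power_matrix(perm_mat, period_grid_h), 2, max)
  p <- (1 + sum(perm_max >= obs)) / (1 + n_permutations)
  structure(list(observed_max_power = obs,
                 dominant_period_h = pg$dominant_period_h,
                 p_value = p, n_permutations = n_permutations, alpha = alpha,
                 significant = p <= alpha),
            class = "rhythm_test")
}

#' Day/night activity totals for a cohort
#'
#' For each animal, total distance within dark versus light schedule
#' intervals is averaged per interval (i.e. per 12-h phase across days in a
#' 12:12 cycle), then summarized across animals.
#'
#' @param traces list of \code{activity_trace} objects.
#' @param schedule a \code{light_schedule} covering the trace duration.
#' @return An object of class \code{day_night_summary}:
#'   \code{mean_dark_total_cm}, \code{se_dark}, \code{mean_light_total_cm},
#'   \code{se_light}, \code{n}. Totals for a state absent from the schedule
#'   are \code{NA}.
#' @export
day_night_summary <- function(traces, schedule) {
  stopifnot(inherits(schedule, "light_schedule"), length(traces) >= 1L)
  per_animal <- lapply(traces, function(tr) {
    hourly <- bin_hourly(tr)
    states <- schedule_states_hourly(schedule, length(hourly))
    iv <- schedule$intervals
    iv_idx <- findInterval(seq_along(hourly) - 0.5, iv$start_h)
    totals <- tapply(hourly, factor(iv_idx, levels = seq_len(nrow(iv))), sum)
    totals[is.na(totals)] <- 0
    c(dark = if (any(iv$state == "dark"))
        mean(totals[iv$state == "dark"]) else NA_real_,
      light = if (any(iv$state == "light"))
        mean(totals[iv$state == "light"]) else NA_real_)
  })
  m <- do.call(rbind, per_animal)
  n <- nrow(m)
  se <- function(v) if (n == 1L) 0 else stats::sd(v) / sqrt(n)
  structure(list(mean_dark_total_cm = mean(m[, "dark"]),
                 se_dark = se(m[, "dark"]),
                 mean_light_total_cm = mean(m[, "light"]),
                 se_light = se(m[, "light"]),
                 n = n),
            class = "day_night_summary")
}

# centered moving average of window 3, shortened at the edges
smooth_ma3 <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) mean(x[max(1, i - 1):min(n, i + 1)]),
         numeric(1))
}

#' Daily activity peaks of a cohort profile
#'
#' For each full 24-h window of the mean profile, the ZT of the maximum
#' after 3-h centered moving-average smoothing (the smoothing makes single
#' daily peaks identifiable on noisy means). Ties resolve to the earliest
#' hour.
#'
#' @param cohort a \code{cohort_activity} or bare numeric mean profile.
#' @param schedule a \code{light_schedule} (supplies the ZT offset).
#' @return Numeric vector: peak ZT in [0, 24) per full day.
#' @export
daily_peaks <- function(cohort, schedule) {
  profile <- if (inherits(cohort, "cohort_activity")) cohort$mean_pct
             else as.numeric(cohort)
  stopifnot(inherits(schedule, "light_schedule"), length(profile) >= 24)
  sm <- smooth_ma3(profile)
  n_days <- length(profile) %/% 24
  vapply(seq_len(n_days), function(d) {
    idx <- (d - 1L) * 24L + 1:24
    h <- idx[which.max(sm[idx])] - 1L   # bin start hour; which.max = first tie
    zt_of_hour(schedule, h)
  }, numeric(1))
}

#' Phase shifts of daily peaks relative to a baseline peak
#'
#' The shift for each day is the circular difference baseline minus peak,
#' mapped to (-12, 12]; positive values are phase advances (peak earlier
#' than baseline).
#'
#' @param peaks per-day peak ZT (NA allowed for days with no defined peak).
#' @param baseline_zt the reference (entrained) peak ZT.
#' @return An object of class \code{phase_shift_report}:
#'   \code{baseline_peak_zt}, \code{daily_peak_zt}, \code{shift_h}.
#' @export
phase_shift <- function(peaks, baseline_zt) {
  if (length(peaks) < 1L) stop("peaks must be non-empty")
  d <- (baseline_zt - peaks) %% 24
  d[!is.na(d) & d > 12] <- d[!is.na(d) & d > 12] - 24
  structure(list(baseline_peak_zt = baseline_zt %% 24,
                 daily_peak_zt = peaks %% 24,
                 shift_h = d),
            class = "phase_shift_report")
}
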