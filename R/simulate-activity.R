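#' Specification for a simulated locomotor-activity cohort
#'
#' Describes a cohort of individually tracked animals whose hourly locomotor
#' activity follows a nocturnal ~24-h rhythm under a configurable lighting
#' condition. The deterministic part of each animal's hourly distance is
#' \deqn{scale_i (baseline + A \cos(2\pi (h - peak\_zt)/T))}
#' with Gaussian noise added and negative values clipped at zero. The cosine
#' trough is centred in the light phase (peak at ZT18 for a 12:12 cycle), so
#' simulated animals are nocturnal.
#'
#' Conditions:
#' \describe{
#'   \item{LD}{12:12 light:dark; rhythm locked to the schedule.}
#'   \item{DD}{constant dark free-run; rhythm persists at \code{period_h}.}
#'   \item{LL}{constant light; the rhythmic term is zeroed from light onset
#'     (i.e. throughout), leaving baseline plus noise.}
#'   \item{arrhythmic}{no rhythmic term regardless of schedule (used, e.g.,
#'     to emulate pharmacological clock disruption).}
#'   \item{dark_pulse}{LD-entrained rhythm whose phase is advanced by
#'     \code{pulse_shift_h} from the end of \code{pulse_window} onward.}
#'   \item{light_pulse}{LD-entrained rhythm zeroed from the end of
#'     \code{pulse_window} onward (cycle disruption).}
#' }
#'
#' @param n_animals number of animals (> 0).
#' @param duration_h recorded hours (> 0); 72 h (three cycles) by default.
#' @param condition one of \code{"LD"}, \code{"DD"}, \code{"LL"},
#'   \code{"dark_pulse"}, \code{"light_pulse"}, \code{"arrhythmic"}.
#' @param schedule optional \code{light_schedule}; defaults to the schedule
#'   implied by \code{condition} (12:12 LD, constant dark, or constant light).
#' @param period_h rhythm period in hours (default 24).
#' @param nocturnal_amplitude cosine amplitude A in cm/h (>= 0). Zero makes
#'   the cohort effectively arrhythmic.
#' @param baseline mean activity level in cm/h (> 0).
#' @param peak_zt ZT of the nocturnal activity peak (default 18, the middle
#'   of the dark phase).
#' @param animal_scale_range range of the uniform per-animal scale
#'   multipliers modelling animal-to-animal amplitude heterogeneity.
#' @param noise_sd SD of additive Gaussian noise in cm/h (>= 0).
#' @param pulse_window numeric \code{c(start_h, length_h)}: the recording
#'   hour at which a light/dark pulse starts and its length. Required for the
#'   pulse conditions. With the default \code{zt0_offset_h = 0} the start
#'   hour modulo 24 is the pulse's ZT.
#' @param pulse_shift_h phase advance (hours, positive = earlier peak)
#'   applied from the pulse onward under \code{dark_pulse} (default 2).
#' @param seed integer seed; mandatory for reproducibility.
#' @return An object of class \code{activity_sim_spec}.
#' @export
activity_sim_spec <- function(n_animals,
                              duration_h = 72,
                              condition = c("LD", "DD", "LL", "dark_pulse",
                                            "light_pulse", "arrhythmic"),
                              schedule = NULL,
                              period_h = 24,
                              nocturnal_amplitude = 8,
                              baseline = 10,
                              peak_zt = 18,
                              animal_scale_range = c(0.5, 2),
                              noise_sd = 4,
                              pulse_window = NULL,
                              pulse_shift_h = 2,
                              seed = 1L) {
  condition <- match.arg(condition)
  if (!is.numeric(n_animals) || length(n_animals) != 1L || n_animals < 1) {
    stop("invalid spec: n_animals must be a positive count")
  }
  if (!is.numeric(duration_h) || length(duration_h) != 1L || duration_h <= 0) {
    stop("invalid spec: duration_h must be positive")
  }
  stopifnot(period_h > 0, nocturnal_amplitude >= 0, baseline > 0,
            noise_sd >= 0, length(animal_scale_range) == 2L,
            all(animal_scale_range > 0),
            animal_scale_range[1] <= animal_scale_range[2])
  if (condition %in% c("dark_pulse", "light_pulse")) {
    if (is.null(pulse_window) || length(pulse_window) != 2L ||
        pulse_window[2] <= 0) {
      stop("invalid spec: pulse conditions need pulse_window = c(start_h, length_h)")
    }
  }
  if (is.null(schedule)) {
    schedule <- switch(condition,
      LD = , dark_pulse = , light_pulse = ld_schedule(duration_h),
      DD = , arrhythmic = constant_schedule(duration_h, "dark"),
      LL = constant_schedule(duration_h, "light"))
  }
  structure(
    list(n_animals = as.integer(n_animals), duration_h = as.integer(duration_h),
         condition = condition, schedule = schedule, period_h = period_h,
         nocturnal_amplitude = nocturnal_amplitude, baseline = baseline,
         peak_zt = peak_zt, animal_scale_range = animal_scale_range,
         noise_sd = noise_sd, pulse_window = pulse_window,
         pulse_shift_h = pulse_shift_h, seed = as.integer(seed)),
    class = "activity_sim_spec"
  )
}

# deterministic (noise-free, unit-scale) hourly expectation for one animal
activity_expected_profile <- function(spec) {
  h <- seq_len(spec$duration_h) - 1L
  zt <- h + spec$schedule$zt0_offset_h
  rhythm <- cos(2 * pi * (zt - spec$peak_zt) / spec$period_h)
  if (spec$condition %in% c("LL", "arrhythmic") ||
      spec$nocturnal_amplitude == 0) {
    rhythm[] <- 0
  } else if (spec$condition == "dark_pulse") {
    after <- h >= spec$pulse_window[1] + spec$pulse_window[2]
    rhythm[after] <- cos(2 * pi * (zt[after] + spec$pulse_shift_h -
                                     spec$peak_zt) / spec$period_h)
  } else if (spec$condition == "light_pulse") {
    after <- h >= spec$pulse_window[1] + spec$pulse_window[2]
    rhythm[after] <- 0
  }
  spec$baseline + spec$nocturnal_amplitude * rhythm
}

#' Simulate a locomotor-activity cohort
#'
#' Draws per-animal hourly activity traces from an [activity_sim_spec()].
#' One RNG stream seeded from \code{spec$seed} drives the whole cohort; the
#' per-animal scale multiplier and noise are consumed in a fixed animal
#' order, so identical specs give bit-identical cohorts.
#'
#' @param spec an \code{activity_sim_spec}.
#' @return A list with \code{traces} (a list of \code{activity_trace}
#'   objects, each holding \code{animal_id}, \code{hourly_cm},
#'   \code{duration_h}, \code{condition}) and \code{truth} (the ground truth:
#'   \code{true_period_h}, \code{peak_zt}, \code{rhythmic} flag,
#'   \code{animal_scales}, and the noise-free unit-scale \code{expected}
#'   hourly profile).
#' @export
simulate_activity_cohort <- function(spec) {
  stopifnot(inherits(spec, "activity_sim_spec"))
  set.seed(spec$seed)
  expected <- activity_expected_profile(spec)
  rhythmic <- !(spec$condition %in% c("LL", "arrhythmic")) &&
    spec$nocturnal_amplitude > 0
  traces <- vector("list", spec$n_animals)
  scales <- numeric(spec$n_animals)
  for (i in seq_len(spec$n_animals)) {
    scales[i] <- stats::runif(1, spec$animal_scale_range[1],
                              spec$animal_scale_range[2])
    hourly <- scales[i] * expected +
      stats::rnorm(spec$duration_h, 0, spec$noise_sd)
    hourly <- pmax(hourly, 0)  # clipping slightly biases low means upward
    traces[[i]] <- structure(
      list(animal_id = sprintf("animal_%02d", i), hourly_cm = hourly,
           duration_h = spec$duration_h, condition = spec$condition),
      class = "activity_trace")
  }
  list(traces = traces,
       truth = list(true_period_h = if (rhythmic) spec$period_h else NA_real_,
                    peak_zt = if (rhythmic) spec$peak_zt else NA_real_,
                    rhythmic = rhythmic,
                    animal_scales = scales,
                    expected = expected))
}

#' Construct an activity trace from raw tracking events
#'
#' @param animal_id label.
#' @param events data frame with columns \code{time_s} (seconds since
#'   recording start) and \code{displacement_cm} (>= 0), as exported by
#'   centre-point video tracking.
#' @param duration_h recording length in hours.
#' @param condition optional condition label.
#' @return An \code{activity_trace} carrying the raw events; see
#'   [bin_hourly()].
#' @export
activity_trace_events <- function(animal_id, events, duration_h,
                                  condition = NA_character_) {
  stopifnot(is.data.frame(events),
            all(c("time_s", "displacement_cm") %in% names(events)))
  if (any(events$displacement_cm < 0)) stop("displacements must be non-negative")
  if (nrow(events) &&
      (any(events$time_s < 0) || any(events$time_s >= duration_h * 3600))) {
    stop("event time outside [0, duration)")
  }
  structure(list(animal_id = animal_id, events = events,
                 duration_h = duration_h, condition = condition),
            class = "activity_trace")
}
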