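#' Construct a light schedule
#'
#' A light schedule describes the illumination regime of a recording as an
#' ordered set of contiguous intervals, each labelled \code{"light"} or
#' \code{"dark"}, together with the Zeitgeber-time offset of the recording
#' start. By convention ZT0 is lights-on, so in a 12:12 light:dark (LD) cycle
#' dark runs from ZT12 to ZT24.
#'
#' @param intervals data frame with columns \code{start_h}, \code{end_h}
#'   (hours since recording start) and \code{state} (\code{"light"} or
#'   \code{"dark"}). Intervals must be contiguous, non-overlapping and cover
#'   \code{[0, duration)}.
#' @param zt0_offset_h hours to add to a recording hour to obtain Zeitgeber
#'   time, i.e. the ZT of recording hour 0. Default 0 (recording starts at
#'   lights-on).
#' @return An object of class \code{light_schedule} with fields
#'   \code{intervals}, \code{zt0_offset_h} and \code{duration_h}.
#' @seealso [ld_schedule()], [constant_schedule()]
#' @export
light_schedule <- function(intervals, zt0_offset_h = 0) {
  stopifnot(is.data.frame(intervals),
            all(c("start_h", "end_h", "state") %in% names(intervals)))
  intervals <- intervals[order(intervals$start_h), , drop = FALSE]
  if (nrow(intervals) == 0L) stop("schedule must contain at least one interval")
  if (!all(intervals$state %in% c("light", "dark"))) {
    stop("schedule states must be 'light' or 'dark'")
  }
  if (intervals$start_h[1] != 0) stop("schedule must start at hour 0")
  if (any(intervals$end_h <= intervals$start_h)) {
    stop("schedule intervals must have positive length")
  }
  if (nrow(intervals) > 1L) {
    gaps <- intervals$start_h[-1L] - intervals$end_h[-nrow(intervals)]
    if (any(abs(gaps) > 1e-9)) {
      stop("schedule intervals must be contiguous and non-overlapping")
    }
  }
  structure(
    list(intervals = intervals,
         zt0_offset_h = zt0_offset_h %% 24,
         duration_h = intervals$end_h[nrow(intervals)]),
    class = "light_schedule"
  )
}

#' Standard alternating light:dark schedule
#'
#' @param duration_h total recorded hours.
#' @param light_h,dark_h lengths of the light and dark phases (default 12:12).
#' @param zt0_offset_h ZT of recording hour 0 (default 0: start at lights-on).
#' @return A \code{light_schedule}.
#' @export
ld_schedule <- function(duration_h, light_h = 12, dark_h = 12,
                        zt0_offset_h = 0) {
  stopifnot(duration_h > 0, light_h > 0, dark_h > 0)
  starts <- c()
  states <- c()
  t <- 0
  lights_on <- TRUE
  while (t < duration_h) {
    starts <- c(starts, t)
    states <- c(states, if (lights_on) "light" else "dark")
    t <- t + if (lights_on) light_h else dark_h
    lights_on <- !lights_on
  }
  ends <- pmin(c(starts[-1L], t), duration_h)
  light_schedule(data.frame(start_h = starts, end_h = ends, state = states),
                 zt0_offset_h = zt0_offset_h)
}

#' Constant-condition schedule (DD or LL free-run)
#'
#' @param duration_h recorded hours.
#' @param state \code{"dark"} (DD) or \code{"light"} (LL).
#' @param zt0_offset_h ZT of recording hour 0, i.e. subjective time carried
#'   over from entrainment.
#' @return A \code{light_schedule} with a single interval.
#' @export
constant_schedule <- function(duration_h, state = c("dark", "light"),
                              zt0_offset_h = 0) {
  state <- match.arg(state)
  light_schedule(
    data.frame(start_h = 0, end_h = duration_h, state = state),
    zt0_offset_h = zt0_offset_h
  )
}

#' Map recording hours to Zeitgeber time
#'
#' @param schedule a \code{light_schedule}.
#' @param hour recording hour(s) (bin start).
#' @return ZT in \code{[0, 24)}.
#' @export
zt_of_hour <- function(schedule, hour) {
  stopifnot(inherits(schedule, "light_schedule"))
  (hour + schedule$zt0_offset_h) %% 24
}

# state ("light"/"dark") of each hourly bin [h, h+1)
schedule_states_hourly <- function(schedule, duration_h) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (schedule$duration_h < duration_h - 1e-9) {
    stop("schedule does not cover the trace duration")
  }
  mid <- seq_len(duration_h) - 0.5
  iv <- schedule$intervals
  idx <- findInterval(mid, iv$start_h)
  iv$state[idx]
}

#' Read a light schedule from a YAML config
#'
#' The config is a structured text file with a \code{zt0_offset_h} scalar and
#' an \code{intervals} list, each entry holding \code{start_h}, \code{end_h}
#' and \code{state}.
#'
#' @param path file path.
#' @return A \code{light_schedule}.
#' @export
read_light_schedule <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$intervals)) {
    stop("schedule config '", path, "' has no 'intervals' entry")
  }
  iv <- do.call(rbind, lapply(cfg$intervals, function(x) {
    data.frame(start_h = as.numeric(x$start_h),
               end_h = as.numeric(x$end_h),
               state = as.character(x$state))
  }))
  light_schedule(iv, zt0_offset_h = if (is.null(cfg$zt0_offset_h)) 0
                 else as.numeric(cfg$zt0_offset_h))
}

#' Write a light schedule to a YAML config
#'
#' @param schedule a \code{light_schedule}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_light_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "light_schedule"))
  iv <- schedule$intervals
  yaml::write_yaml(
    list(zt0_offset_h = schedule$zt0_offset_h,
         intervals = lapply(seq_len(nrow(iv)), function(i) {
           list(start_h = iv$start_h[i], end_h = iv$end_h[i],
                state = iv$state[i])
         })),
    path)
  invisible(path)
}
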