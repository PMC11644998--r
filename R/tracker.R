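# Minute-level tracker features derived from a wrist acceleration stream.
#
# The deviation signal is |a_mag - 1 g| (acceleration magnitude minus gravity,
# rectified): zero at rest, positive during motion. The tracker's own internal
# formula is proprietary; this definition is the package's documented stand-in
# and is used consistently by the synthetic cohort and the models.

tl_dev <- function(accel) abs(accel$a_mag - 1)

tl_minute_slice <- function(accel, minute_start, minute_s = 60, closed_right = FALSE) {
  eps <- 1e-9
  t <- accel$t
  lo <- findInterval(minute_start - eps, t) + 1L
  hi <- findInterval(minute_start + minute_s + (if (closed_right) eps else -eps), t)
  if (lo > hi) integer(0) else lo:hi
}

#' Activity time within one minute
#'
#' Seconds per minute during which the acceleration-magnitude deviation
#' exceeds (strictly) the activity gate, 50 mG by default. Computed as
#' (number of samples above gate) / sample rate.
#'
#' @param accel A \code{wrist_accel_series} fully covering the minute.
#' @param minute_start Minute start time in seconds.
#' @param threshold Gate in g (default 0.050).
#' @return Seconds in [0, 60].
#' @export
activity_time <- function(accel, minute_start, threshold = 0.050) {
  rate <- attr(accel, "sample_rate") %||% 25
  idx <- tl_minute_slice(accel, minute_start)
  if (length(idx) != rate * 60) {
    tl_data_error(sprintf("minute at %g s is only partially covered (%d of %d samples)",
                          minute_start, length(idx), rate * 60))
  }
  # strict "exceeds the gate", with a 1e-12 guard against representation
  # noise putting an exactly-at-gate deviation infinitesimally above it
  sum(tl_dev(accel)[idx] - threshold > 1e-12) / rate
}

#' Activity level (proportional integration) within one minute
#'
#' Area under the rectified acceleration-deviation curve over the minute
#' (trapezoidal rule), in g*s. This is the proportional-integration measure of
#' motion vigor exported by consumer trackers.
#'
#' @inheritParams activity_time
#' @return Activity level in g*s, nonnegative.
#' @export
activity_level <- function(accel, minute_start) {
  rate <- attr(accel, "sample_rate") %||% 25
  n_open <- length(tl_minute_slice(accel, minute_start))
  if (n_open != rate * 60) {
    tl_data_error(sprintf("minute at %g s is only partially covered (%d of %d samples)",
                          minute_start, n_open, rate * 60))
  }
  idx <- tl_minute_slice(accel, minute_start, closed_right = TRUE)
  pracma::trapz(accel$t[idx], tl_dev(accel)[idx])
}

#' Scale step count and activity time by activity level
#'
#' @param step_count Steps in the minute.
#' @param activity_time Seconds of activity in the minute.
#' @param activity_level Activity level in g*s.
#' @return Named list with \code{scaled_steps} and \code{scaled_activity}.
#' @export
scale_features <- function(step_count, activity_time, activity_level) {
  if (any(step_count < 0) || any(activity_time < 0) || any(activity_level < 0)) {
    tl_validation_error("scale_features inputs must be nonnegative")
  }
  list(scaled_steps = step_count * activity_level,
       scaled_activity = activity_time * activity_level)
}

#' Assemble the five-feature tracker minute table
#'
#' Derives activity time and activity level for every minute of the wrist
#' stream, combines them with the per-minute step counts, and returns a
#' validated \code{tracker_minute_table}.
#'
#' @param accel A \code{wrist_accel_series} covering whole minutes, starting
#'   on a minute boundary.
#' @param step_counts Integer vector of steps per minute, one per minute of
#'   the stream.
#' @param threshold Activity-time gate in g (default 0.050).
#' @return A \code{tracker_minute_table}.
#' @export
build_minute_table <- function(accel, step_counts, threshold = 0.050) {
  rate <- attr(accel, "sample_rate") %||% 25
  n <- nrow(accel)
  if (n == 0) tl_data_error("empty wrist stream")
  t0 <- accel$t[1]
  if (abs(t0 %% 60) > 1e-9) tl_data_error("wrist stream must start on a minute boundary")
  n_min <- length(step_counts)
  minute_start <- t0 + 60 * (seq_len(n_min) - 1)
  per_min <- rate * 60
  dev <- tl_dev(accel)
  if (n == n_min * per_min &&
      max(abs(accel$t - (t0 + (seq_len(n) - 1) / rate))) <= 1e-9) {
    # fast path: contiguous uniform stream -> reshape by minute
    mdev <- matrix(dev, nrow = per_min)
    at <- colSums(mdev - threshold > 1e-12) / rate
    # trapezoid with the next minute's first sample closing each minute
    first_next <- c(mdev[1, -1], NA)
    al <- (colSums(mdev) - mdev[1, ] / 2 + first_next / 2) / rate
    al[n_min] <- pracma::trapz(accel$t[((n_min - 1) * per_min + 1):n],
                               dev[((n_min - 1) * per_min + 1):n])
  } else {
    at <- vapply(minute_start, function(m0) activity_time(accel, m0, threshold), numeric(1))
    al <- vapply(minute_start, function(m0) activity_level(accel, m0), numeric(1))
  }
  tracker_minute_table(minute_start, at, step_counts, al)
}
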