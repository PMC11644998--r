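# Domain types. All are thin S3 classes over data.frames / lists with strict
# validators; validators raise typed conditions (see utils.R) so that any
# invariant violation is observable and testable.

#' Insole force / center-of-pressure time series
#'
#' A uniformly sampled recording of total plantar normal force and the
#' longitudinal center of pressure (CoP) from one pressure insole. Time is in
#' seconds since the start of the recording day; samples must lie on the
#' \code{1/sample_rate} grid and be strictly increasing, but rows may be absent
#' (missing wear time is represented by absent rows, never by sentinel values).
#'
#' @param t Sample times in seconds since day start.
#' @param force Total plantar normal force in newtons; must be nonnegative.
#' @param cop Longitudinal center of pressure in meters measured from the back
#'   of the insole. Must be finite wherever \code{force > 0}.
#' @param sample_rate Sampling rate in Hz (default 25).
#' @param insole_length Optional insole length in meters; when given, CoP is
#'   checked to lie within \code{[0, insole_length]}.
#' @param validate Run the validator (default \code{TRUE}).
#' @return An object of class \code{insole_series} (a data.frame with columns
#'   \code{t}, \code{force}, \code{cop}).
#' @export
insole_series <- function(t, force, cop, sample_rate = 25, insole_length = NULL,
                          validate = TRUE) {
  x <- structure(
    data.frame(t = as.numeric(t), force = as.numeric(force), cop = as.numeric(cop)),
    class = c("insole_series", "data.frame"),
    sample_rate = sample_rate
  )
  if (validate) validate_insole_series(x, insole_length = insole_length)
  x
}

#' Validate an insole series
#'
#' @param x An \code{insole_series}.
#' @param insole_length Optional insole length in meters for the CoP range check.
#' @return \code{x}, invisibly; raises a typed error on any violated invariant.
#' @export
validate_insole_series <- function(x, insole_length = NULL) {
  if (!all(c("t", "force", "cop") %in% names(x))) {
    tl_format_error("insole series must have columns t, force, cop")
  }
  rate <- attr(x, "sample_rate") %||% 25
  if (nrow(x) > 0) {
    d <- diff(x$t)
    if (any(d <= 0)) {
      i <- which(d <= 0)[1] + 1L
      tl_data_error(sprintf("non-monotone time at row %d", i), row = i)
    }
    k <- x$t * rate
    if (max(abs(x$t - round(k) / rate)) > 1e-9) {
      tl_data_error(sprintf("sample times off the 1/%g s grid", rate))
    }
    if (any(!is.finite(x$force)) || any(x$force < 0)) {
      tl_validation_error("force must be finite and nonnegative")
    }
    loaded <- x$force > 0
    if (any(loaded & !is.finite(x$cop))) {
      tl_validation_error("cop must be finite wherever force > 0")
    }
    if (!is.null(insole_length)) {
      ok <- !is.finite(x$cop) | (x$cop >= -1e-12 & x$cop <= insole_length + 1e-12)
      if (!all(ok)) {
        tl_validation_error("cop outside [0, insole_length]")
      }
    }
  }
  invisible(x)
}

#' Per-minute fitness tracker metric table
#'
#' One row per minute of the five wrist-tracker features: activity time
#' (seconds with acceleration deviation above the 50 mG gate), step count,
#' activity level (proportional-integration area in g*s), and the two scaled
#' features \code{scaled_steps = step_count * activity_level} and
#' \code{scaled_activity = activity_time * activity_level}.
#'
#' @param minute_start Minute start times in seconds since day start (multiples
#'   of 60, strictly increasing by 60).
#' @param activity_time Seconds per minute above the activity gate, in [0, 60].
#' @param step_count Nonnegative integer steps per minute.
#' @param activity_level Nonnegative activity magnitude in g*s.
#' @param scaled_steps,scaled_activity Optional; computed from their defining
#'   products when omitted.
#' @param validate Run the validator (default \code{TRUE}).
#' @return An object of class \code{tracker_minute_table}.
#' @export
tracker_minute_table <- function(minute_start, activity_time, step_count,
                                 activity_level, scaled_steps = NULL,
                                 scaled_activity = NULL, validate = TRUE) {
  activity_level <- as.numeric(activity_level)
  x <- structure(
    data.frame(
      minute_start = as.numeric(minute_start),
      activity_time = as.numeric(activity_time),
      step_count = as.numeric(step_count),
      activity_level = activity_level,
      scaled_steps = as.numeric(scaled_steps %||% (as.numeric(step_count) * activity_level)),
      scaled_activity = as.numeric(scaled_activity %||% (as.numeric(activity_time) * activity_level))
    ),
    class = c("tracker_minute_table", "data.frame")
  )
  if (validate) validate_tracker_minute_table(x)
  x
}

#' Validate a tracker minute table
#'
#' @param x A \code{tracker_minute_table}.
#' @return \code{x}, invisibly; raises a typed error on any violated invariant.
#' @export
validate_tracker_minute_table <- function(x) {
  need <- c("minute_start", "activity_time", "step_count", "activity_level",
            "scaled_steps", "scaled_activity")
  if (!all(need %in% names(x))) {
    tl_format_error(sprintf("tracker table missing column(s): %s",
                            paste(setdiff(need, names(x)), collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(abs(x$minute_start %% 60) > 1e-9 & abs(x$minute_start %% 60 - 60) > 1e-9)) {
    tl_validation_error("minute_start values must be multiples of 60 s")
  }
  if (nrow(x) > 1 && any(abs(diff(x$minute_start) - 60) > 1e-9)) {
    tl_validation_error("minute_start must increase in steps of exactly 60 s")
  }
  if (any(x$activity_time < 0 | x$activity_time > 60)) {
    tl_validation_error("activity_time outside [0, 60] s")
  }
  if (any(x$step_count < 0) || any(abs(x$step_count - round(x$step_count)) > 1e-9)) {
    tl_validation_error("step_count must be a nonnegative integer")
  }
  if (any(x$activity_level < 0)) {
    tl_validation_error("activity_level must be nonnegative")
  }
  tol <- 1e-9 * pmax(1, abs(x$scaled_steps))
  if (any(abs(x$scaled_steps - x$step_count * x$activity_level) > tol)) {
    tl_validation_error("scaled_steps != step_count * activity_level")
  }
  tol <- 1e-9 * pmax(1, abs(x$scaled_activity))
  if (any(abs(x$scaled_activity - x$activity_time * x$activity_level) > tol)) {
    tl_validation_error("scaled_activity != activity_time * activity_level")
  }
  invisible(x)
}

#' Participant metadata
#'
#' Anthropometrics and insole geometry needed by the tibia-force model:
#' body mass, the measured horizontal distance from the back of the insole to
#' the ankle joint center (x), the Achilles tendon moment arm (r, default
#' 5 cm), and the insole length.
#'
#' @param participant_id Character identifier.
#' @param body_mass Body mass in kg (> 0).
#' @param ankle_offset_x Back-of-insole to ankle-joint-center distance, m.
#' @param insole_length Insole length, m; must exceed \code{ankle_offset_x}.
#' @param achilles_moment_arm_r Achilles tendon moment arm, m (default 0.05).
#' @return An object of class \code{participant_meta}.
#' @export
participant_meta <- function(participant_id, body_mass, ankle_offset_x,
                             insole_length, achilles_moment_arm_r = 0.05) {
  x <- structure(
    list(
      participant_id = as.character(participant_id),
      body_mass = as.numeric(body_mass),
      ankle_offset_x = as.numeric(ankle_offset_x),
      insole_length = as.numeric(insole_length),
      achilles_moment_arm_r = as.numeric(achilles_moment_arm_r)
    ),
    class = "participant_meta"
  )
  if (x$body_mass <= 0) tl_validation_error("body_mass must be > 0")
  if (x$achilles_moment_arm_r <= 0) tl_validation_error("achilles_moment_arm_r must be > 0")
  if (x$ankle_offset_x <= 0 || x$ankle_offset_x >= x$insole_length) {
    tl_validation_error("ankle_offset_x must lie strictly inside (0, insole_length)")
  }
  x
}

#' One participant's full recording day
#'
#' Bundles metadata, the insole recording, the tracker minute table and, for
#' synthetic data only, ground-truth labels (true per-minute LS and the bout
#' schedule). The insole recording must lie within the tracker's day span.
#'
#' @param meta A \code{participant_meta}.
#' @param insole An \code{insole_series}.
#' @param tracker A \code{tracker_minute_table}.
#' @param ground_truth Optional list of synthetic ground truth.
#' @return An object of class \code{participant_day}.
#' @export
participant_day <- function(meta, insole, tracker, ground_truth = NULL) {
  validate_insole_series(insole, insole_length = meta$insole_length)
  validate_tracker_minute_table(tracker)
  if (nrow(insole) > 0 && nrow(tracker) > 0) {
    lo <- min(tracker$minute_start)
    hi <- max(tracker$minute_start) + 60
    if (min(insole$t) < lo - 1e-9 || max(insole$t) >= hi + 1e-9) {
      tl_validation_error("insole recording extends outside the tracker day span")
    }
  }
  structure(
    list(meta = meta, insole = insole, tracker = tracker, ground_truth = ground_truth),
    class = "participant_day"
  )
}

#' Per-minute loading stimulus series
#'
#' Minute-wise loading stimulus (LS) values with a per-minute provenance tag:
#' computed from the insole, estimated by the generic tracker model, or
#' estimated by the participant-calibrated tracker model. LS is in units of
#' bodyweight^m * s when the tibia force was normalized to bodyweights.
#'
#' @param minute_start Minute start times, seconds since day start.
#' @param ls Nonnegative stimulus values.
#' @param source One of \code{"insole"}, \code{"tracker_generic"},
#'   \code{"tracker_calibrated"} (scalar or per-row).
#' @param validate Run the validator (default \code{TRUE}).
#' @return An object of class \code{ls_series}.
#' @export
ls_series <- function(minute_start, ls, source = "insole", validate = TRUE) {
  x <- structure(
    data.frame(
      minute_start = as.numeric(minute_start),
      ls = as.numeric(ls),
      source = as.character(source),
      stringsAsFactors = FALSE
    ),
    class = c("ls_series", "data.frame")
  )
  if (validate) validate_ls_series(x)
  x
}

#' Validate a loading-stimulus series
#'
#' @param x An \code{ls_series}.
#' @return \code{x}, invisibly.
#' @export
validate_ls_series <- function(x) {
  if (!all(c("minute_start", "ls", "source") %in% names(x))) {
    tl_format_error("ls series must have columns minute_start, ls, source")
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(!is.finite(x$ls)) || any(x$ls < 0)) {
    tl_validation_error("ls must be finite and nonnegative")
  }
  if (any(abs(x$minute_start %% 60) > 1e-9 & abs(x$minute_start %% 60 - 60) > 1e-9)) {
    tl_validation_error("minute_start values must be multiples of 60 s")
  }
  if (nrow(x) > 1 && any(diff(x$minute_start) <= 0)) {
    tl_validation_error("minute_start must be strictly increasing")
  }
  bad <- setdiff(unique(x$source), c("insole", "tracker_generic", "tracker_calibrated"))
  if (length(bad)) {
    tl_validation_error(sprintf("unknown ls source tag(s): %s", paste(bad, collapse = ", ")))
  }
  invisible(x)
}

#' Wrist acceleration magnitude series
#'
#' Uniformly sampled acceleration magnitude (including gravity) from a
#' wrist-worn tracker, in g. The deviation signal used by the minute metrics is
#' \code{abs(a_mag - 1)}.
#'
#' @param t Sample times, seconds since day start.
#' @param a_mag Acceleration magnitude in g, nonnegative.
#' @param sample_rate Sampling rate in Hz (default 25).
#' @return An object of class \code{wrist_accel_series}.
#' @export
wrist_accel_series <- function(t, a_mag, sample_rate = 25) {
  x <- structure(
    data.frame(t = as.numeric(t), a_mag = as.numeric(a_mag)),
    class = c("wrist_accel_series", "data.frame"),
    sample_rate = sample_rate
  )
  if (nrow(x) > 0) {
    if (any(x$a_mag < 0)) tl_validation_error("a_mag must be nonnegative")
    if (nrow(x) > 1 && any(diff(x$t) <= 0)) tl_data_error("non-monotone time in wrist series")
  }
  x
}
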