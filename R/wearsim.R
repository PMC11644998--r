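# Wear-time simulation: sliding insole-wear windows over each recorded day,
# tracker-based gap filling, combined DLS, and binned absolute-percent-error
# summaries.

#' Sliding-window schedule for simulated days
#'
#' Window lengths grow from \code{start_length} in \code{increment}-minute
#' steps up to the day length; each length slides across the day at the given
#' stride. The full-day window is always present (the zero-error anchor).
#' When \code{stride} is \code{NULL} it is auto-selected per day as the
#' largest stride whose schedule still contains at least \code{target[1]}
#' windows, so a 9-10 h day yields on the order of 300-400 simulated days.
#'
#' @param day_length Day length in minutes.
#' @param start_length First window length in minutes (default 30).
#' @param increment Window growth per pass in minutes (default 5).
#' @param stride Slide step in minutes, or \code{NULL} for auto.
#' @param target Length-2 target range for the auto stride (default
#'   \code{c(300, 400)}).
#' @return Data.frame with columns \code{start} and \code{length} (minutes).
#' @export
window_schedule <- function(day_length, start_length = 30, increment = 5,
                            stride = NULL, target = c(300, 400)) {
  if (day_length < start_length) {
    tl_validation_error("day_length must be >= the starting window length")
  }
  if (!is.null(stride) && stride <= 0) tl_validation_error("stride must be positive")
  lengths <- seq(start_length, day_length, by = increment)
  count_for <- function(s) sum(floor((day_length - lengths) / s) + 1)
  if (is.null(stride)) {
    cand <- seq_len(day_length)
    counts <- vapply(cand, count_for, numeric(1))
    ok <- which(counts >= target[1])
    stride <- if (length(ok)) max(ok) else 1L
  }
  rows <- lapply(lengths, function(L) {
    data.frame(start = seq(0, day_length - L, by = stride), length = L)
  })
  out <- do.call(rbind, rows)
  if (!any(out$start == 0 & out$length == day_length)) {
    out <- rbind(out, data.frame(start = 0, length = day_length))
  }
  out
}

#' Simulate one partial-wear day
#'
#' Treats the window as the period the insoles were worn: a participant
#' calibration model is fitted on the insole-covered minutes inside the
#' window, minutes inside the window take the insole LS, minutes outside take
#' clamped model predictions, and the combined DLS is compared with the
#' all-insole reference. If the window cannot support a calibration (fewer
#' than 2 usable minutes), the uncalibrated generic predictions are used as a
#' fallback and flagged. With \code{gap_fill = "generic"} the calibration
#' stage is skipped entirely (the paper-style generic-vs-calibrated
#' comparison).
#'
#' @param day A \code{participant_day}.
#' @param model_set A \code{tl_generic_set}.
#' @param window Length-2 numeric: window start and length, minutes from day
#'   start.
#' @param gap_fill \code{"calibrated"} (default) or \code{"generic"}.
#' @param config A \code{run_config}.
#' @param insole_ls,generic_ls Optional precomputed per-day series.
#' @return One-row data.frame (class \code{simulated_day}): participant,
#'   window placement, insole fraction of the day, combined and reference
#'   DLS, absolute percent error, and a flag (\code{"ok"},
#'   \code{"low_information"} or \code{"fallback_generic"}); \code{NULL}
#'   (with a warning) if the reference DLS is below 1e-9.
#' @export
simulate_day <- function(day, model_set, window, gap_fill = c("calibrated", "generic"),
                         config = run_config(), insole_ls = NULL, generic_ls = NULL) {
  gap_fill <- match.arg(gap_fill)
  if (is.null(insole_ls)) insole_ls <- day_insole_ls(day, config)
  if (is.null(generic_ls)) generic_ls <- predict_generic(model_set, day)
  minutes <- day$tracker$minute_start
  day_len <- length(minutes)
  w_start <- window[1]; w_len <- window[2]
  if (w_start < 0 || w_start + w_len > day_len + 1e-9) {
    tl_validation_error("window extends outside the day")
  }
  min_idx <- (minutes - minutes[1]) / 60
  inside <- min_idx >= w_start & min_idx < w_start + w_len

  ref <- compute_dls(insole_ls, m = config$m,
                     span = range(minutes))$dls
  if (ref < 1e-9) {
    warning(sprintf("participant %s: reference DLS below 1e-9; day excluded",
                    day$meta$participant_id))
    return(NULL)
  }

  flag <- "ok"
  if (gap_fill == "calibrated") {
    win_minutes <- minutes[inside]
    cal <- tryCatch(
      fit_calibration(day, generic_ls, win_minutes, config,
                      insole_ls = insole_ls,
                      seed = tl_child_seeds(config$seed, 1)),
      tibload_validation_error = function(e) NULL
    )
    if (is.null(cal)) {
      pred <- generic_ls$ls
      flag <- "fallback_generic"
    } else {
      pred <- predict_calibration(cal, day, generic_ls)$ls
      if (cal$low_information_flag) flag <- "low_information"
    }
  } else {
    pred <- generic_ls$ls
  }

  ls_combined <- pred
  m_ins <- match(minutes[inside], insole_ls$minute_start)
  ls_combined[inside][!is.na(m_ins)] <- insole_ls$ls[m_ins[!is.na(m_ins)]]
  dls_combined <- sum(pmax(ls_combined, 0))^(1 / (2 * config$m))
  ape <- abs(dls_combined - ref) / ref * 100

  structure(data.frame(
    participant_id = day$meta$participant_id,
    window_start_min = w_start,
    window_len_min = w_len,
    insole_fraction_pct = 100 * w_len / day_len,
    dls_combined = dls_combined,
    dls_reference = ref,
    ape_pct = ape,
    flag = flag,
    stringsAsFactors = FALSE
  ), class = c("simulated_day", "data.frame"))
}

#' Run the full wear-time simulation for one day
#'
#' Builds the window schedule for the day and simulates every window.
#'
#' @param day A \code{participant_day}.
#' @param model_set A \code{tl_generic_set}.
#' @param config A \code{run_config}.
#' @param gap_fill \code{"calibrated"} or \code{"generic"}.
#' @param insole_ls,generic_ls Optional precomputed series.
#' @return Data.frame of simulated-day rows.
#' @export
run_wear_sim <- function(day, model_set, config = run_config(),
                         gap_fill = "calibrated", insole_ls = NULL,
                         generic_ls = NULL) {
  if (is.null(insole_ls)) insole_ls <- day_insole_ls(day, config)
  if (is.null(generic_ls)) generic_ls <- predict_generic(model_set, day)
  day_len <- nrow(day$tracker)
  sched <- window_schedule(day_len, config$window_start_min,
                           config$window_increment_min, config$window_stride_min)
  rows <- lapply(seq_len(nrow(sched)), function(i) {
    simulate_day(day, model_set, c(sched$start[i], sched$length[i]),
                 gap_fill = gap_fill, config = config,
                 insole_ls = insole_ls, generic_ls = generic_ls)
  })
  do.call(rbind, rows)
}

#' Binned cross-participant summary of simulated days
#'
#' Bins simulated days by insole coverage into left-open, right-closed
#' \code{bin_width}\%-wide bins ((0-5\%], (5-10\%], ...); computes the mean
#' absolute percent error per participant per bin, then the cross-participant
#' mean and sample standard deviation of those per-participant means. Bins
#' with no simulated days are reported as \code{NA}, never zero.
#'
#' @param sim_days Data.frame of simulated-day rows.
#' @param bin_width Bin width in percent of the day (default 5).
#' @return A list of class \code{tl_binned_summary}: \code{summary}
#'   (bin edges, cross-participant mean and SD, participant count) and
#'   \code{per_participant} (participant x bin matrix of mean APE).
#' @export
summarize_sim <- function(sim_days, bin_width = 5) {
  if (is.null(sim_days) || nrow(sim_days) == 0) {
    tl_validation_error("no simulated days to summarize")
  }
  n_bins <- ceiling(100 / bin_width)
  bin <- pmin(pmax(ceiling(sim_days$insole_fraction_pct / bin_width), 1L), n_bins)
  pids <- sort(unique(sim_days$participant_id))
  per <- matrix(NA_real_, nrow = length(pids), ncol = n_bins,
                dimnames = list(pids, NULL))
  for (p in pids) {
    sel <- sim_days$participant_id == p
    means <- tapply(sim_days$ape_pct[sel], bin[sel], mean)
    per[p, as.integer(names(means))] <- means
  }
  mean_ape <- apply(per, 2, function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  sd_ape <- apply(per, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else stats::sd(v)
  })
  n_part <- apply(per, 2, function(v) sum(!is.na(v)))
  structure(list(
    summary = data.frame(
      bin_low_pct = (seq_len(n_bins) - 1) * bin_width,
      bin_high_pct = seq_len(n_bins) * bin_width,
      mean_ape = unname(mean_ape),
      sd_ape = unname(sd_ape),
      n_participants = unname(n_part)
    ),
    per_participant = per,
    bin_width = bin_width
  ), class = "tl_binned_summary")
}
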