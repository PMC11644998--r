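# Biomechanical core: tibia force from insole signals, minute-wise loading
# stimulus (LS), and the daily load stimulus (DLS) cumulative summary.

#' Tibia compression force from insole force and center of pressure
#'
#' Computes the per-sample tibia compression force from the total plantar
#' force F(t) and longitudinal center of pressure CoP(t):
#' \deqn{F_{Tibia}(t) = F(t) + (CoP(t) - x) \, F(t) / r}
#' where \code{x} is the horizontal distance from the back of the insole to
#' the ankle joint center and \code{r} is the Achilles tendon moment arm
#' (default 5 cm). The second term is the Achilles tendon force needed to
#' balance the external ankle moment; compression cannot be negative, so the
#' result is clamped at zero (CoP behind the ankle can otherwise drive it
#' negative at very low loads).
#'
#' @param insole An \code{insole_series}.
#' @param meta A \code{participant_meta} providing \code{ankle_offset_x},
#'   \code{achilles_moment_arm_r} and \code{body_mass}.
#' @param normalize If \code{TRUE} (default), express the result in
#'   bodyweights (\code{F / (9.81 * body_mass)}); otherwise newtons.
#' @return A \code{tibia_force_series} data.frame with columns \code{t} and
#'   \code{f_tibia}, on the same sample grid as the input.
#' @export
compute_tibia_force <- function(insole, meta, normalize = TRUE) {
  validate_insole_series(insole, insole_length = meta$insole_length)
  f <- insole$force
  # f == 0 rows contribute 0 regardless of (carried-forward) CoP
  ft <- f + (insole$cop - meta$ankle_offset_x) * f / meta$achilles_moment_arm_r
  ft[f == 0] <- 0
  ft <- pmax(ft, 0)
  if (normalize) ft <- ft / (G_ACCEL * meta$body_mass)
  structure(
    data.frame(t = insole$t, f_tibia = ft),
    class = c("tibia_force_series", "data.frame"),
    sample_rate = attr(insole, "sample_rate") %||% 25,
    normalized = normalize
  )
}

#' Minute-wise loading stimulus (LS)
#'
#' Trapezoidal integral of tibia force raised to the damage exponent
#' \code{m} over each half-open minute \code{[t0, t0 + 60)}. The sample
#' falling exactly on the right boundary (the next minute's first sample)
#' closes the integration interval, so a constant force over a fully covered
#' minute integrates over exactly 60 s. Minutes with fewer than
#' \code{coverage_frac} of their expected samples (default 90\%, i.e. 1350 of
#' 1500 at 25 Hz) are omitted from the output: they do not count as
#' insole-covered.
#'
#' @param tibia A \code{tibia_force_series} (normalized to bodyweights for
#'   LS in BW^m s).
#' @param minute_grid Minute start times in seconds; defaults to all whole
#'   minutes spanned by the series.
#' @param m Damage-weighting exponent (default 4); must be positive.
#' @param coverage_frac Minimum fraction of expected samples for a minute to
#'   count as covered (default 0.9).
#' @param minute_s Minute length in seconds (default 60).
#' @return An \code{ls_series} with source \code{"insole"}, one row per
#'   covered minute.
#' @export
compute_ls <- function(tibia, minute_grid = NULL, m = 4, coverage_frac = 0.9,
                       minute_s = 60) {
  if (!is.numeric(m) || length(m) != 1 || m <= 0) {
    tl_parameter_error("exponent m must be a positive scalar")
  }
  t <- tibia$t
  if (length(t) == 0) return(ls_series(numeric(0), numeric(0), character(0)))
  rate <- attr(tibia, "sample_rate") %||% 25
  if (is.null(minute_grid)) {
    minute_grid <- seq(floor(t[1] / minute_s), floor(t[length(t)] / minute_s)) * minute_s
  }
  y <- tibia$f_tibia^m
  eps <- 1e-9
  lo <- findInterval(minute_grid - eps, t) + 1L          # first sample >= t0
  hi_in <- findInterval(minute_grid + minute_s - eps, t) # last sample  <  t0+60
  hi_cl <- findInterval(minute_grid + minute_s + eps, t) # last sample  <= t0+60
  expected <- rate * minute_s
  covered <- (hi_in - lo + 1L) >= coverage_frac * expected
  out_min <- minute_grid[covered]
  out_ls <- vapply(which(covered), function(j) {
    idx <- lo[j]:hi_cl[j]
    if (length(idx) < 2) return(0)
    pracma::trapz(t[idx], y[idx])
  }, numeric(1))
  ls_series(out_min, out_ls, source = "insole")
}

#' Daily load stimulus (DLS)
#'
#' Cumulative-damage summary of a complete day of minute-wise loading
#' stimulus values, treating every minute as a discrete task with one cycle:
#' \deqn{DLS = \left(\sum_j LS_j\right)^{1/(2m)}}
#' The series must be complete over its span (every minute present); gap-fill
#' with tracker estimates first if insoles were not worn all day.
#'
#' @param ls An \code{ls_series} covering every minute of the evaluation span.
#' @param m Damage-weighting exponent (default 4).
#' @param span Optional length-2 vector (first, last minute start in seconds)
#'   defining the required span; defaults to the series' own range.
#' @return A list of class \code{dls_value} with elements \code{dls},
#'   \code{m}, and \code{n_minutes}.
#' @export
compute_dls <- function(ls, m = 4, span = NULL) {
  if (!is.numeric(m) || length(m) != 1 || m <= 0) {
    tl_parameter_error("exponent m must be a positive scalar")
  }
  validate_ls_series(ls)
  if (nrow(ls) == 0) tl_incomplete_error("cannot compute DLS from an empty series")
  span <- span %||% range(ls$minute_start)
  need <- seq(span[1], span[2], by = 60)
  missing <- setdiff(need, ls$minute_start)
  if (length(missing)) {
    tl_incomplete_error(sprintf(
      "LS series is missing %d minute(s) in its span (first at %g s); gap-fill before computing DLS",
      length(missing), min(missing)))
  }
  structure(
    list(dls = sum(ls$ls)^(1 / (2 * m)), m = m, n_minutes = nrow(ls)),
    class = "dls_value"
  )
}

#' @method print dls_value
#' @export
print.dls_value <- function(x, ...) {
  cat(sprintf("DLS = %.6g (m = %g, %d minutes)\n", x$dls, x$m, x$n_minutes))
  invisible(x)
}
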