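# Run configuration: defaults, merging, validation, YAML loading.

#' Default synthetic-cohort configuration
#'
#' Parameters of the synthetic study-day generator. The defaults emulate the
#' study conditions: 8 participants wearing a right insole (25 Hz) and a wrist
#' tracker for 9-10 h, with two ~20-min in-lab exercise bouts (morning and
#' afternoon), bout-structured free-living activity, participant-specific
#' arm-swing gains (lognormal across the cohort) and sedentary hand-gesture
#' noise. The \code{"noisefree"} preset switches off every stochastic
#' perturbation and restricts loading to walking bouts; it is intended for
#' parameter-recovery validation, where the tracker-to-LS relation is exactly
#' linear and calibrated models should recover LS to numerical precision.
#'
#' @param preset \code{"default"} or \code{"noisefree"}.
#' @param ... Named overrides of individual fields; unknown names are an error.
#' @return A named list of class \code{cohort_config}.
#' @export
cohort_config <- function(preset = c("default", "noisefree"), ...) {
  preset <- match.arg(preset)
  base <- list(
    n_participants = 8L,
    day_length_range_min = c(540, 600),     # minutes; 9-10 h
    sample_rate = 25,                        # Hz, insole and wrist
    body_mass_range_kg = c(55, 90),
    insole_length_range_m = c(0.24, 0.28),
    ankle_offset_x_range_m = c(0.05, 0.07),
    achilles_moment_arm_r_m = 0.05,
    cadence_range_spm = c(105, 120),         # steps/min, both feet, walking
    peak_vgrf_range_bw = c(1.1, 1.3),        # per-step peak vertical force
    run_multiplier_range = c(1.5, 2.0),      # force multiplier, vigorous bouts
    run_cadence_factor = 1.3,
    stance_walk_s = 0.6,
    stance_run_s = 0.35,
    standing_force_bw = 0.5,                 # single-leg share of quiet standing
    wrist_gain_sdlog = 0.5,                  # lognormal arm-swing gain spread
    gesture_rate_range_per_min = c(0, 6),    # sedentary gesture events/min
    gesture_amp_range_g = c(0.15, 0.35),
    gesture_dur_s = 2,
    walk_arm_amp_g = 0.12,
    run_arm_amp_g = 0.35,
    arm_noise_sd_g = 0.015,                  # below the 50 mG gate
    amplitude_cv = 0.08,                     # per-step lognormal force noise
    step_jitter_s = 0.03,
    step_miss_rate = 0.03,                   # tracker step-counter miss rate
    p_bout = c(sedentary = 0.55, standing = 0.15, walking = 0.25, vigorous = 0.05),
    bout_dur_sedentary_min = c(10, 30),
    bout_dur_standing_min = c(5, 10),
    bout_dur_walking_min = c(5, 15),
    bout_dur_vigorous_min = c(4, 8),
    exercise_bouts = TRUE,
    exercise_len_min = 20
  )
  if (preset == "noisefree") {
    base$wrist_gain_sdlog <- 0.5   # gains still differ; the *relation* is noise-free
    base$gesture_rate_range_per_min <- c(0, 0)
    base$arm_noise_sd_g <- 0
    base$amplitude_cv <- 0
    base$step_jitter_s <- 0
    base$step_miss_rate <- 0
    base$cadence_range_spm <- c(100, 100)  # 50 steps/min per foot, 1.2 s period
    base$p_bout <- c(sedentary = 0.6, standing = 0, walking = 0.4, vigorous = 0)
    base$exercise_bouts <- FALSE
  }
  user <- list(...)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    tl_validation_error(sprintf("unknown cohort config key(s): %s",
                                paste(unknown, collapse = ", ")))
  }
  base[names(user)] <- user
  cfg <- structure(base, class = "cohort_config", preset = preset)
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_participants < 1) tl_validation_error("n_participants must be >= 1")
  rng <- function(nm) {
    v <- cfg[[nm]]
    if (length(v) != 2 || any(!is.finite(v)) || v[1] > v[2]) {
      tl_validation_error(sprintf("%s must be a nondecreasing length-2 range", nm))
    }
  }
  for (nm in c("day_length_range_min", "body_mass_range_kg", "insole_length_range_m",
               "ankle_offset_x_range_m", "cadence_range_spm", "peak_vgrf_range_bw",
               "run_multiplier_range", "gesture_rate_range_per_min",
               "gesture_amp_range_g")) rng(nm)
  if (cfg$sample_rate <= 0) tl_validation_error("sample_rate must be > 0")
  if (any(cfg$p_bout < 0) || sum(cfg$p_bout) <= 0) {
    tl_validation_error("p_bout must be nonnegative with positive sum")
  }
  if (!identical(sort(names(cfg$p_bout)),
                 sort(c("sedentary", "standing", "walking", "vigorous")))) {
    tl_validation_error("p_bout must name sedentary, standing, walking, vigorous")
  }
  invisible(cfg)
}

#' Run configuration
#'
#' Assembles the configuration shared by the whole pipeline, filling defaults:
#' damage exponent \code{m = 4}, Achilles moment arm 0.05 m, 25 Hz insole
#' sampling, 60 s minutes, a wear-time window schedule starting at 30 min and
#' growing in 5-min increments, 5\% coverage bins, and the LASSO
#' hyper-parameter grid. Unknown keys and out-of-range values are errors.
#'
#' @param ... Named overrides; \code{cohort} may be a list of cohort overrides
#'   or a \code{cohort_config}.
#' @return A named list of class \code{run_config}.
#' @export
run_config <- function(...) {
  base <- list(
    m = 4,                         # damage-weighting exponent
    achilles_moment_arm_r = 0.05,  # m
    sample_rate = 25,              # Hz
    minute_s = 60,
    noise_floor_n = 1,             # N; below this, CoP is carried forward
    coverage_frac = 0.9,           # minute counts as insole-covered at >= 90%
    normalize = "bw",              # "bw" or "newton" tibia-force scale
    log1p_target = FALSE,          # optional log1p transform of the LS target
    window_start_min = 30,
    window_increment_min = 5,
    window_stride_min = NULL,      # NULL = auto, targeting 300-400 windows/day
    bin_width_pct = 5,
    n_lambda = 12,
    lambda_min_ratio = 1e-3,
    lambda_include_zero = TRUE,
    nfolds = 5,
    low_information_min_loaded = 10,
    seed = 1L,
    cohort = cohort_config()
  )
  user <- list(...)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    tl_validation_error(sprintf("unknown config key(s): %s",
                                paste(unknown, collapse = ", ")))
  }
  if (!is.null(user$cohort) && !inherits(user$cohort, "cohort_config")) {
    user$cohort <- do.call(cohort_config, as.list(user$cohort))
  }
  base[names(user)] <- user
  cfg <- structure(base, class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  pos <- function(nm) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0) {
      tl_validation_error(sprintf("%s must be a positive scalar", nm))
    }
  }
  for (nm in c("m", "achilles_moment_arm_r", "sample_rate", "minute_s",
               "window_start_min", "window_increment_min", "bin_width_pct",
               "n_lambda", "nfolds")) pos(nm)
  if (!is.null(cfg$window_stride_min) && cfg$window_stride_min <= 0) {
    tl_validation_error("window_stride_min must be positive (or NULL for auto)")
  }
  if (cfg$noise_floor_n < 0) tl_validation_error("noise_floor_n must be >= 0")
  if (cfg$coverage_frac <= 0 || cfg$coverage_frac > 1) {
    tl_validation_error("coverage_frac must lie in (0, 1]")
  }
  if (cfg$bin_width_pct > 100) tl_validation_error("bin_width_pct must be <= 100")
  if (!cfg$normalize %in% c("bw", "newton")) {
    tl_validation_error("normalize must be 'bw' or 'newton'")
  }
  if (cfg$lambda_min_ratio <= 0 || cfg$lambda_min_ratio >= 1) {
    tl_validation_error("lambda_min_ratio must lie in (0, 1)")
  }
  invisible(cfg)
}

#' Load a run configuration from a YAML document
#'
#' An empty document yields all defaults. Unknown keys raise an error listing
#' them; out-of-range values raise validation errors.
#'
#' @param path Path to a YAML file.
#' @return A \code{run_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) tl_format_error(sprintf("config file not found: %s", path))
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) tl_format_error("config document must be a YAML mapping")
  do.call(run_config, doc)
}
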