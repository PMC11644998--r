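# Synthetic study-day generator.
#
# Produces day-long (9-10 h) right-insole and wrist-acceleration streams with
# ground truth. Loading is built from per-step half-sine vertical-force pulses
# with a heel-to-toe center-of-pressure progression; wrist motion carries a
# participant-specific arm-swing gain and sedentary gesture bursts, the two
# behaviors that make a generic wrist-to-LS model degrade across people while
# participant calibration recovers accuracy.

BOUT_TYPES <- c("sedentary", "standing", "walking", "vigorous", "exercise")

# Within an exercise bout, minutes cycle through a fixed moderate/vigorous
# pattern (a generic stand-in for a rehabilitation exercise battery).
EXERCISE_CYCLE <- c("walking", "walking", "vigorous", "standing")

#' Generate a bout schedule for one day
#'
#' Minute-aligned, non-overlapping bouts covering the whole day. When
#' \code{cfg$exercise_bouts} is \code{TRUE}, two \code{exercise_len_min}-long
#' exercise bouts are placed (one in the morning, one in the afternoon); the
#' remaining time is filled with sedentary / standing / walking / vigorous
#' bouts drawn from \code{cfg$p_bout} with durations from the per-type ranges.
#'
#' @param cfg A \code{cohort_config}.
#' @param day_len Day length in whole minutes.
#' @param seed RNG seed.
#' @return A data.frame (class \code{bout_schedule}) with columns
#'   \code{type}, \code{start_min}, \code{dur_min}; durations sum to
#'   \code{day_len} exactly.
#' @export
generate_schedule <- function(cfg = cohort_config(), day_len = 570, seed = 1L) {
  day_len <- as.integer(day_len)
  if (day_len < 1) tl_validation_error("day_len must be >= 1 minute")
  set.seed(seed)
  fixed <- NULL
  if (isTRUE(cfg$exercise_bouts)) {
    ex <- cfg$exercise_len_min
    if (day_len < 2 * ex + 120) {
      tl_validation_error("mandatory exercise bouts do not fit in the day length")
    }
    s1 <- sample(45:75, 1)
    s2_lo <- max(s1 + ex + 60, floor(day_len * 0.6))
    s2_hi <- min(day_len - ex, s2_lo + 30)
    if (s2_hi < s2_lo) tl_validation_error("mandatory exercise bouts do not fit in the day length")
    s2 <- sample(s2_lo:s2_hi, 1)
    fixed <- data.frame(type = "exercise", start_min = c(s1, s2), dur_min = ex)
  }
  gaps <- if (is.null(fixed)) {
    data.frame(start = 0, len = day_len)
  } else {
    data.frame(start = c(0, fixed$start_min + fixed$dur_min),
               len = c(fixed$start_min, day_len) - c(0, fixed$start_min + fixed$dur_min))
  }
  p <- cfg$p_bout / sum(cfg$p_bout)
  dur_rng <- list(sedentary = cfg$bout_dur_sedentary_min,
                  standing = cfg$bout_dur_standing_min,
                  walking = cfg$bout_dur_walking_min,
                  vigorous = cfg$bout_dur_vigorous_min)
  rows <- list()
  for (g in seq_len(nrow(gaps))) {
    cur <- gaps$start[g]
    left <- gaps$len[g]
    while (left > 0) {
      ty <- sample(names(p), 1, prob = p)
      r <- dur_rng[[ty]]
      d <- min(sample(seq(r[1], r[2]), 1), left)
      rows[[length(rows) + 1L]] <- data.frame(type = ty, start_min = cur, dur_min = d)
      cur <- cur + d
      left <- left - d
    }
  }
  sched <- rbind(do.call(rbind, rows), fixed)
  sched <- sched[order(sched$start_min), , drop = FALSE]
  rownames(sched) <- NULL
  stopifnot(sum(sched$dur_min) == day_len)
  structure(sched, class = c("bout_schedule", "data.frame"), day_len = day_len)
}

#' Per-minute activity type implied by a schedule
#'
#' Expands a bout schedule to one type per minute; exercise bouts expand to
#' their internal walking/vigorous/standing cycle.
#'
#' @param schedule A \code{bout_schedule}.
#' @return Character vector of length \code{day_len} with values in
#'   sedentary / standing / walking / vigorous.
#' @export
minute_types <- function(schedule) {
  day_len <- attr(schedule, "day_len")
  out <- character(day_len)
  for (i in seq_len(nrow(schedule))) {
    idx <- schedule$start_min[i] + seq_len(schedule$dur_min[i])
    ty <- schedule$type[i]
    out[idx] <- if (ty == "exercise") {
      rep_len(EXERCISE_CYCLE, schedule$dur_min[i])
    } else ty
  }
  out
}

# --- step model -------------------------------------------------------------

# Relative CoP path during stance: heel strike near the back of the insole
# progressing to the forefoot at toe-off, as a fraction of insole length.
COP_PATH <- c(from = 0.12, to = 0.82)
STANDING_COP_FRAC <- 0.45

# Step table for the locomotor minutes of a day. Single-leg (right-foot)
# stream: per-foot step rate is half the (both-feet) cadence.
tl_make_steps <- function(types, profile, cfg) {
  rows <- list()
  for (ty in c("walking", "vigorous")) {
    mins <- which(types == ty) - 1L
    if (!length(mins)) next
    cad <- profile$cadence * (if (ty == "vigorous") cfg$run_cadence_factor else 1)
    n_per_min <- max(1L, round(cad / 2))
    period <- 60 / n_per_min
    stance <- if (ty == "vigorous") cfg$stance_run_s else cfg$stance_walk_s
    peak_bw <- profile$peak_vgrf * (if (ty == "vigorous") profile$run_multiplier else 1)
    start <- rep(mins * 60, each = n_per_min) +
      rep((seq_len(n_per_min) - 1) * period, times = length(mins))
    if (cfg$step_jitter_s > 0) {
      start <- start + runif(length(start), -cfg$step_jitter_s, cfg$step_jitter_s)
      start <- pmax(start, 0)
    }
    amp <- peak_bw * G_ACCEL * profile$body_mass
    if (cfg$amplitude_cv > 0) {
      amp <- amp * exp(rnorm(length(start), 0, cfg$amplitude_cv))
    } else {
      amp <- rep(amp, length(start))
    }
    rows[[ty]] <- data.frame(start = start, stance = stance, peak_n = amp, type = ty)
  }
  steps <- do.call(rbind, rows)
  if (is.null(steps)) {
    return(data.frame(start = numeric(0), stance = numeric(0),
                      peak_n = numeric(0), type = character(0)))
  }
  steps[order(steps$start), , drop = FALSE]
}

# Dimensionless stance-shape integral: int_0^1 (sin(pi s) * g(s))^m ds with
# g(s) the tibia-force amplification along the CoP path. The per-step LS (in
# N^m s before bodyweight normalization) is peak^m * stance * C. Also returns
# the normalized cumulative profile H(u) for splitting steps that straddle a
# minute boundary.
tl_stance_shape <- function(profile, m, n_fine = 2048) {
  s <- (seq_len(n_fine) - 0.5) / n_fine
  cop <- profile$insole_length * (COP_PATH["from"] + diff(COP_PATH) * s)
  g <- 1 + (cop - profile$ankle_offset_x) / profile$achilles_moment_arm_r
  w <- (sin(pi * s) * pmax(g, 0))^m
  total <- mean(w)
  cum <- cumsum(w) / sum(w)
  list(C = total, H = stats::approxfun(c(0, s, 1), c(0, cum, 1), rule = 2))
}

#' Generate the insole recording for one day
#'
#' Per-step half-sine vertical-force pulses at the profile cadence with
#' heel-to-toe CoP progression during stance; quiet standing contributes a
#' constant single-leg force at a mid-foot CoP; sedentary minutes carry zero
#' force with the CoP carried forward. The returned series has two
#' attributes of ground truth: \code{true_ls} (per-minute LS of the
#' continuous-time force trajectory, in BW^m s, computed by fine midpoint
#' quadrature independent of the 25 Hz sampling) and \code{true_steps}
#' (per-minute step counts).
#'
#' @param schedule A \code{bout_schedule}.
#' @param profile Participant profile list (see \code{generate_cohort}).
#' @param cfg A \code{cohort_config}.
#' @param seed RNG seed.
#' @param m Damage exponent used for the ground-truth LS (default 4).
#' @return An \code{insole_series} covering the whole day at
#'   \code{cfg$sample_rate}.
#' @export
generate_insole <- function(schedule, profile, cfg = cohort_config(), seed = 1L,
                            m = 4) {
  set.seed(seed)
  day_len <- attr(schedule, "day_len")
  rate <- cfg$sample_rate
  types <- minute_types(schedule)
  n <- day_len * 60 * rate
  t <- (seq_len(n) - 1) / rate
  force <- numeric(n)
  cop <- rep(NA_real_, n)
  L <- profile$insole_length
  bwN <- G_ACCEL * profile$body_mass

  type_per_sample <- rep(types, each = 60 * rate)
  stand <- type_per_sample == "standing"
  stand_n <- cfg$standing_force_bw * bwN
  force[stand] <- stand_n
  cop[stand] <- STANDING_COP_FRAC * L

  steps <- tl_make_steps(types, profile, cfg)
  if (nrow(steps)) {
    k0 <- pmax(ceiling(steps$start * rate), 0)
    k1 <- pmin(floor((steps$start + steps$stance) * rate), n - 1)
    keep <- k1 >= k0
    k0 <- k0[keep]; k1 <- k1[keep]
    st <- steps[keep, , drop = FALSE]
    lens <- k1 - k0 + 1L
    idx <- sequence(lens, from = k0 + 1L)
    s <- (t[idx] - rep(st$start, lens)) / rep(st$stance, lens)
    pulse <- rep(st$peak_n, lens) * pmax(sin(pi * s), 0)
    force[idx] <- force[idx] + pulse
    cop[idx] <- L * (COP_PATH["from"] + diff(COP_PATH) * pmin(pmax(s, 0), 1))
  }
  cop <- tl_carry_cop(cop, force, noise_floor_n = 1)
  cop[is.na(cop)] <- STANDING_COP_FRAC * L

  # ground truth: per-minute LS of the continuous trajectory, in BW^m s
  true_ls <- numeric(day_len)
  if (nrow(steps)) {
    shapes <- list()
    for (ty in unique(steps$type)) shapes[[ty]] <- tl_stance_shape(profile, m)
    ls_step <- steps$peak_n^m * steps$stance *
      vapply(steps$type, function(ty) shapes[[ty]]$C, numeric(1))
    m0 <- floor(steps$start / 60)
    m1 <- floor((steps$start + steps$stance) / 60 - 1e-12)
    frac1 <- rep(1, nrow(steps))
    strad <- which(m1 > m0)
    for (i in strad) {
      u <- ((m0[i] + 1) * 60 - steps$start[i]) / steps$stance[i]
      frac1[i] <- shapes[[steps$type[i]]]$H(u)
    }
    add_by_min <- function(vals, mins) {
      keep <- mins >= 0 & mins <= day_len - 1 & vals > 0
      if (!any(keep)) return(numeric(day_len))
      agg <- rowsum(vals[keep], mins[keep])
      out <- numeric(day_len)
      out[as.integer(rownames(agg)) + 1L] <- agg[, 1]
      out
    }
    true_ls <- true_ls + add_by_min(ls_step * frac1, m0) +
      add_by_min(ls_step * (1 - frac1), m1)
    true_ls <- true_ls / bwN^m
  }
  g_stand <- 1 + (STANDING_COP_FRAC * L - profile$ankle_offset_x) /
    profile$achilles_moment_arm_r
  true_ls[types == "standing"] <- true_ls[types == "standing"] +
    60 * (cfg$standing_force_bw * max(g_stand, 0))^m

  true_steps <- as.integer(tabulate(floor(steps$start / 60) + 1L, nbins = day_len))

  out <- insole_series(t, force, cop, sample_rate = rate, insole_length = L)
  attr(out, "true_ls") <- true_ls
  attr(out, "true_steps") <- true_steps
  out
}

#' Generate the wrist acceleration stream for one day
#'
#' Locomotor minutes produce an oscillatory arm-swing deviation with
#' amplitude proportional to the participant's wrist gain and the bout
#' intensity; sedentary minutes produce hand-gesture bursts (half-sine, ~2 s)
#' at the participant's gesture rate with amplitudes above the 50 mG activity
#' gate; everything else is additive noise below the gate.
#'
#' @param schedule A \code{bout_schedule}.
#' @param profile Participant profile list.
#' @param cfg A \code{cohort_config}.
#' @param seed RNG seed.
#' @return A \code{wrist_accel_series} covering the whole day.
#' @export
generate_wrist <- function(schedule, profile, cfg = cohort_config(), seed = 1L) {
  set.seed(seed)
  day_len <- attr(schedule, "day_len")
  rate <- cfg$sample_rate
  types <- minute_types(schedule)
  n <- day_len * 60 * rate
  t <- (seq_len(n) - 1) / rate
  s <- numeric(n)
  type_per_sample <- rep(types, each = 60 * rate)

  for (ty in c("walking", "vigorous")) {
    idx <- which(type_per_sample == ty)
    if (!length(idx)) next
    cad <- profile$cadence * (if (ty == "vigorous") cfg$run_cadence_factor else 1)
    f_arm <- cad / 120  # one swing per stride
    amp <- profile$wrist_gain *
      (if (ty == "vigorous") cfg$run_arm_amp_g else cfg$walk_arm_amp_g)
    s[idx] <- s[idx] + amp * sin(2 * pi * f_arm * t[idx])
  }

  sed_min <- which(types == "sedentary") - 1L
  if (length(sed_min) && profile$gesture_rate > 0) {
    n_ev <- rpois(length(sed_min), profile$gesture_rate)
    total <- sum(n_ev)
    if (total > 0) {
      dur <- cfg$gesture_dur_s
      ev_min <- rep(sed_min, n_ev)
      ev_start <- ev_min * 60 + runif(total, 0, 60 - dur)
      ev_amp <- runif(total, cfg$gesture_amp_range_g[1], cfg$gesture_amp_range_g[2])
      k0 <- pmax(ceiling(ev_start * rate), 0)
      k1 <- pmin(floor((ev_start + dur) * rate), n - 1)
      lens <- k1 - k0 + 1L
      idx <- sequence(lens, from = k0 + 1L)
      u <- (t[idx] - rep(ev_start, lens)) / dur
      s[idx] <- s[idx] + rep(ev_amp, lens) * pmax(sin(pi * u), 0)
    }
  }
  if (cfg$arm_noise_sd_g > 0) s <- s + rnorm(n, 0, cfg$arm_noise_sd_g)
  wrist_accel_series(t, pmax(1 + s, 0), sample_rate = rate)
}

#' Generate a synthetic study cohort
#'
#' Draws participant profiles from the cohort configuration (body mass,
#' insole geometry, cadence, per-step force, a lognormal wrist arm-swing
#' gain, and a sedentary gesture rate), then assembles one full recording day
#' per participant: insole stream, wrist stream, the five-feature tracker
#' minute table (step counts carry the configured miss rate), and ground
#' truth (true per-minute LS, true steps, schedule, profile).
#'
#' @param cfg A \code{cohort_config}.
#' @param seed Master seed; all per-participant streams derive from it.
#' @param m Damage exponent for ground-truth LS (default 4).
#' @return List of \code{participant_day}, one per participant.
#' @export
generate_cohort <- function(cfg = cohort_config(), seed = 1L, m = 4) {
  n <- cfg$n_participants
  if (n < 2) tl_validation_error("generate_cohort needs n_participants >= 2")
  set.seed(seed)
  ru <- function(r, k = n) runif(k, r[1], r[2])
  profiles <- data.frame(
    participant_id = sprintf("P%02d", seq_len(n)),
    body_mass = ru(cfg$body_mass_range_kg),
    insole_length = ru(cfg$insole_length_range_m),
    ankle_offset_x = ru(cfg$ankle_offset_x_range_m),
    cadence = ru(cfg$cadence_range_spm),
    peak_vgrf = ru(cfg$peak_vgrf_range_bw),
    run_multiplier = ru(cfg$run_multiplier_range),
    wrist_gain = exp(rnorm(n, 0, cfg$wrist_gain_sdlog)),
    gesture_rate = ru(cfg$gesture_rate_range_per_min),
    day_len = sample(seq(cfg$day_length_range_min[1], cfg$day_length_range_min[2]),
                     n, replace = TRUE)
  )
  seeds <- matrix(tl_child_seeds(seed, 4 * n), nrow = n)
  days <- vector("list", n)
  for (i in seq_len(n)) {
    pr <- c(as.list(profiles[i, ]),
            achilles_moment_arm_r = cfg$achilles_moment_arm_r)
    sched <- generate_schedule(cfg, profiles$day_len[i], seed = seeds[i, 1])
    insole <- generate_insole(sched, pr, cfg, seed = seeds[i, 2], m = m)
    wrist <- generate_wrist(sched, pr, cfg, seed = seeds[i, 3])
    true_steps <- attr(insole, "true_steps")
    if (cfg$step_miss_rate > 0) {
      set.seed(seeds[i, 4])
      steps <- rbinom(length(true_steps), true_steps, 1 - cfg$step_miss_rate)
    } else {
      steps <- true_steps
    }
    tracker <- build_minute_table(wrist, steps)
    meta <- participant_meta(pr$participant_id, pr$body_mass, pr$ankle_offset_x,
                             pr$insole_length, pr$achilles_moment_arm_r)
    days[[i]] <- participant_day(
      meta, insole, tracker,
      ground_truth = list(ls = attr(insole, "true_ls"),
                          steps = true_steps,
                          schedule = sched,
                          profile = pr,
                          wrist = NULL)
    )
  }
  names(days) <- profiles$participant_id
  days
}
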