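# Shared fixture builders. Everything is generated in code; no stored data.

toy_meta <- function(id = "T01", body_mass = 70, x = 0.05, L = 0.26, r = 0.05) {
  participant_meta(id, body_mass, x, L, r)
}

# Tibia-force series with a constant level over whole minutes, including the
# closing boundary sample so each minute integrates over exactly 60 s.
const_tibia <- function(level_bw, n_minutes = 1, rate = 25) {
  t <- seq(0, n_minutes * 60, by = 1 / rate)
  structure(
    data.frame(t = t, f_tibia = rep(level_bw, length(t))),
    class = c("tibia_force_series", "data.frame"),
    sample_rate = rate, normalized = TRUE
  )
}

# Wrist stream with a given deviation |a-1| per minute (constant within each
# minute), covering length(dev_per_min) minutes at `rate`.
const_wrist <- function(dev_per_min, rate = 25) {
  n_min <- length(dev_per_min)
  t <- (seq_len(n_min * 60 * rate) - 1) / rate
  a <- 1 + rep(dev_per_min, each = 60 * rate)
  wrist_accel_series(t, a, sample_rate = rate)
}

# Small noise-free cohort: walking/sedentary only, exactly linear
# tracker-to-LS relation, short days to keep tests fast.
noisefree_cfg <- function(n = 2, day_len = c(360, 360)) {
  cohort_config("noisefree", n_participants = n, day_length_range_min = day_len)
}

# Small default-preset cohort (heterogeneous), shortened days, no mandatory
# exercise bouts so very short days remain feasible.
small_cfg <- function(n = 3, day_len = c(300, 310)) {
  cohort_config(n_participants = n, day_length_range_min = day_len,
                exercise_bouts = FALSE)
}
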