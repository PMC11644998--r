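test_that("insole files round-trip byte-identically through the canonical writer", {
  set.seed(7)
  n <- 200
  t <- (0:(n - 1)) / 25
  force <- pmax(0, 700 * sin(pi * (0:(n - 1)) / 15)) * rbinom(n, 1, 0.8)
  cop <- rep(0.12, n)
  cop[force > 0] <- runif(sum(force > 0), 0.05, 0.22)
  x <- insole_series(t, force, tibload:::tl_carry_cop(cop, force, 1),
                     sample_rate = 25, insole_length = 0.26)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_insole(x, p1)
  y <- read_insole(p1, meta = toy_meta())
  write_insole(y, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(y$t, x$t)
  expect_equal(y$force, x$force, tolerance = 1e-9)
})

test_that("insole reader rejects malformed headers and non-monotone time", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_s,force_n,cop_mm", "0,0,0.1"), p)
  err <- expect_error(read_insole(p), class = "tibload_format_error")
  expect_match(conditionMessage(err), "cop_m")

  writeLines(c("t_s,force_n,cop_m", "0,10,0.1", "0.08,10,0.1", "0.04,10,0.1"), p)
  err <- expect_error(read_insole(p), class = "tibload_data_error")
  expect_match(conditionMessage(err), "row 3")
})

test_that("reader carries CoP forward over unloaded samples", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_s,force_n,cop_m",
               "0,0,0.9", "0.04,500,0.15", "0.08,0.5,0.9", "0.12,600,0.2"), p)
  x <- read_insole(p, noise_floor_n = 1)
  # leading unloaded row takes the first loaded CoP; interior one the previous
  expect_equal(x$cop, c(0.15, 0.15, 0.15, 0.2))
})

test_that("tracker tables round-trip and validate ranges", {
  tab <- tracker_minute_table(minute_start = c(0, 60, 120),
                              activity_time = c(0, 30, 60),
                              step_count = c(0, 40, 55),
                              activity_level = c(0, 3.5, 7.25))
  p <- withr::local_tempfile(fileext = ".csv")
  write_tracker(tab, p)
  y <- read_tracker(p)
  expect_equal(as.data.frame(y), as.data.frame(tab), tolerance = 1e-12)

  expect_error(
    tracker_minute_table(0, activity_time = 61, step_count = 0, activity_level = 0),
    class = "tibload_validation_error"
  )
  expect_error(
    tracker_minute_table(c(0, 30), c(0, 0), c(0, 0), c(0, 0)),
    class = "tibload_validation_error"
  )
  expect_error(
    tracker_minute_table(0, 30, 10, 2, scaled_steps = 99),
    class = "tibload_validation_error"
  )
})

test_that("a header-only tracker file yields an empty table without error", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines("minute_start_s,activity_time_s,step_count,activity_level,scaled_steps,scaled_activity", p)
  tab <- read_tracker(p)
  expect_s3_class(tab, "tracker_minute_table")
  expect_identical(nrow(tab), 0L)
})

test_that("participant metadata round-trips through YAML", {
  meta <- toy_meta("P07", body_mass = 63.2, x = 0.061, L = 0.252)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_meta(meta, p)
  back <- read_meta(p)
  expect_equal(back, meta)
  expect_error(participant_meta("Q", 70, 0.3, insole_length = 0.26),
               class = "tibload_validation_error")
  expect_error(participant_meta("Q", -1, 0.05, insole_length = 0.26),
               class = "tibload_validation_error")
})

test_that("insole validator rejects mutated fixtures", {
  good <- insole_series(c(0, 0.04), c(10, 20), c(0.1, 0.1), insole_length = 0.26)
  bad <- good; bad$force[1] <- -5
  expect_error(validate_insole_series(bad), class = "tibload_validation_error")
  bad <- good; bad$cop <- c(0.5, 0.5)
  expect_error(validate_insole_series(bad, insole_length = 0.26),
               class = "tibload_validation_error")
  bad <- good; bad$t[2] <- 0.05  # off the 25 Hz grid
  expect_error(validate_insole_series(bad), class = "tibload_data_error")
  expect_error(ls_series(0, -1), class = "tibload_validation_error")
  expect_error(ls_series(0, 1, "telepathy"), class = "tibload_validation_error")
})

test_that("configuration defaults, overrides, and rejection of unknown keys", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", p)
  cfg <- load_config(p)
  expect_equal(cfg$m, 4)
  expect_equal(cfg$achilles_moment_arm_r, 0.05)
  expect_equal(cfg$sample_rate, 25)
  expect_equal(cfg$minute_s, 60)
  expect_equal(cfg$window_start_min, 30)
  expect_equal(cfg$window_increment_min, 5)
  expect_equal(cfg$bin_width_pct, 5)

  writeLines("m: 4\nwindow_start_min: 45", p)
  cfg <- load_config(p)
  expect_equal(cfg$window_start_min, 45)

  writeLines("exponent_m: 4", p)
  err <- expect_error(load_config(p), class = "tibload_validation_error")
  expect_match(conditionMessage(err), "exponent_m")

  writeLines("window_increment_min: -5", p)
  expect_error(load_config(p), class = "tibload_validation_error")
})

test_that("the configured exponent propagates into stimulus computations", {
  tib <- const_tibia(2, n_minutes = 1)
  for (m in c(2, 4)) {
    ls <- compute_ls(tib, minute_grid = 0, m = m)
    expect_equal(ls$ls, 60 * 2^m)
  }
})
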