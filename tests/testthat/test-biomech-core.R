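test_that("tibia force matches hand evaluation of the moment-balance model", {
  meta <- toy_meta(body_mass = 70, x = 0.05, L = 0.26, r = 0.05)
  ins <- insole_series(t = c(0, 0.04, 0.08, 0.12),
                       force = c(0, 700, 400, 700),
                       cop = c(0.15, 0.15, 0.05, 0.10),
                       insole_length = 0.26)
  tf <- compute_tibia_force(ins, meta, normalize = FALSE)
  # F + (CoP - x) F / r, hand-evaluated
  expect_equal(tf$f_tibia,
               c(0, 700 + 0.10 * 700 / 0.05, 400, 700 + 0.05 * 700 / 0.05),
               tolerance = 1e-9)
  # CoP = x removes the ankle-moment term entirely
  expect_identical(tf$f_tibia[3], 400)
  # bodyweight normalization
  tf_bw <- compute_tibia_force(ins, meta, normalize = TRUE)
  expect_equal(tf_bw$f_tibia, tf$f_tibia / (9.81 * 70), tolerance = 1e-12)
})

test_that("tibia force is clamped at zero when CoP sits behind the ankle", {
  meta <- toy_meta(x = 0.20, L = 0.26)
  ins <- insole_series(c(0, 0.04), c(50, 50), c(0.01, 0.01), insole_length = 0.26)
  tf <- compute_tibia_force(ins, meta, normalize = FALSE)
  expect_true(all(tf$f_tibia == 0))
})

test_that("LS closed forms: constant and zero force", {
  expect_equal(compute_ls(const_tibia(2), minute_grid = 0, m = 4)$ls, 960)
  expect_equal(compute_ls(const_tibia(0), minute_grid = 0, m = 4)$ls, 0)
  expect_error(compute_ls(const_tibia(1), m = -1), class = "tibload_parameter_error")
})

test_that("trapezoidal LS matches the analytic integral of a half-sine pulse", {
  T_st <- 0.6; A <- 4
  for (rate in c(25, 250)) {
    t <- seq(0, 60, by = 1 / rate)
    f <- ifelse(t <= T_st, A * sin(pi * t / T_st), 0)
    tib <- structure(data.frame(t = t, f_tibia = f),
                     class = c("tibia_force_series", "data.frame"),
                     sample_rate = rate, normalized = TRUE)
    ls <- compute_ls(tib, minute_grid = 0, m = 4)$ls
    analytic <- A^4 * (3 / 8) * T_st  # int sin^4 = 3T/8
    rel <- abs(ls - analytic) / analytic
    expect_lt(rel, 0.005)
    if (rate == 250) expect_lt(rel, 1e-5)  # converges with sampling rate
  }
})

test_that("LS and DLS are homogeneous in the force scale", {
  set.seed(11)
  t <- seq(0, 600, by = 1 / 25)
  f <- pmax(0, sin(2 * pi * t / 7)) * runif(length(t), 0.5, 3)
  tib <- structure(data.frame(t = t, f_tibia = f),
                   class = c("tibia_force_series", "data.frame"),
                   sample_rate = 25, normalized = TRUE)
  tib_c <- tib; tib_c$f_tibia <- 1.7 * f
  ls1 <- compute_ls(tib, m = 4); ls2 <- compute_ls(tib_c, m = 4)
  expect_equal(ls2$ls, 1.7^4 * ls1$ls, tolerance = 1e-9)
  d1 <- compute_dls(ls1, m = 4)$dls; d2 <- compute_dls(ls2, m = 4)$dls
  expect_equal(d2, sqrt(1.7) * d1, tolerance = 1e-9)
})

test_that("minutes below the 90% sample-coverage rule are omitted", {
  t_full <- seq(0, 120 - 1 / 25, by = 1 / 25)     # two full minutes
  keep <- t_full < 60 | t_full >= 60 + 7          # second minute loses 175 samples (11.7%)
  tib <- structure(data.frame(t = t_full[keep], f_tibia = 1),
                   class = c("tibia_force_series", "data.frame"),
                   sample_rate = 25, normalized = TRUE)
  ls <- compute_ls(tib, minute_grid = c(0, 60), m = 4)
  expect_identical(ls$minute_start, 0)
  keep2 <- t_full < 60 | t_full >= 60 + 5         # loses 125 samples (8.3%) -> covered
  tib2 <- structure(data.frame(t = t_full[keep2], f_tibia = 1),
                    class = c("tibia_force_series", "data.frame"),
                    sample_rate = 25, normalized = TRUE)
  expect_identical(compute_ls(tib2, minute_grid = c(0, 60), m = 4)$minute_start, c(0, 60))
})

test_that("DLS closed form, order invariance, and completeness checking", {
  one <- ls_series(0, 960)
  expect_equal(compute_dls(one, m = 4)$dls, 960^(1 / 8))
  expect_equal(compute_dls(ls_series(c(0, 60), c(0, 0)), m = 4)$dls, 0)

  a <- ls_series(seq(0, 240, by = 60), c(5, 0, 12, 7, 1))
  b <- ls_series(seq(0, 240, by = 60), c(12, 7, 5, 1, 0))  # permuted values
  expect_equal(compute_dls(a, m = 4)$dls, compute_dls(b, m = 4)$dls)

  gappy <- ls_series(c(0, 120), c(5, 5))
  expect_error(compute_dls(gappy, m = 4), class = "tibload_incomplete_error")

  # adding a loaded minute strictly increases DLS
  more <- ls_series(seq(0, 300, by = 60), c(5, 0, 12, 7, 1, 3))
  expect_gt(compute_dls(more, m = 4)$dls, compute_dls(a, m = 4)$dls)
})

test_that("DLS is stable under grid refinement of a smooth day", {
  day <- function(rate) {
    t <- seq(0, 1800, by = 1 / rate)
    f <- 2 + sin(2 * pi * t / 180) + 0.5 * sin(2 * pi * t / 13)
    structure(data.frame(t = t, f_tibia = f),
              class = c("tibia_force_series", "data.frame"),
              sample_rate = rate, normalized = TRUE)
  }
  d25 <- compute_dls(compute_ls(day(25), minute_grid = seq(0, 1740, 60), m = 4), m = 4)$dls
  d250 <- compute_dls(compute_ls(day(250), minute_grid = seq(0, 1740, 60), m = 4), m = 4)$dls
  expect_lt(abs(d25 - d250) / d250, 0.005)
})
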