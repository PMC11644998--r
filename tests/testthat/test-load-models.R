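test_that("the unpenalized fit matches the normal-equations solution", {
  set.seed(5)
  x <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 1, 4, 3, 6))
  y <- c(1.2, 0.7, 2.9, 2.0, 4.1)
  m <- fit_lasso(x, y, lambda = 0)
  # normal-equations oracle on the raw design with intercept
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  got <- coef(m)
  expect_equal(unname(got), as.numeric(beta), tolerance = 1e-6)
  expect_equal(unname(predict(m, x)), as.numeric(X %*% beta), tolerance = 1e-6)
})

test_that("a noiseless linear signal is recovered exactly with zero R^2 loss", {
  set.seed(6)
  n <- 60
  x <- cbind(u = runif(n), v = rnorm(n), w = runif(n))
  y <- 3 * x[, "u"]
  m <- fit_lasso(x, y, seed = 2)
  cf <- coef(m)
  expect_equal(unname(cf["u"]), 3, tolerance = 1e-6)
  expect_lt(max(abs(cf[c("v", "w")])), 1e-6)
  expect_equal(r_squared(y, predict(m, x)), 1, tolerance = 1e-9)
})

test_that("degenerate designs fall back to the intercept-only model", {
  x <- cbind(a = rep(2, 6), b = rep(-1, 6))
  y <- c(1, 2, 3, 4, 5, 6)
  m <- fit_lasso(x, y)
  expect_equal(unname(m$coefficients), c(0, 0))
  expect_equal(m$intercept, mean(y))
  expect_equal(unname(predict(m, x)), rep(mean(y), 6))
})

test_that("training-data preconditions are enforced", {
  expect_error(fit_lasso(matrix(numeric(0), 0, 2), numeric(0)),
               class = "tibload_validation_error")
  expect_error(fit_lasso(matrix(1, 1, 2), 1), class = "tibload_validation_error")
  expect_error(fit_lasso(matrix(c(1, NA, 2, 3), 2, 2), c(1, 2)),
               class = "tibload_validation_error")
  expect_warning(fit_lasso(matrix(rnorm(8), 4, 2), rnorm(4), nfolds = 5),
                 "reducing CV folds")
})

test_that("fitting is deterministic for fixed data and seed", {
  set.seed(8)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- x[, 1] - 2 * x[, 3] + rnorm(100, 0, 0.3)
  m1 <- fit_lasso(x, y, seed = 99)
  m2 <- fit_lasso(x, y, seed = 99)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$lambda, m2$lambda)
})

test_that("single-feature designs are handled", {
  x <- matrix(seq(1, 10), ncol = 1, dimnames = list(NULL, "a"))
  y <- 2 * x[, 1] + 1
  m <- fit_lasso(x, y, lambda = 0)
  expect_equal(unname(coef(m)), c(1, 2), tolerance = 1e-6)
})

test_that("generic model set holds one leakage-free model per participant", {
  days <- generate_cohort(small_cfg(n = 3), seed = 21)
  config <- run_config()
  ms <- fit_generic(days, config)
  ids <- vapply(days, function(d) d$meta$participant_id, character(1))
  expect_setequal(names(ms$models), ids)
  for (pid in ids) {
    expect_false(pid %in% ms$models[[pid]]$train_participants)
    expect_setequal(ms$models[[pid]]$train_participants, setdiff(ids, pid))
  }
  expect_error(fit_generic(days[1], config), class = "tibload_validation_error")
})

test_that("two identical participants yield identical generic models", {
  days <- generate_cohort(small_cfg(n = 2), seed = 33)
  # clone participant 1 under both ids so both held-out fits see the same data
  clone <- days[[1]]
  clone$meta$participant_id <- days[[2]]$meta$participant_id
  twin <- list(days[[1]], clone)
  ms <- fit_generic(twin, run_config(), seed = 5)
  m1 <- ms$models[[1]]; m2 <- ms$models[[2]]
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-9)
  expect_equal(m1$intercept, m2$intercept, tolerance = 1e-9)
})

test_that("generic predictions are clamped, order-stable, and hand-checkable", {
  days <- generate_cohort(small_cfg(n = 2), seed = 13)
  config <- run_config()
  ms <- fit_generic(days, config)
  p <- predict_generic(ms, days[[1]])
  expect_true(all(p$ls >= 0))
  expect_identical(p$minute_start, days[[1]]$tracker$minute_start)
  # prediction arithmetic: intercept + sum(coef * standardized features)
  model <- ms$models[[days[[1]]$meta$participant_id]]
  row <- days[[1]]$tracker[7, tibload:::TRACKER_FEATURES]
  z <- (as.numeric(row) - model$center) / model$scale
  expect_equal(predict(model, row), sum(z * model$coefficients) + model$intercept,
               tolerance = 1e-12)
  expect_error(predict_generic(ms, { d <- days[[1]]; d$meta$participant_id <- "ghost"; d }),
               class = "tibload_validation_error")
})

test_that("calibration flags low-information windows and rejects tiny ones", {
  days <- generate_cohort(small_cfg(n = 2), seed = 55)
  config <- run_config()
  ms <- fit_generic(days, config)
  d <- days[[1]]
  ils <- day_insole_ls(d, config)
  gls <- predict_generic(ms, d)
  # an all-sedentary stretch: pick the minutes with the smallest LS
  quiet <- ils$minute_start[order(ils$ls)][1:12]
  cal <- fit_calibration(d, gls, quiet, config, insole_ls = ils)
  expect_true(cal$low_information_flag)
  expect_error(fit_calibration(d, gls, ils$minute_start[1], config, insole_ls = ils),
               class = "tibload_validation_error")
  # training minutes recorded for leakage audits
  expect_setequal(cal$training_window, quiet)
})

test_that("quarter calibration never scores its own training minutes", {
  days <- generate_cohort(small_cfg(n = 2, day_len = c(300, 310)), seed = 77)
  config <- run_config()
  ms <- fit_generic(days, config)
  q <- evaluate_quarter_calibration(days[[1]], ms, config)
  covered <- day_insole_ls(days[[1]], config)$minute_start
  for (k in 1:4) {
    train <- q$fits[[k]]$training_window
    scored <- q$pooled$minute_start[q$pooled$trained_on_quarter == k]
    expect_length(intersect(train, scored), 0)
    expect_setequal(c(train, scored), covered)
  }
  expect_true(is.finite(q$r2))
})
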