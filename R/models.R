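# Two-stage LS estimation: a generic LASSO trained across participants and
# evaluated leave-one-participant-out, plus a participant-specific calibration
# LASSO stacked on the generic estimate.
#
# glmnet is the solver; lambda is selected by an explicit seeded K-fold CV
# loop over a fixed decreasing grid that ends at 0 (the unpenalized least
# squares endpoint), so noise-free data can be fitted exactly and fold
# assignment is fully reproducible.

TRACKER_FEATURES <- c("activity_time", "step_count", "activity_level",
                      "scaled_steps", "scaled_activity")

# Unpenalized least squares with intercept on standardized features; QR with
# pivoting, aliased coefficients set to 0.
tl_ols <- function(xs, y) {
  cf <- stats::lm.fit(cbind(1, xs), y)$coefficients
  cf[is.na(cf)] <- 0
  unname(cf)
}

#' Fit a LASSO linear model with seeded cross-validated penalty selection
#'
#' Features are standardized to zero mean / unit variance on the training rows
#' (constant features get scale 1 and a zero coefficient); the intercept is
#' unpenalized. When \code{lambda} is \code{NULL}, the penalty is chosen by
#' K-fold cross-validation (deterministic fold assignment from \code{seed})
#' minimizing mean squared error over a logarithmic grid that includes 0.
#' Supplying a single \code{lambda} skips CV and fits at that penalty.
#'
#' @param x Feature matrix or data.frame (>= 2 rows, no missing values).
#' @param y Numeric response.
#' @param lambda Optional penalty value(s); \code{NULL} for the default grid.
#' @param n_lambda,lambda_min_ratio,include_zero Grid shape when
#'   \code{lambda} is \code{NULL}.
#' @param nfolds CV folds (default 5); reduced with a warning when there are
#'   fewer rows than folds.
#' @param seed RNG seed for fold assignment.
#' @return An object of class \code{tl_model}: standardized coefficients,
#'   intercept, per-feature center/scale, selected lambda, seed, and the
#'   training row identifiers (for leakage auditing).
#' @export
fit_lasso <- function(x, y, lambda = NULL, n_lambda = 12, lambda_min_ratio = 1e-3,
                      include_zero = TRUE, nfolds = 5, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  n <- nrow(x)
  if (n == 0 || length(y) == 0) tl_validation_error("empty training data")
  if (n != length(y)) tl_validation_error("x and y row counts differ")
  if (n < 2) tl_validation_error("need at least 2 training rows")
  if (anyNA(x) || anyNA(y)) tl_validation_error("missing values in training data")
  fn <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  colnames(x) <- fn
  train_ids <- attr(x, "row_ids") %||% rownames(x) %||% seq_len(n)

  mu <- colMeans(x)
  sc <- apply(x, 2, stats::sd)
  sc[!is.finite(sc) | sc < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, mu, "-"), 2, sc, "/")

  done <- function(beta, intercept, lam, grid) {
    structure(list(
      feature_names = fn,
      coefficients = setNames(as.numeric(beta), fn),
      intercept = as.numeric(intercept),
      center = setNames(as.numeric(mu), fn),
      scale = setNames(as.numeric(sc), fn),
      lambda = lam, lambda_grid = grid, seed = seed,
      n_train = n, train_ids = train_ids
    ), class = "tl_model")
  }

  # degenerate designs: constant response or no varying feature
  active <- apply(xs, 2, function(col) any(abs(col) > 1e-12))
  if (stats::var(y) < 1e-24 || !any(active)) {
    return(done(rep(0, length(fn)), mean(y), NA_real_, numeric(0)))
  }

  lmax <- max(abs(crossprod(xs, y - mean(y)))) / n
  if (is.null(lambda)) {
    grid <- lmax * exp(seq(0, log(lambda_min_ratio), length.out = n_lambda))
    if (include_zero) grid <- c(grid, 0)
    sel <- NULL
  } else {
    lambda <- sort(unique(as.numeric(lambda)), decreasing = TRUE)
    if (any(lambda < 0)) tl_parameter_error("lambda must be nonnegative")
    # fit along a decreasing path through the requested values for stability
    grid <- sort(unique(c(lmax * exp(seq(0, log(1e-3), length.out = 8)), lambda)),
                 decreasing = TRUE)
    sel <- if (length(lambda) == 1) lambda else NULL
  }

  nfolds_eff <- min(nfolds, n)
  if (nfolds_eff < nfolds) {
    warning(sprintf("reducing CV folds from %d to the %d available rows", nfolds, n))
  }
  cv_candidates <- if (is.null(sel)) {
    if (is.null(lambda)) grid else lambda
  } else NULL

  if (is.null(sel) && (n - ceiling(n / nfolds_eff)) < 2) {
    # folds too small to fit: fall back to the least-penalized candidate
    sel <- min(cv_candidates)
  }

  # The lambda = 0 endpoint is unpenalized least squares; it is solved exactly
  # by QR (rank-deficient designs get pivoted-out coefficients set to 0)
  # rather than by coordinate descent, which converges slowly there.
  grid_pos <- grid[grid > 0]
  if (is.null(sel)) {
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(nfolds_eff), n))
    cand_pos <- cv_candidates[cv_candidates > 0]
    sse <- setNames(numeric(length(cv_candidates)), format(cv_candidates))
    for (f in seq_len(nfolds_eff)) {
      hold <- foldid == f
      xtr <- xs[!hold, , drop = FALSE]; ytr <- y[!hold]
      if (length(cand_pos)) {
        if (stats::var(ytr) < 1e-24) {
          # constant-response fold: every penalty predicts the fold mean
          pred <- matrix(mean(ytr), sum(hold), length(cand_pos))
        } else {
          fit <- glmnet::glmnet(xtr, ytr, lambda = grid_pos, standardize = FALSE,
                                thresh = 1e-8, maxit = 1e7)
          # cand_pos is a subset of the fitted path, so no refit is needed
          pred <- predict(fit, xs[hold, , drop = FALSE], s = cand_pos)
        }
        sse[seq_along(cand_pos)] <- sse[seq_along(cand_pos)] +
          colSums((pred - y[hold])^2)
      }
      if (any(cv_candidates == 0)) {
        cf0 <- tl_ols(xtr, ytr)
        pred0 <- drop(cbind(1, xs[hold, , drop = FALSE]) %*% cf0)
        sse[length(sse)] <- sse[length(sse)] + sum((pred0 - y[hold])^2)
      }
    }
    sel <- cv_candidates[which.min(sse / n)]
  }

  if (sel == 0) {
    cf <- tl_ols(xs, y)
    return(done(cf[-1], cf[1], 0, grid))
  }
  fit <- glmnet::glmnet(xs, y, lambda = grid_pos, standardize = FALSE,
                        thresh = 1e-10, maxit = 1e7)
  cf <- predict(fit, type = "coefficients", s = sel)
  beta <- as.numeric(cf)[-1]
  done(beta, as.numeric(cf)[1], sel, grid)
}

#' Predict from a fitted linear model
#'
#' @param object A \code{tl_model}.
#' @param newdata Matrix or data.frame containing the model's features.
#' @param clamp Clamp predictions at zero (LS is nonnegative by construction);
#'   default \code{FALSE}.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.tl_model <- function(object, newdata, clamp = FALSE, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  storage.mode(x) <- "double"
  z <- sweep(sweep(x, 2, object$center, "-"), 2, object$scale, "/")
  out <- drop(z %*% object$coefficients) + object$intercept
  if (clamp) out <- pmax(out, 0)
  unname(out)
}

#' Original-scale coefficients of a fitted model
#'
#' @param object A \code{tl_model}.
#' @param ... Unused.
#' @return Named vector: \code{(Intercept)} followed by per-feature slopes on
#'   the original (unstandardized) feature scale.
#' @export
coef.tl_model <- function(object, ...) {
  b <- object$coefficients / object$scale
  a <- object$intercept - sum(object$coefficients * object$center / object$scale)
  c("(Intercept)" = a, b)
}

# Extract the (features, target) rows of one day that are insole-covered.
tl_day_rows <- function(day, insole_ls) {
  tr <- day$tracker
  keep <- tr$minute_start %in% insole_ls$minute_start
  x <- as.matrix(tr[keep, TRACKER_FEATURES])
  y <- insole_ls$ls[match(tr$minute_start[keep], insole_ls$minute_start)]
  list(x = x, y = y, minute_start = tr$minute_start[keep])
}

#' Insole-derived LS for one participant day
#'
#' Convenience wrapper: tibia force from the day's insole recording, then
#' minute-wise LS on the tracker's minute grid.
#'
#' @param day A \code{participant_day}.
#' @param config A \code{run_config}.
#' @return An \code{ls_series} (source \code{"insole"}).
#' @export
day_insole_ls <- function(day, config = run_config()) {
  tibia <- compute_tibia_force(day$insole, day$meta,
                               normalize = config$normalize == "bw")
  compute_ls(tibia, minute_grid = day$tracker$minute_start, m = config$m,
             coverage_frac = config$coverage_frac, minute_s = config$minute_s)
}

#' Fit the generic model set (leave-one-participant-out)
#'
#' For each participant, fits one LASSO mapping the five tracker features to
#' insole LS on the pooled insole-covered minutes of all other participants.
#' The resulting set holds one model per held-out participant; no model's
#' training set contains its own participant.
#'
#' @param days List of \code{participant_day} (>= 2 participants).
#' @param config A \code{run_config}.
#' @param seed Seed for fold assignment (default \code{config$seed}).
#' @param insole_ls Optional precomputed list of \code{ls_series}, one per day.
#' @return An object of class \code{tl_generic_set}.
#' @export
fit_generic <- function(days, config = run_config(), seed = config$seed,
                        insole_ls = NULL) {
  ids <- vapply(days, function(d) d$meta$participant_id, character(1))
  if (length(unique(ids)) < 2) {
    tl_validation_error("generic model needs >= 2 participants (no held-out fold otherwise)")
  }
  if (is.null(insole_ls)) insole_ls <- lapply(days, day_insole_ls, config = config)
  rows <- Map(tl_day_rows, days, insole_ls)
  seeds <- tl_child_seeds(seed, length(ids))
  models <- list()
  for (i in seq_along(ids)) {
    x <- do.call(rbind, lapply(rows[-i], `[[`, "x"))
    y <- unlist(lapply(rows[-i], `[[`, "y"))
    # every training row is tagged with its participant for leakage audits
    rownames(x) <- rep(ids[-i], vapply(rows[-i], function(r) nrow(r$x), integer(1)))
    yt <- if (isTRUE(config$log1p_target)) log1p(y) else y
    m <- fit_lasso(x, yt, n_lambda = config$n_lambda,
                   lambda_min_ratio = config$lambda_min_ratio,
                   include_zero = config$lambda_include_zero,
                   nfolds = config$nfolds, seed = seeds[i])
    m$train_participants <- ids[-i]
    models[[ids[i]]] <- m
  }
  structure(list(models = models, participants = ids, seed = seed,
                 log1p_target = isTRUE(config$log1p_target)),
            class = "tl_generic_set")
}

#' Generic (participant-independent) LS predictions for one day
#'
#' Applies the model held out for the day's participant to every tracker
#' minute; predictions are clamped at zero.
#'
#' @param model_set A \code{tl_generic_set}.
#' @param day A \code{participant_day} whose participant is in the set.
#' @return An \code{ls_series} with source \code{"tracker_generic"}.
#' @export
predict_generic <- function(model_set, day) {
  pid <- day$meta$participant_id
  model <- model_set$models[[pid]]
  if (is.null(model)) {
    tl_validation_error(sprintf("no generic model held out for participant '%s'", pid))
  }
  pred <- predict(model, day$tracker[, TRACKER_FEATURES])
  if (isTRUE(model_set$log1p_target)) pred <- expm1(pred)
  ls_series(day$tracker$minute_start, pmax(pred, 0), source = "tracker_generic")
}

#' Fit a participant-specific calibration model
#'
#' Second-stage LASSO whose features are the generic LS estimate plus the
#' five tracker metrics, trained only on minutes that are insole-covered and
#' inside the given training window; the target is the insole LS. The
#' \code{low_information_flag} is set when fewer than
#' \code{config$low_information_min_loaded} window minutes carry nonzero LS
#' (e.g. an all-sedentary window), signalling an unreliable calibration.
#'
#' @param day A \code{participant_day}.
#' @param generic_ls \code{ls_series} of generic predictions for the day.
#' @param window Numeric vector of minute_start values (seconds) defining the
#'   simultaneous-wear training window.
#' @param config A \code{run_config}.
#' @param insole_ls Optional precomputed insole \code{ls_series} for the day.
#' @param seed Seed for fold assignment.
#' @return An object of class \code{tl_calibration}.
#' @export
fit_calibration <- function(day, generic_ls, window, config = run_config(),
                            insole_ls = NULL, seed = config$seed) {
  if (is.null(insole_ls)) insole_ls <- day_insole_ls(day, config)
  use <- intersect(intersect(window, insole_ls$minute_start),
                   day$tracker$minute_start)
  if (length(use) < 2) {
    tl_validation_error(sprintf(
      "calibration window has %d usable insole-covered minute(s); need >= 2", length(use)))
  }
  x <- tl_calibration_features(day, generic_ls, use)
  y <- insole_ls$ls[match(use, insole_ls$minute_start)]
  model <- fit_lasso(x, y, n_lambda = config$n_lambda,
                     lambda_min_ratio = config$lambda_min_ratio,
                     include_zero = config$lambda_include_zero,
                     nfolds = config$nfolds, seed = seed)
  structure(list(
    model = model,
    participant_id = day$meta$participant_id,
    training_window = use,
    low_information_flag = sum(y > 0) < config$low_information_min_loaded
  ), class = "tl_calibration")
}

tl_calibration_features <- function(day, generic_ls, minutes) {
  i_tr <- match(minutes, day$tracker$minute_start)
  i_g <- match(minutes, generic_ls$minute_start)
  if (anyNA(i_tr) || anyNA(i_g)) {
    tl_validation_error("requested minutes missing from tracker or generic series")
  }
  cbind(generic_ls = generic_ls$ls[i_g],
        as.matrix(day$tracker[i_tr, TRACKER_FEATURES]))
}

#' Calibrated LS predictions for selected minutes
#'
#' @param calibration A \code{tl_calibration}.
#' @param day The same participant's \code{participant_day}.
#' @param generic_ls Generic predictions for the day.
#' @param minutes Minute_start values to predict (default: all tracker minutes).
#' @return An \code{ls_series} with source \code{"tracker_calibrated"},
#'   clamped at zero.
#' @export
predict_calibration <- function(calibration, day, generic_ls, minutes = NULL) {
  minutes <- minutes %||% day$tracker$minute_start
  x <- tl_calibration_features(day, generic_ls, minutes)
  pred <- predict(calibration$model, x, clamp = TRUE)
  ls_series(minutes, pred, source = "tracker_calibrated")
}

#' Quarter-wise calibration evaluation for one day
#'
#' Splits the day's insole-covered minutes into 4 contiguous quarters; for
#' each quarter, fits a calibration model on that quarter only and predicts
#' the other three. Held-out predictions are pooled and scored against the
#' insole LS with the coefficient of determination. This emulates wearing
#' both sensors for 25\% of the day and only the tracker for the rest.
#'
#' @param day A \code{participant_day}.
#' @param model_set A \code{tl_generic_set} containing the participant.
#' @param config A \code{run_config}.
#' @param min_minutes Minimum insole-covered minutes required (default 240,
#'   i.e. 4 h of simultaneous wear).
#' @param insole_ls,generic_ls Optional precomputed series.
#' @return List with pooled \code{r2}, the pooled prediction table, and the
#'   four \code{tl_calibration} fits.
#' @export
evaluate_quarter_calibration <- function(day, model_set, config = run_config(),
                                         min_minutes = 240, insole_ls = NULL,
                                         generic_ls = NULL) {
  if (is.null(insole_ls)) insole_ls <- day_insole_ls(day, config)
  if (is.null(generic_ls)) generic_ls <- predict_generic(model_set, day)
  covered <- insole_ls$minute_start
  n <- length(covered)
  if (n < min_minutes) {
    tl_validation_error(sprintf(
      "day has %d insole-covered minutes; need >= %d for quarter calibration", n, min_minutes))
  }
  quarter <- ceiling(4 * seq_len(n) / n)
  seeds <- tl_child_seeds(config$seed, 4)
  target <- numeric(0); est <- numeric(0); held_min <- numeric(0); by_q <- integer(0)
  fits <- vector("list", 4)
  for (q in 1:4) {
    win <- covered[quarter == q]
    fits[[q]] <- fit_calibration(day, generic_ls, win, config,
                                 insole_ls = insole_ls, seed = seeds[q])
    hold <- covered[quarter != q]
    pred <- predict_calibration(fits[[q]], day, generic_ls, minutes = hold)
    target <- c(target, insole_ls$ls[match(hold, covered)])
    est <- c(est, pred$ls)
    held_min <- c(held_min, hold)
    by_q <- c(by_q, rep(q, length(hold)))
  }
  list(r2 = r_squared(target, est),
       pooled = data.frame(minute_start = held_min, target = target,
                           estimate = est, trained_on_quarter = by_q),
       fits = fits)
}
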