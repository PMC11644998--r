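# Evaluation statistics and the end-to-end study orchestrator.

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}. Negative values mean the estimate fits
#' worse than a horizontal line at the target mean; 1 means a perfect fit.
#'
#' @param target Numeric vector of reference values (variance must be > 0).
#' @param estimate Numeric vector of estimates, same length.
#' @return Scalar R-squared (may be negative).
#' @export
r_squared <- function(target, estimate) {
  if (length(target) != length(estimate)) {
    tl_validation_error("target and estimate must have equal length")
  }
  if (length(target) < 2) tl_validation_error("need at least 2 observations")
  ss_tot <- sum((target - mean(target))^2)
  if (ss_tot == 0) {
    tl_validation_error("R^2 undefined: target has zero variance")
  }
  1 - sum((target - estimate)^2) / ss_tot
}

tl_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    tl_abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             "tibload_stage_error")
  })
}

#' Run the full study pipeline on a synthetic cohort
#'
#' Orchestrates the four analysis steps on generated data: (1) generate the
#' cohort; (2) compute insole-derived LS per day; (3) fit the generic
#' (leave-one-participant-out) model set and score per-participant generic
#' R-squared, then score the quarter-wise participant calibration; (4) run
#' the sliding-window wear-time simulation with calibrated and with generic
#' gap filling, and summarize absolute percent error in coverage bins.
#'
#' @param config A \code{run_config}.
#' @param seed Master seed (default \code{config$seed}); the report is a
#'   deterministic function of (config, seed).
#' @return A list of class \code{tl_report}: \code{participants}
#'   (per-participant generic and calibrated R-squared), cohort means and
#'   SDs, the two binned summaries, the raw simulated-day tables, and a run
#'   log (config hash, seed, per-stage row counts).
#' @export
run_study <- function(config = run_config(), seed = config$seed) {
  config$seed <- seed
  seeds <- tl_child_seeds(seed, 3)

  cohort <- tl_stage("generate_cohort",
                     generate_cohort(config$cohort, seed = seeds[1], m = config$m))
  insole_ls <- tl_stage("insole_ls", lapply(cohort, day_insole_ls, config = config))
  model_set <- tl_stage("fit_generic",
                        fit_generic(cohort, config, seed = seeds[2],
                                    insole_ls = insole_ls))
  generic_ls <- tl_stage("predict_generic", lapply(cohort, predict_generic,
                                                   model_set = model_set))

  cfg_q <- config
  cfg_q$seed <- seeds[3]
  per <- tl_stage("evaluate", {
    do.call(rbind, lapply(seq_along(cohort), function(i) {
      day <- cohort[[i]]
      ils <- insole_ls[[i]]
      gls <- generic_ls[[i]]
      tgt <- ils$ls
      est <- gls$ls[match(ils$minute_start, gls$minute_start)]
      q <- evaluate_quarter_calibration(day, model_set, cfg_q,
                                        insole_ls = ils, generic_ls = gls)
      data.frame(participant_id = day$meta$participant_id,
                 generic_r2 = r_squared(tgt, est),
                 calibrated_r2 = q$r2,
                 n_minutes = length(tgt),
                 stringsAsFactors = FALSE)
    }))
  })

  sim_cal <- tl_stage("wear_sim_calibrated", do.call(rbind, lapply(
    seq_along(cohort), function(i) {
      run_wear_sim(cohort[[i]], model_set, config, gap_fill = "calibrated",
                   insole_ls = insole_ls[[i]], generic_ls = generic_ls[[i]])
    })))
  sim_gen <- tl_stage("wear_sim_generic", do.call(rbind, lapply(
    seq_along(cohort), function(i) {
      run_wear_sim(cohort[[i]], model_set, config, gap_fill = "generic",
                   insole_ls = insole_ls[[i]], generic_ls = generic_ls[[i]])
    })))
  bins_cal <- tl_stage("summarize", summarize_sim(sim_cal, config$bin_width_pct))
  bins_gen <- tl_stage("summarize", summarize_sim(sim_gen, config$bin_width_pct))

  cfg_yaml <- yaml::as.yaml(tl_config_as_list(config))
  tf <- tempfile(fileext = ".yaml"); writeLines(cfg_yaml, tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)

  structure(list(
    participants = per,
    generic_r2_mean = mean(per$generic_r2),
    generic_r2_sd = stats::sd(per$generic_r2),
    calibrated_r2_mean = mean(per$calibrated_r2),
    calibrated_r2_sd = stats::sd(per$calibrated_r2),
    bins_calibrated = bins_cal,
    bins_generic = bins_gen,
    sim_calibrated = sim_cal,
    sim_generic = sim_gen,
    config = config,
    seed = seed,
    log = list(config_hash = cfg_hash, seed = seed,
               n_participants = nrow(per),
               minutes_per_participant = setNames(per$n_minutes, per$participant_id),
               sim_days_calibrated = nrow(sim_cal),
               sim_days_generic = nrow(sim_gen))
  ), class = "tl_report")
}

tl_config_as_list <- function(config) {
  out <- unclass(config)
  out$cohort <- unclass(out$cohort)
  out
}

#' @method print tl_report
#' @export
print.tl_report <- function(x, ...) {
  cat(sprintf("tibload study report (seed %s, %d participants)\n",
              x$seed, nrow(x$participants)))
  cat(sprintf("  generic R^2:    mean %+.3f (sd %.3f)\n",
              x$generic_r2_mean, x$generic_r2_sd))
  cat(sprintf("  calibrated R^2: mean %+.3f (sd %.3f)\n",
              x$calibrated_r2_mean, x$calibrated_r2_sd))
  s <- x$bins_calibrated$summary
  occ <- which(!is.na(s$mean_ape))
  if (length(occ)) {
    cat(sprintf("  wear-sim (calibrated): mean APE %.2f%% in the (%g-%g%%] bin, %.2f%% at full coverage\n",
                s$mean_ape[occ[1]], s$bin_low_pct[occ[1]], s$bin_high_pct[occ[1]],
                s$mean_ape[occ[length(occ)]]))
  }
  invisible(x)
}

#' Persist a study report as plain-text tables
#'
#' Writes per-participant R-squared values, both binned APE summaries, the
#' raw simulated-day tables, and a YAML run log. Output is byte-identical for
#' identical (config, seed), which is the package's determinism contract.
#'
#' @param report A \code{tl_report}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
save_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  }
  wcsv(report$participants, "participants.csv")
  wcsv(report$bins_calibrated$summary, "bins_calibrated.csv")
  wcsv(report$bins_generic$summary, "bins_generic.csv")
  wcsv(report$sim_calibrated, "sim_days_calibrated.csv")
  wcsv(report$sim_generic, "sim_days_generic.csv")
  yaml::write_yaml(c(report$log,
                     list(generic_r2_mean = report$generic_r2_mean,
                          calibrated_r2_mean = report$calibrated_r2_mean,
                          config = tl_config_as_list(report$config))),
                   file.path(dir, "run_log.yaml"))
  invisible(dir)
}
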