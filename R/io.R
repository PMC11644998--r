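# Readers and writers for the package's delimited-text dialects.
#
# Insole dialect:  header t_s,force_n,cop_m            one row per sample
# Tracker dialect: header minute_start_s,activity_time_s,step_count,
#                  activity_level,scaled_steps,scaled_activity
# LS dialect:      header minute_start_s,ls,source
# Metadata:        one YAML document per participant
#
# All writers use a canonical number format (tl_fmt_num) so that
# write -> read -> write is byte-identical.

INSOLE_HEADER  <- c("t_s", "force_n", "cop_m")
TRACKER_HEADER <- c("minute_start_s", "activity_time_s", "step_count",
                    "activity_level", "scaled_steps", "scaled_activity")
LS_HEADER      <- c("minute_start_s", "ls", "source")

tl_check_header <- function(path, expected) {
  line <- readLines(path, n = 1L)
  if (length(line) == 0) tl_format_error(sprintf("%s: empty file, missing header", path))
  got <- strsplit(line, ",", fixed = TRUE)[[1]]
  missing <- setdiff(expected, got)
  if (length(missing)) {
    tl_format_error(sprintf("%s: malformed header; missing column(s): %s",
                            path, paste(missing, collapse = ", ")))
  }
  if (!identical(got, expected)) {
    tl_format_error(sprintf("%s: header columns must be exactly: %s",
                            path, paste(expected, collapse = ",")))
  }
  invisible(TRUE)
}

#' Read an insole recording
#'
#' Reads the delimited insole dialect (\code{t_s,force_n,cop_m}). Rows whose
#' force falls below the noise floor get their CoP carried forward from the
#' last loaded sample (swing-phase CoP from pressure insoles is noise);
#' leading unloaded rows take the first loaded CoP.
#'
#' @param path File path.
#' @param meta Optional \code{participant_meta}; supplies the insole length for
#'   CoP range validation.
#' @param sample_rate Sampling rate in Hz (default 25).
#' @param noise_floor_n Force noise floor in newtons (default 1).
#' @return A validated \code{insole_series}.
#' @export
read_insole <- function(path, meta = NULL, sample_rate = 25, noise_floor_n = 1) {
  if (!file.exists(path)) tl_format_error(sprintf("file not found: %s", path))
  tl_check_header(path, INSOLE_HEADER)
  df <- utils::read.csv(path, colClasses = "numeric")
  names(df) <- c("t", "force", "cop")
  if (nrow(df) > 1) {
    d <- diff(df$t)
    if (any(d <= 0)) {
      tl_data_error(sprintf("%s: non-monotone time at row %d", path, which(d <= 0)[1] + 1L))
    }
  }
  df$cop <- tl_carry_cop(df$cop, df$force, noise_floor_n)
  insole_series(df$t, df$force, df$cop, sample_rate = sample_rate,
                insole_length = meta$insole_length)
}

# Last-observation-carried-forward CoP over unloaded rows.
tl_carry_cop <- function(cop, force, noise_floor_n) {
  loaded <- force >= noise_floor_n & is.finite(cop)
  if (!any(loaded)) return(cop)
  v <- cop
  v[!loaded] <- NA_real_
  idx <- cumsum(loaded)
  first <- which(loaded)[1]
  idx[idx == 0] <- 1L
  out <- v[loaded][idx]
  out[seq_len(first - 1)] <- v[loaded][1]
  out
}

#' Write an insole recording
#'
#' @param x An \code{insole_series}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_insole <- function(x, path) {
  lines <- c(paste(INSOLE_HEADER, collapse = ","),
             paste(tl_fmt_num(x$t), tl_fmt_num(x$force), tl_fmt_num(x$cop), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a tracker minute table
#'
#' A file containing only the header yields an empty (zero-row) table.
#'
#' @param path File path.
#' @return A validated \code{tracker_minute_table}.
#' @export
read_tracker <- function(path) {
  if (!file.exists(path)) tl_format_error(sprintf("file not found: %s", path))
  tl_check_header(path, TRACKER_HEADER)
  df <- utils::read.csv(path, colClasses = "numeric")
  if (nrow(df) > 1) {
    d <- diff(df[[1]])
    if (any(d <= 0)) {
      tl_data_error(sprintf("%s: non-monotone minute_start at row %d",
                            path, which(d <= 0)[1] + 1L))
    }
  }
  tracker_minute_table(df[[1]], df[[2]], df[[3]], df[[4]], df[[5]], df[[6]])
}

#' Write a tracker minute table
#'
#' @param x A \code{tracker_minute_table}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tracker <- function(x, path) {
  lines <- c(paste(TRACKER_HEADER, collapse = ","),
             paste(tl_fmt_num(x$minute_start), tl_fmt_num(x$activity_time),
                   tl_fmt_num(x$step_count), tl_fmt_num(x$activity_level),
                   tl_fmt_num(x$scaled_steps), tl_fmt_num(x$scaled_activity),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a loading-stimulus series
#' @param path File path.
#' @return A validated \code{ls_series}.
#' @export
read_ls <- function(path) {
  if (!file.exists(path)) tl_format_error(sprintf("file not found: %s", path))
  tl_check_header(path, LS_HEADER)
  df <- utils::read.csv(path, colClasses = c("numeric", "numeric", "character"))
  ls_series(df[[1]], df[[2]], df[[3]])
}

#' Write a loading-stimulus series
#' @param x An \code{ls_series}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_ls <- function(x, path) {
  lines <- c(paste(LS_HEADER, collapse = ","),
             paste(tl_fmt_num(x$minute_start), tl_fmt_num(x$ls), x$source, sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read participant metadata
#'
#' YAML document with keys \code{participant_id}, \code{body_mass_kg},
#' \code{ankle_offset_x_m}, \code{achilles_moment_arm_r_m},
#' \code{insole_length_m}.
#'
#' @param path File path.
#' @return A \code{participant_meta}.
#' @export
read_meta <- function(path) {
  if (!file.exists(path)) tl_format_error(sprintf("file not found: %s", path))
  doc <- yaml::read_yaml(path)
  need <- c("participant_id", "body_mass_kg", "ankle_offset_x_m", "insole_length_m")
  missing <- setdiff(need, names(doc))
  if (length(missing)) {
    tl_format_error(sprintf("%s: metadata missing key(s): %s",
                            path, paste(missing, collapse = ", ")))
  }
  participant_meta(doc$participant_id, doc$body_mass_kg, doc$ankle_offset_x_m,
                   doc$insole_length_m,
                   doc$achilles_moment_arm_r_m %||% 0.05)
}

#' Write participant metadata
#' @param meta A \code{participant_meta}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_meta <- function(meta, path) {
  yaml::write_yaml(list(
    participant_id = meta$participant_id,
    body_mass_kg = meta$body_mass,
    ankle_offset_x_m = meta$ankle_offset_x,
    achilles_moment_arm_r_m = meta$achilles_moment_arm_r,
    insole_length_m = meta$insole_length
  ), path)
  invisible(path)
}

#' Serialize a fitted linear model as a plain-text document
#'
#' @param model A \code{tl_model}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path) {
  yaml::write_yaml(list(
    feature_names = model$feature_names,
    coefficients = as.list(setNames(model$coefficients, model$feature_names)),
    intercept = model$intercept,
    center = as.list(setNames(model$center, model$feature_names)),
    scale = as.list(setNames(model$scale, model$feature_names)),
    lambda = model$lambda,
    seed = model$seed
  ), path)
  invisible(path)
}

#' Read a serialized linear model
#' @param path File path.
#' @return A \code{tl_model}.
#' @export
read_model <- function(path) {
  doc <- yaml::read_yaml(path)
  fn <- as.character(doc$feature_names)
  structure(list(
    feature_names = fn,
    coefficients = setNames(as.numeric(unlist(doc$coefficients[fn])), fn),
    intercept = as.numeric(doc$intercept),
    center = setNames(as.numeric(unlist(doc$center[fn])), fn),
    scale = setNames(as.numeric(unlist(doc$scale[fn])), fn),
    lambda = as.numeric(doc$lambda),
    seed = doc$seed,
    train_ids = NULL
  ), class = "tl_model")
}
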