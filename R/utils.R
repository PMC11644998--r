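# Internal helpers shared across modules.

# Typed conditions: every user-facing failure carries a tibload_* class so
# callers (and tests) can distinguish format, data, validation, parameter and
# incompleteness errors.
tl_abort <- function(message, class = character(), ...) {
  cond <- structure(
    class = c(class, "tibload_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

tl_format_error     <- function(message, ...) tl_abort(message, "tibload_format_error", ...)
tl_data_error       <- function(message, ...) tl_abort(message, "tibload_data_error", ...)
tl_validation_error <- function(message, ...) tl_abort(message, "tibload_validation_error", ...)
tl_parameter_error  <- function(message, ...) tl_abort(message, "tibload_parameter_error", ...)
tl_incomplete_error <- function(message, ...) tl_abort(message, "tibload_incomplete_error", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Standard gravity, m/s^2; converts newtons to bodyweights via F / (g * mass).
G_ACCEL <- 9.81

# Deterministic stream of child seeds (< 2^31) derived arithmetically from a
# master seed so that sub-generators do not perturb each other's RNG state.
tl_child_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  k <- seq_len(n)
  s <- (abs(seed) %% 2147483647) + 1
  ((s * 48271 + k * 2654435761) %% 2147483629) + 1
}

# Half-open minute index of a time in seconds: [0,60) -> 0, [60,120) -> 1, ...
tl_minute_index <- function(t, minute_s = 60) floor(t / minute_s)

# Number formatting used by all delimited-text writers; canonical so that
# write -> read -> write round-trips are byte-identical.
tl_fmt_num <- function(x) {
  out <- sprintf("%.10g", x)
  out[is.na(x)] <- "NA"
  out
}
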