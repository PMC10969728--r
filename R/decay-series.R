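#' Time series of a decaying property
#'
#' A `decay_series` is a two-column data frame (`time`, `value`) carrying a
#' measured or simulated trajectory: absorbance (AU at 600 nm) of a stored
#' emulsion over days, or monolith weight / remaining oil fraction over the
#' release experiment. Times must be strictly increasing and non-negative.
#'
#' @param time numeric vector of strictly increasing, non-negative times.
#'   Units are days for stability trajectories; minutes or seconds for
#'   release curves (record them in `time_unit`).
#' @param value numeric vector, same length as `time`. Absorbance, weight in
#'   grams, or a dimensionless remaining fraction. Values are not clipped:
#'   noisy absorbance arithmetic may legitimately go negative.
#' @param sample_id optional sample label.
#' @param condition optional condition label (e.g. storage temperature).
#' @param time_unit one of `"day"`, `"min"`, `"s"`.
#'
#' @return A data frame of class `decay_series` with attributes `sample_id`,
#'   `condition` and `time_unit`.
#' @export
#' @examples
#' decay_series(0:3, c(233, 167.8, 111.8, 83.9), sample_id = "S6")
decay_series <- function(time, value, sample_id = NA_character_,
                         condition = NA_character_,
                         time_unit = c("day", "min", "s")) {
  time_unit <- match.arg(time_unit)
  if (length(time) != length(value)) {
    stop_relkin("invalid_input", "`time` and `value` must have equal length")
  }
  if (anyNA(time) || anyNA(value)) {
    stop_relkin("invalid_input", "`time` and `value` must not contain NA")
  }
  if (any(time < 0)) {
    stop_relkin("invalid_input", "times must be non-negative")
  }
  if (length(time) > 1L && any(diff(time) <= 0)) {
    stop_relkin("invalid_input", "times must be strictly increasing")
  }
  out <- data.frame(time = as.numeric(time), value = as.numeric(value))
  class(out) <- c("decay_series", "data.frame")
  attr(out, "sample_id") <- sample_id
  attr(out, "condition") <- condition
  attr(out, "time_unit") <- time_unit
  out
}

#' @export
print.decay_series <- function(x, ...) {
  cat(sprintf("<decay_series> sample=%s condition=%s unit=%s n=%d\n",
              attr(x, "sample_id"), attr(x, "condition"),
              attr(x, "time_unit"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

# Classed condition so callers can distinguish failure modes programmatically.
# `class` is a short machine tag: invalid_config, invalid_input,
# degenerate_design, insufficient_data, fit_failure, undefined_ratio,
# undefined_correlation, join_failure, invalid_geometry, schema_error,
# invalid_normalization.
stop_relkin <- function(class, message, ...) {
  cnd <- structure(
    class = c(paste0("relkin_", class), "relkin_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cnd)
}

warn_relkin <- function(class, message) {
  cnd <- structure(
    class = c(paste0("relkin_", class), "relkin_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  )
  warning(cnd)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
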