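#' Emulsion stability index
#'
#' Percent ratio of the absorbance measured after `t` days of storage to the
#' absorbance immediately after homogenization (the emulsion activity):
#' `100 * a_t / a_0`. Values above 100 are legal — stored emulsions can
#' transiently recover turbidity — so no capping is applied.
#'
#' @param a_t absorbance (AU at 600 nm) after storage; vectorized.
#' @param a_0 absorbance immediately after homogenization; must be positive.
#' @return Stability in percent.
#' @export
#' @examples
#' emulsion_stability(137.845, 145.1)  # 95
emulsion_stability <- function(a_t, a_0) {
  if (any(a_0 <= 0)) {
    stop_relkin("undefined_ratio", "`a_0` must be positive")
  }
  if (any(a_t < 0)) {
    stop_relkin("invalid_input", "`a_t` must be non-negative")
  }
  100 * a_t / a_0
}

#' Reconstruct an absolute absorbance trajectory from stability percents
#'
#' Inverts the stability index: given the day-0 activity `a0` and the
#' per-day stability percents, returns the absolute absorbance series with
#' day 0 at the activity value (stability 100%). Fitting is done on this
#' absolute trajectory, whose intercepts then track the measured activities.
#'
#' @param activity_a0 day-0 absorbance (AU); positive.
#' @param stability_percents stability index for days `1, 2, ...` (percent).
#' @param sample_id,condition labels forwarded to the series.
#' @return A [decay_series()] in days: `(0, a0), (1, a0*S1/100), ...`.
#' @export
#' @examples
#' reconstruct_trajectory(233, c(72, 48, 36))
reconstruct_trajectory <- function(activity_a0, stability_percents,
                                   sample_id = NA_character_,
                                   condition = NA_character_) {
  if (activity_a0 <= 0) {
    stop_relkin("invalid_input", "`activity_a0` must be positive")
  }
  if (any(stability_percents < 0)) {
    stop_relkin("invalid_input", "stability percents must be non-negative")
  }
  days <- 0:length(stability_percents)
  values <- c(activity_a0, activity_a0 * stability_percents / 100)
  decay_series(days, values, sample_id = sample_id, condition = condition,
               time_unit = "day")
}

new_kinetic_fit <- function(order, intercept, rate, direction,
                            se_intercept, se_rate, r_squared, n,
                            fitted, converged = TRUE, time_unit = "day") {
  structure(list(order = order, intercept = intercept, rate = rate,
                 direction = direction, se_intercept = se_intercept,
                 se_rate = se_rate, r_squared = r_squared, n = n,
                 fitted = fitted, converged = converged,
                 time_unit = time_unit),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> order %d: P0 = %.4g (se %.3g), k = %s%.4g per %s (se %.3g), R^2 = %.4f, n = %d%s\n",
    x$order, x$intercept, x$se_intercept,
    if (x$direction < 0) "-" else "+", x$rate, x$time_unit, x$se_rate,
    x$r_squared, x$n, if (x$converged) "" else " [not converged]"))
  invisible(x)
}

r_squared_about_mean <- function(observed, fitted) {
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else -Inf)
  1 - ss_res / ss_tot
}

#' Zero-order kinetic fit
#'
#' Ordinary least squares of `value ~ time` (`Pr = P0 - k t` for decay). The
#' rate is stored as a magnitude with the slope's sign in `direction`, since
#' the integrated rate law is written with an ambiguous sign and the study's
#' stability slopes are all negative.
#'
#' @param series a [decay_series()] (or any data frame with `time`, `value`)
#'   with at least 2 distinct time points.
#' @return A `kinetic_fit` with `order = 0`, `intercept` (fitted value at
#'   t = 0), `rate` (|slope|), standard errors, and R^2 about the mean.
#' @export
#' @examples
#' fit_zero_order(reconstruct_trajectory(233, c(72, 48, 36)))
fit_zero_order <- function(series) {
  t <- series$time; y <- series$value
  if (length(unique(t)) < 2L) {
    stop_relkin("degenerate_design", "need >= 2 distinct time points")
  }
  fit <- stats::lm(y ~ t)
  # summary.lm warns on zero-residual data; exact fits are legitimate here
  cf <- suppressWarnings(summary(fit))$coefficients
  slope <- cf["t", "Estimate"]
  # 2-point fits have zero residual df; lm reports NaN standard errors there
  se <- if (nrow(series) > 2L) cf[, "Std. Error"] else c(0, 0)
  new_kinetic_fit(order = 0L,
                  intercept = cf["(Intercept)", "Estimate"],
                  rate = abs(slope),
                  direction = if (slope < 0) -1L else 1L,
                  se_intercept = se[[1]], se_rate = se[[2]],
                  r_squared = r_squared_about_mean(y, stats::fitted(fit)),
                  n = length(y), fitted = as.numeric(stats::fitted(fit)),
                  time_unit = attr(series, "time_unit") %||% "day")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' First-order kinetic fit
#'
#' Nonlinear least squares of `Pr = P0 * exp(s * k * t)` on the original
#' (untransformed) scale, with the direction `s` and starting values taken
#' from a log-linear regression and `k` constrained to `[0, 10]` per time
#' unit. R^2 is computed on the original scale and may be negative for a
#' poor fit. If the optimizer fails to converge, a `relkin_fit_failure`
#' error is signalled carrying the log-linear initializer's fit in its
#' `fit` field.
#'
#' @param series a [decay_series()] with >= 3 points, all values positive
#'   (needed for the log-linear initialization).
#' @param max_iter iteration cap for the Levenberg–Marquardt optimizer.
#' @return A `kinetic_fit` with `order = 1`.
#' @export
#' @examples
#' s <- decay_series(0:3, 200 * exp(-0.3 * 0:3))
#' fit_first_order(s)
fit_first_order <- function(series, max_iter = 100L) {
  t <- series$time; y <- series$value
  if (length(y) < 3L) {
    stop_relkin("insufficient_data", "need >= 3 points for a first-order fit")
  }
  if (any(y <= 0)) {
    stop_relkin("invalid_input",
                "all values must be positive for log-linear initialization")
  }
  loglin <- stats::lm(log(y) ~ t)
  s_dir <- if (stats::coef(loglin)[["t"]] < 0) -1 else 1
  start <- list(P0 = exp(stats::coef(loglin)[["(Intercept)"]]),
                k = min(abs(stats::coef(loglin)[["t"]]), 10))
  init_fit <- {
    f <- start$P0 * exp(s_dir * start$k * t)
    new_kinetic_fit(order = 1L, intercept = start$P0, rate = start$k,
                    direction = as.integer(s_dir), se_intercept = NA_real_,
                    se_rate = NA_real_,
                    r_squared = r_squared_about_mean(y, f),
                    n = length(y), fitted = f, converged = FALSE,
                    time_unit = attr(series, "time_unit") %||% "day")
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ P0 * exp(s_dir * k * t),
                      start = start,
                      lower = c(P0 = .Machine$double.xmin, k = 0),
                      upper = c(P0 = Inf, k = 10),
                      control = minpack.lm::nls.lm.control(maxiter = max_iter)),
    error = function(e) NULL)
  if (is.null(fit)) {
    stop_relkin("fit_failure",
                "first-order fit did not converge; initializer attached",
                fit = init_fit)
  }
  cf <- summary(fit)$coefficients
  se <- if (length(y) > 2L) cf[, "Std. Error"] else c(0, 0)
  new_kinetic_fit(order = 1L,
                  intercept = cf["P0", "Estimate"],
                  rate = cf["k", "Estimate"],
                  direction = as.integer(s_dir),
                  se_intercept = se[["P0"]], se_rate = se[["k"]],
                  r_squared = r_squared_about_mean(y, stats::fitted(fit)),
                  n = length(y), fitted = as.numeric(stats::fitted(fit)),
                  time_unit = attr(series, "time_unit") %||% "day")
}

#' Average goodness of fit across kinetic fits
#'
#' Arithmetic mean of the R^2 values of a homogeneous (same-order)
#' collection of fits — the study-level summary used to compare the
#' zero- and first-order descriptions of stability decay.
#'
#' @param fits a list of `kinetic_fit` objects, or a numeric vector of R^2
#'   values.
#' @return Mean R^2.
#' @export
average_r_squared <- function(fits) {
  if (is.numeric(fits)) {
    if (length(fits) == 0L) {
      stop_relkin("invalid_input", "empty collection")
    }
    return(mean(fits))
  }
  if (length(fits) == 0L) stop_relkin("invalid_input", "empty collection")
  if (!all(vapply(fits, inherits, logical(1), "kinetic_fit"))) {
    stop_relkin("invalid_input", "all elements must be kinetic_fit objects")
  }
  orders <- vapply(fits, `[[`, integer(1), "order")
  if (length(unique(orders)) != 1L) {
    stop_relkin("invalid_input", "fits must all have the same order")
  }
  mean(vapply(fits, `[[`, numeric(1), "r_squared"))
}

#' Classify the temperature dependence of degradation rates
#'
#' Arrhenius behavior predicts rates monotone in temperature; the study's
#' intermediate gum blends instead peak at the middle storage temperature.
#' This classifier reports `"peaked"` when the maximum rate magnitude sits
#' at a strictly interior temperature and strictly exceeds both neighbors,
#' `"flat"` when all rates agree within `tol`, and `"monotone"` otherwise
#' (the non-peaked catch-all).
#'
#' @param rates rate magnitudes, named by temperature (deg C), or a numeric
#'   vector accompanied by `temperatures`.
#' @param temperatures temperatures matching `rates` if unnamed.
#' @param tol equality tolerance for the flat test.
#' @return `"peaked"`, `"monotone"` or `"flat"`.
#' @export
#' @examples
#' detect_rate_peak(c("5" = 38, "20" = 55, "35" = 34))  # "peaked"
detect_rate_peak <- function(rates, temperatures = NULL, tol = 1e-9) {
  if (is.null(temperatures)) {
    if (is.null(names(rates))) {
      stop_relkin("invalid_input",
                  "supply `temperatures` or name `rates` by temperature")
    }
    temperatures <- as.numeric(names(rates))
  }
  if (length(rates) < 3L) {
    stop_relkin("insufficient_data", "need rates at >= 3 temperatures")
  }
  o <- order(temperatures)
  r <- as.numeric(rates)[o]
  if (diff(range(r)) <= tol) return("flat")
  i <- which.max(r)
  interior <- i > 1L && i < length(r)
  if (interior && r[i] > r[i - 1L] && r[i] > r[i + 1L]) "peaked" else "monotone"
}
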