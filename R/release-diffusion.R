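#' Trim a gravimetric release record at its plateau
#'
#' The release experiment weighs the monolith every 30 min and stops once
#' the balance reads steady for three consecutive measurements. This
#' reproduces that stopping rule offline: it scans for the first run of
#' three consecutive weights that agree pairwise within `tolerance` and cuts
#' the record at the second reading of that run (never keeping fewer than 3
#' points, the minimum any downstream fit needs). If no plateau exists the
#' series is returned unchanged — a valid outcome, not an error.
#'
#' @param weights a [decay_series()] of monolith weights (g); >= 3 points.
#' @param tolerance pairwise agreement tolerance in grams. The default
#'   1e-4 g is a typical analytical-balance resolution.
#' @return The trimmed [decay_series()].
#' @export
#' @examples
#' s <- decay_series(0:5, c(10, 9, 8, 8.0001, 8.0000, 8.0001), time_unit = "min")
#' trim_at_plateau(s, tolerance = 0.001)  # first 4 points
trim_at_plateau <- function(weights, tolerance = 1e-4) {
  w <- weights$value
  n <- length(w)
  if (n < 3L) {
    stop_relkin("insufficient_data", "need >= 3 points to look for a plateau")
  }
  for (i in seq_len(n - 2L)) {
    trio <- w[i:(i + 2L)]
    if (max(trio) - min(trio) <= tolerance) {
      keep <- max(3L, i + 1L)
      out <- weights[seq_len(keep), , drop = FALSE]
      class(out) <- class(weights)
      for (a in c("sample_id", "condition", "time_unit", "truth")) {
        attr(out, a) <- attr(weights, a)
      }
      return(out)
    }
  }
  weights
}

#' Normalize monolith weights to a remaining oil fraction
#'
#' `remaining(t) = (w(t) - plateau_mass) / (w(0) - plateau_mass)`: the
#' plateau mass is the non-volatile carrier (cellulose disc plus
#' non-releasable residue), so the normalized series starts at exactly 1 and
#' tracks the releasable-oil fraction still in the matrix.
#'
#' @param weights a [decay_series()] of weights (g).
#' @param plateau_mass non-volatile mass in grams; must be below `w(0)`.
#' @return A [decay_series()] of remaining fractions, with the implied
#'   releasable mass `w(0) - plateau_mass` in attribute `M0_g`.
#' @export
#' @examples
#' s <- decay_series(0:2, c(6.0, 5.5, 5.0), time_unit = "min")
#' normalize_release(s, plateau_mass = 5.0)
normalize_release <- function(weights, plateau_mass) {
  w0 <- weights$value[1]
  if (w0 <= plateau_mass) {
    stop_relkin("invalid_normalization",
                "initial weight must exceed `plateau_mass`")
  }
  frac <- (weights$value - plateau_mass) / (w0 - plateau_mass)
  out <- decay_series(weights$time, frac,
                      sample_id = attr(weights, "sample_id"),
                      condition = attr(weights, "condition"),
                      time_unit = attr(weights, "time_unit") %||% "min")
  attr(out, "M0_g") <- w0 - plateau_mass
  out
}

#' First-order fit of a release curve
#'
#' Nonlinear least squares of `M0 * exp(-k t)` to a remaining-fraction (or
#' remaining-mass) series — the same contract as [fit_first_order()] but on
#' the release time base. The rate is stored in SI (per second) and also
#' reported per minute, the unit the release literature prints.
#'
#' @param fractions a [decay_series()] with >= 3 positive values; times in
#'   the unit declared by its `time_unit` attribute (`"min"` or `"s"`).
#' @param max_iter optimizer iteration cap.
#' @return A list of class `release_fit`: `M0`, `k_per_s`, `k_per_min`,
#'   standard errors, and R^2 on the original scale.
#' @export
#' @examples
#' t_min <- seq(0, 300, by = 30)
#' s <- decay_series(t_min, exp(-1.46e-3 * t_min), time_unit = "min")
#' fit_first_order_release(s)
fit_first_order_release <- function(fractions, max_iter = 100L) {
  unit <- attr(fractions, "time_unit") %||% "min"
  if (!unit %in% c("min", "s")) {
    stop_relkin("invalid_input", "release series must be in minutes or seconds")
  }
  to_s <- if (unit == "min") 60 else 1
  constant <- diff(range(fractions$value)) == 0
  if (constant) {
    # no decay at all: k = 0 exactly, M0 = the constant level
    fit <- new_kinetic_fit(order = 1L, intercept = fractions$value[1],
                           rate = 0, direction = -1L, se_intercept = 0,
                           se_rate = 0, r_squared = 1,
                           n = nrow(fractions), fitted = fractions$value,
                           time_unit = unit)
  } else {
    fit <- fit_first_order(fractions, max_iter = max_iter)
  }
  structure(list(M0 = fit$intercept,
                 k_per_s = fit$rate / to_s,
                 k_per_min = fit$rate / to_s * 60,
                 se_M0 = fit$se_intercept,
                 se_k_per_s = fit$se_rate / to_s,
                 r_squared = fit$r_squared,
                 n = fit$n, converged = fit$converged),
            class = "release_fit")
}

#' @export
print.release_fit <- function(x, ...) {
  cat(sprintf("<release_fit> M0 = %.4g, k = %.4g min^-1 (%.4g s^-1), R^2 = %.4f, n = %d\n",
              x$M0, x$k_per_min, x$k_per_s, x$r_squared, x$n))
  invisible(x)
}

#' Diffusivity from a first-order rate constant (slab relation)
#'
#' For desorption through the faces of a plane slab, the long-time decay of
#' the first eigenmode links a first-order rate constant to a diffusivity:
#' `D = k * L^2 / pi^2`. `L` is deliberately a required argument with no
#' default: the study's text defines it as the slab half-thickness
#' (0.0025 m), yet its kinetic-route diffusivities are numerically
#' consistent with L = 0.020 m (the disc radius), while its truncated-model
#' evaluations are consistent with L = 0.005 m (the full thickness). Both
#' conventions are reproducible here; neither is guessed for you.
#'
#' @param k first-order rate constant in s^-1 (convert per-minute rates by
#'   dividing by 60 first, or use a [fit_first_order_release()] `k_per_s`).
#' @param L characteristic length in meters.
#' @return Diffusivity in m^2/s.
#' @export
#' @examples
#' k_to_diffusivity(6.69e-4 / 60, L = 0.020)  # ~4.5e-10 m^2/s
k_to_diffusivity <- function(k, L) {
  if (any(L <= 0)) stop_relkin("invalid_geometry", "`L` must be positive")
  if (any(k < 0)) stop_relkin("invalid_input", "`k` must be non-negative")
  k * L^2 / pi^2
}

#' One-term truncated Fickian remaining fraction
#'
#' The eigenfunction series for slab desorption truncated to its first term,
#' in the surface-concentration form: `(4/pi) * exp(-D * pi^2 * t / L^2)`.
#' At `t = 0` this evaluates to 4/pi (about 1.273), above 1 — the truncation
#' artifact of dropping the higher modes — and it is deliberately not
#' clamped: the model is only meaningful once it has decayed below 1.
#'
#' @param D diffusivity, m^2/s.
#' @param L slab length convention, m.
#' @param t time in seconds; vectorized.
#' @return Dimensionless remaining fraction(s).
#' @export
#' @examples
#' truncated_remaining_fraction(2.4e-10, 0.005, 9000)  # ~0.543
truncated_remaining_fraction <- function(D, L, t) {
  if (any(L <= 0)) stop_relkin("invalid_geometry", "`L` must be positive")
  if (any(D < 0) || any(t < 0)) {
    stop_relkin("invalid_input", "`D` and `t` must be non-negative")
  }
  (4 / pi) * exp(-D * pi^2 * t / L^2)
}

#' Fit the truncated Fickian slab model to a release curve
#'
#' Least-squares estimation of the effective diffusivity `D` in the
#' one-term model `A * exp(-D * pi^2 * t / L^2)`. The amplitude `A` is a
#' fitted nuisance parameter initialized at its theoretical value 4/pi; it
#' absorbs the offset between the one-term surface form and whatever the
#' data's true early-time amplitude is, which keeps the decay constant — and
#' hence `D` — nearly unbiased even when the data follow the full series
#' (set `fix_amplitude = TRUE` to pin `A = 4/pi` instead).
#'
#' Because the truncated model is non-physical (above 1) at early times,
#' points are windowed to dimensionless time
#' `tau = D * pi^2 * t / L^2 >= fit_window_tau_min`, with `tau` evaluated
#' iteratively from the current `D` estimate until the window stabilizes.
#' The default threshold `log(4/pi)` is exactly where the truncated model
#' first drops to 1; set it to 0 to mimic naive whole-curve fitting.
#'
#' @param fractions a [decay_series()] of remaining fractions (times in
#'   minutes or seconds per its `time_unit`); >= 3 points must survive
#'   windowing.
#' @param L characteristic length in meters (required; see
#'   [k_to_diffusivity()] for why there is no default).
#' @param fit_window_tau_min dimensionless lower window edge.
#' @param fix_amplitude pin the amplitude at 4/pi instead of fitting it.
#' @param max_iter optimizer iteration cap per window pass.
#' @return A list of class `fickian_fit`: `D_eff` (m^2/s), `amplitude`,
#'   `r_squared` (original scale, windowed points), `L_used`, `n_used`,
#'   `tau_window`, `converged`.
#' @export
#' @examples
#' t <- seq(0, 36000, by = 1800)
#' s <- decay_series(t, truncated_remaining_fraction(1e-10, 0.005, t),
#'                   time_unit = "s")
#' fit_fickian_truncated(s, L = 0.005)
fit_fickian_truncated <- function(fractions, L,
                                  fit_window_tau_min = log(4 / pi),
                                  fix_amplitude = FALSE,
                                  max_iter = 100L) {
  if (missing(L)) stop_relkin("invalid_geometry", "`L` must be given explicitly")
  if (L <= 0) stop_relkin("invalid_geometry", "`L` must be positive")
  unit <- attr(fractions, "time_unit") %||% "min"
  to_s <- switch(unit, min = 60, s = 1,
                 stop_relkin("invalid_input", "times must be minutes or seconds"))
  t_s <- fractions$time * to_s
  y <- fractions$value
  pos <- y > 0
  if (sum(pos) < 3L) {
    stop_relkin("insufficient_data", "need >= 3 positive fraction values")
  }

  # initialize D from the log-linear slope on the positive tail
  ll <- stats::lm(log(y[pos]) ~ t_s[pos])
  D <- max(-stats::coef(ll)[[2]] * L^2 / pi^2, 1e-16)
  A <- 4 / pi
  window <- rep(TRUE, length(t_s))
  fit <- NULL
  for (pass in 1:25) {
    tau <- D * pi^2 * t_s / L^2
    new_window <- tau >= fit_window_tau_min & pos
    if (sum(new_window) < 3L) {
      stop_relkin("insufficient_data",
                  "fewer than 3 points inside the tau window")
    }
    tw <- t_s[new_window]; yw <- y[new_window]
    fit <- tryCatch({
      if (fix_amplitude) {
        minpack.lm::nlsLM(yw ~ (4 / pi) * exp(-Dp * pi^2 * tw / L^2),
                          start = list(Dp = D), lower = c(Dp = 0),
                          control = minpack.lm::nls.lm.control(maxiter = max_iter))
      } else {
        minpack.lm::nlsLM(yw ~ A * exp(-Dp * pi^2 * tw / L^2),
                          start = list(A = A, Dp = D),
                          lower = c(A = 0, Dp = 0),
                          control = minpack.lm::nls.lm.control(maxiter = max_iter))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) {
      stop_relkin("fit_failure", "truncated-Fickian fit did not converge")
    }
    D_new <- stats::coef(fit)[["Dp"]]
    A <- if (fix_amplitude) 4 / pi else stats::coef(fit)[["A"]]
    stable <- identical(window, new_window) &&
      abs(D_new - D) <= 1e-12 * max(D, .Machine$double.xmin)
    window <- new_window
    D <- D_new
    if (stable) break
  }
  yw <- y[window]
  structure(list(D_eff = D, amplitude = A,
                 r_squared = r_squared_about_mean(yw, as.numeric(stats::fitted(fit))),
                 L_used = L, n_used = sum(window),
                 tau_window = fit_window_tau_min,
                 converged = TRUE),
            class = "fickian_fit")
}

#' @export
print.fickian_fit <- function(x, ...) {
  cat(sprintf("<fickian_fit> D_eff = %.4g m^2/s (L = %.4g m, A = %.4g, R^2 = %.4f, n = %d)\n",
              x$D_eff, x$L_used, x$amplitude, x$r_squared, x$n_used))
  invisible(x)
}

#' Full release analysis for one monolith
#'
#' Runs the release chain end to end on a gravimetric record: plateau trim,
#' normalization, first-order fit, rate-constant conversion to diffusivity,
#' and the truncated-Fickian fit — the two independent diffusivity routes
#' reported side by side. The two routes may legitimately use different
#' length conventions (see [k_to_diffusivity()]), so each takes its own `L`.
#'
#' @param weights a [decay_series()] of monolith weights (g), times in
#'   minutes.
#' @param plateau_mass non-volatile carrier mass (g).
#' @param L_kinetic characteristic length (m) for the rate-constant route.
#' @param L_fick characteristic length (m) for the truncated-series route.
#' @param plateau_tolerance balance tolerance (g) for [trim_at_plateau()].
#' @param ... passed to [fit_fickian_truncated()].
#' @return A one-row data frame: `M0_g`, `k_per_min`, `D_from_k`, `r2_k`,
#'   `D_eff_fick`, `r2_fick`, `L_kinetic`, `L_fick`.
#' @export
analyze_release <- function(weights, plateau_mass, L_kinetic, L_fick,
                            plateau_tolerance = 1e-4, ...) {
  trimmed <- trim_at_plateau(weights, tolerance = plateau_tolerance)
  frac <- normalize_release(trimmed, plateau_mass)
  # fully released points (fraction <= 0) carry no kinetic information and
  # would break the log-linear initialization
  keep <- frac$value > 0
  if (sum(keep) < 3L) {
    stop_relkin("insufficient_data",
                "fewer than 3 positive remaining-fraction points")
  }
  M0_g <- attr(frac, "M0_g")
  frac <- decay_series(frac$time[keep], frac$value[keep],
                       sample_id = attr(weights, "sample_id"),
                       condition = attr(weights, "condition"),
                       time_unit = attr(frac, "time_unit"))
  attr(frac, "M0_g") <- M0_g
  fo <- fit_first_order_release(frac)
  fick <- fit_fickian_truncated(frac, L = L_fick, ...)
  data.frame(sample_id = attr(weights, "sample_id") %||% NA_character_,
             M0_g = attr(frac, "M0_g") * fo$M0,
             k_per_min = fo$k_per_min,
             D_from_k = k_to_diffusivity(fo$k_per_s, L_kinetic),
             r2_k = fo$r_squared,
             D_eff_fick = fick$D_eff,
             r2_fick = fick$r_squared,
             L_kinetic = L_kinetic, L_fick = L_fick)
}
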