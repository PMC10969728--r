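#' Configure a synthetic trajectory
#'
#' Builds the configuration object consumed by [simulate_stability()] and
#' [simulate_release()]. Each configuration fixes the deterministic model,
#' its ground-truth parameters, the sampling grid, and the noise seed, so a
#' simulation is reproducible bit-for-bit from its config alone: there is no
#' hidden global random state.
#'
#' @param model one of `"zero_order"`, `"first_order"` (stability
#'   trajectories) or `"fickian_full"`, `"fickian_truncated"` (slab-release
#'   curves).
#' @param truth named list of ground-truth parameters. Stability models use
#'   `P0` (initial property level, e.g. absorbance AU) and `k` (rate
#'   constant, per time unit of `dt`). Fickian models use `D` (m^2/s), `L`
#'   (slab length, m), and optionally `M0` (releasable oil mass, g) when a
#'   gravimetric signal is requested.
#' @param n_points number of samples; times are `0, dt, ..., (n_points-1)*dt`.
#' @param dt sampling interval: days for stability, seconds for release.
#' @param seed integer seed; mandatory so replicates are explicit.
#' @param noise_sd standard deviation of additive Gaussian noise, in the
#'   units of the simulated signal. `0` gives the noiseless model exactly.
#' @param n_terms number of eigenfunction-series terms for `"fickian_full"`.
#'   The default 50 leaves truncation error far below double precision for
#'   dimensionless time `tau = D*pi^2*t/L^2 >= 0.05`.
#' @param plateau_mass non-volatile carrier mass in grams, used when
#'   converting a remaining fraction to monolith weight.
#' @param as_mass if `TRUE`, release curves are reported as gravimetric
#'   weights `plateau_mass + M0 * remaining(t)` instead of fractions,
#'   emulating whole-monolith weighing.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config("zero_order", truth = list(P0 = 233, k = 50),
#'                   n_points = 4, dt = 1, seed = 1)
#' simulate_stability(cfg)
sim_config <- function(model = c("zero_order", "first_order",
                                 "fickian_full", "fickian_truncated"),
                       truth, n_points, dt, seed,
                       noise_sd = 0, n_terms = 50L,
                       plateau_mass = 0, as_mass = FALSE) {
  model <- match.arg(model)
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 1 ||
      n_points != round(n_points)) {
    stop_relkin("invalid_config", "`n_points` must be a positive integer")
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop_relkin("invalid_config", "`dt` must be a positive sampling interval")
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_relkin("invalid_config", "an explicit integer `seed` is required")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop_relkin("invalid_config", "`noise_sd` must be non-negative")
  }
  if (!is.numeric(n_terms) || n_terms < 1) {
    stop_relkin("invalid_config", "`n_terms` must be a positive integer")
  }
  if (plateau_mass < 0) {
    stop_relkin("invalid_config", "`plateau_mass` must be non-negative")
  }
  if (!is.list(truth)) stop_relkin("invalid_config", "`truth` must be a list")
  if (model %in% c("zero_order", "first_order")) {
    if (is.null(truth$P0) || is.null(truth$k)) {
      stop_relkin("invalid_config", "stability truth needs `P0` and `k`")
    }
    if (truth$P0 <= 0) stop_relkin("invalid_config", "`P0` must be positive")
    if (truth$k < 0) stop_relkin("invalid_config", "`k` must be non-negative")
  } else {
    if (is.null(truth$D) || is.null(truth$L)) {
      stop_relkin("invalid_config", "Fickian truth needs `D` and `L`")
    }
    if (truth$D < 0) stop_relkin("invalid_config", "`D` must be non-negative")
    if (truth$L <= 0) stop_relkin("invalid_config", "`L` must be positive")
    if (as_mass && is.null(truth$M0)) {
      stop_relkin("invalid_config", "gravimetric output needs `M0` in truth")
    }
  }
  structure(list(model = model, truth = truth,
                 n_points = as.integer(n_points), dt = dt,
                 seed = as.integer(seed), noise_sd = noise_sd,
                 n_terms = as.integer(n_terms),
                 plateau_mass = plateau_mass, as_mass = isTRUE(as_mass)),
            class = "sim_config")
}

#' Simulate an emulsion-stability trajectory
#'
#' Evaluates the zero-order (`P0 - k*t`) or first-order (`P0 * exp(-k*t)`)
#' decay model on the config's time grid and adds independent Gaussian noise
#' `N(0, noise_sd)` to each point. Values are deliberately not clipped at
#' zero: absorbance arithmetic on noisy measurements is unconstrained.
#'
#' @param config a [sim_config()] with a stability model.
#' @return A [decay_series()] in days, with the config stored in attribute
#'   `truth` for parameter-recovery tests.
#' @export
simulate_stability <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!config$model %in% c("zero_order", "first_order")) {
    stop_relkin("invalid_config",
                "simulate_stability() needs model 'zero_order' or 'first_order'")
  }
  t <- (seq_len(config$n_points) - 1) * config$dt
  mu <- if (config$model == "zero_order") {
    config$truth$P0 - config$truth$k * t
  } else {
    config$truth$P0 * exp(-config$truth$k * t)
  }
  y <- add_noise(mu, config)
  out <- decay_series(t, y, sample_id = "sim", condition = config$model,
                      time_unit = "day")
  attr(out, "truth") <- config
  out
}

#' Remaining oil fraction for Fickian desorption from a plane slab
#'
#' Eigenfunction-series solution for the mass fraction still inside a slab
#' with uniform initial loading and perfect-sink surfaces:
#' \deqn{f(t) = \sum_{n \ge 0} \frac{8}{(2n+1)^2 \pi^2}
#'   \exp\!\left(-\frac{(2n+1)^2 \pi^2 D t}{L^2}\right).}
#' At `t = 0` the analytic value is exactly 1 (the series sums to 1 but
#' partial sums converge only O(1/n) there), so that point is returned
#' exactly rather than through the truncated sum.
#'
#' @param t time in seconds (vectorized).
#' @param D diffusivity, m^2/s.
#' @param L slab characteristic length, m (same convention as the fit it
#'   feeds; see [k_to_diffusivity()] for the study's two conventions).
#' @param n_terms number of series terms.
#' @return Remaining fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' fickian_remaining(c(0, 9000), D = 2.4e-10, L = 0.005)
fickian_remaining <- function(t, D, L, n_terms = 50L) {
  if (n_terms < 1) stop_relkin("invalid_config", "`n_terms` must be >= 1")
  if (L <= 0) stop_relkin("invalid_geometry", "`L` must be positive")
  if (D < 0) stop_relkin("invalid_input", "`D` must be non-negative")
  m <- 2 * (seq_len(n_terms) - 1) + 1  # odd mode numbers 1, 3, 5, ...
  vapply(t, function(tt) {
    if (tt == 0 || D == 0) return(1)
    sum(8 / (m^2 * pi^2) * exp(-m^2 * pi^2 * D * tt / L^2))
  }, numeric(1))
}

#' Simulate a slab-release curve
#'
#' Generates a remaining-oil-fraction series on the config's time grid from
#' either the full eigenfunction series (`"fickian_full"`, [fickian_remaining()])
#' or the one-term truncated model (`"fickian_truncated"`,
#' [truncated_remaining_fraction()]). With `as_mass = TRUE` the fraction is
#' converted to a gravimetric signal `plateau_mass + M0 * remaining(t)`,
#' emulating weighing of the whole monolith (carrier plus residual oil).
#' Gaussian noise is added after model evaluation (and after mass
#' conversion), mimicking balance error.
#'
#' @param config a [sim_config()] with a Fickian model.
#' @return A [decay_series()] in seconds with config in attribute `truth`.
#' @export
simulate_release <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!config$model %in% c("fickian_full", "fickian_truncated")) {
    stop_relkin("invalid_config",
                "simulate_release() needs a Fickian model")
  }
  if (config$truth$D <= 0) {
    stop_relkin("invalid_config", "release simulation needs `D` > 0")
  }
  t <- (seq_len(config$n_points) - 1) * config$dt
  frac <- if (config$model == "fickian_full") {
    fickian_remaining(t, config$truth$D, config$truth$L, config$n_terms)
  } else {
    # first term of the mass series (amplitude 8/pi^2), i.e. the truncation
    # of fickian_full itself; evaluated as-is, with no t = 0 special case.
    # The surface-concentration one-term form (amplitude 4/pi) lives in
    # truncated_remaining_fraction().
    (8 / pi^2) * exp(-pi^2 * config$truth$D * t / config$truth$L^2)
  }
  y <- if (config$as_mass) config$plateau_mass + config$truth$M0 * frac else frac
  y <- add_noise(y, config)
  out <- decay_series(t, y, sample_id = "sim", condition = config$model,
                      time_unit = "s")
  attr(out, "truth") <- config
  out
}

add_noise <- function(mu, config) {
  if (config$noise_sd == 0) return(mu)
  mu + with_local_seed(config$seed,
                       stats::rnorm(length(mu), 0, config$noise_sd))
}

#' Write a simulated series with its ground truth
#'
#' Writes a tidy CSV (`sample_id, condition, time, value`) and a JSON
#' sidecar (`<path>.json`) recording the generating model, ground-truth
#' parameters, seed and noise level, so downstream parameter-recovery tests
#' can reload both data and truth.
#'
#' @param series a [decay_series()] produced by a simulator (must carry the
#'   `truth` attribute).
#' @param path CSV output path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(series, path) {
  stopifnot(inherits(series, "decay_series"))
  cfg <- attr(series, "truth")
  if (is.null(cfg)) {
    stop_relkin("invalid_input", "series has no ground-truth config attribute")
  }
  df <- data.frame(sample_id = attr(series, "sample_id"),
                   condition = attr(series, "condition"),
                   time = series$time, value = series$value)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(model = cfg$model, truth = cfg$truth, seed = cfg$seed,
               noise_sd = cfg$noise_sd, dt = cfg$dt, n_points = cfg$n_points,
               n_terms = cfg$n_terms, plateau_mass = cfg$plateau_mass,
               as_mass = cfg$as_mass, time_unit = attr(series, "time_unit"))
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a simulation written by [write_simulation()]
#'
#' @param path CSV path previously passed to [write_simulation()].
#' @return A [decay_series()] with the `truth` attribute restored as a list.
#' @export
read_simulation <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out <- decay_series(df$time, df$value, sample_id = df$sample_id[1],
                      condition = df$condition[1],
                      time_unit = side$time_unit)
  attr(out, "truth") <- side
  out
}
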