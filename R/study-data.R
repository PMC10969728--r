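# Printed study tables (triplicate means) for the six guar/xanthan
# formulations, transcribed as plain data so the pipeline can be exercised
# without external files. Uncertainties are not carried: fits operate on the
# mean trajectories, replicate-level raw data being unpublished.

#' Study gum formulations
#'
#' The six sample formulations: guar and xanthan gum concentrations summing
#' to 1 g/100 g by design.
#'
#' @return Data frame `sample_id, guar_conc, xanthan_conc` (g/100 g).
#' @export
study_formulations <- function() {
  df <- data.frame(
    sample_id = paste0("S", 1:6),
    guar_conc = c(1.0, 0.8, 0.6, 0.4, 0.2, 0.0),
    xanthan_conc = c(0.0, 0.2, 0.4, 0.6, 0.8, 1.0))
  check_formulation(df)
  df
}

check_formulation <- function(df) {
  tot <- df$guar_conc + df$xanthan_conc
  if (any(abs(tot - 1) > 1e-9)) {
    warn_relkin("off_design",
                "gum concentrations do not sum to 1 g/100 g for some samples")
  }
  invisible(df)
}

#' Study monolith geometry
#'
#' Disc monolith dimensions, in meters. The characteristic length `L` of
#' the diffusion model is left to the caller (see [k_to_diffusivity()]);
#' the half-thickness, thickness and radius are all provided.
#'
#' @return Named list: `diameter`, `thickness`, `radius`, `half_thickness`.
#' @export
study_geometry <- function() {
  list(diameter = 0.040, thickness = 0.005,
       radius = 0.020, half_thickness = 0.0025)
}

#' Study emulsion activity (day 0 absorbance)
#'
#' @return Data frame `sample_id, temperature_C, activity` (AU at 600 nm),
#'   18 rows (6 samples x 3 storage temperatures).
#' @export
study_activity <- function() {
  data.frame(
    sample_id = rep(paste0("S", 1:6), each = 3),
    temperature_C = rep(c(5, 20, 35), times = 6),
    activity = c(145.1, 126, 133,
                 180, 215, 166,
                 213, 200, 145,
                 231, 217, 322,
                 236, 228, 242,
                 233, 268, 191))
}

#' Study emulsion stability indices
#'
#' @return Data frame `sample_id, temperature_C, day, stability_pct` for
#'   days 1-3 (day 0 is 100% by definition; see [study_activity()]).
#' @export
study_stability <- function() {
  pct <- rbind(
    c(95, 73, 33),   c(86, 90, 33),     c(80, 94, 22),      # S1: 5, 20, 35
    c(72.5, 84, 33), c(62.3, 71.6, 17.2), c(75, 91, 36),    # S2
    c(66, 65, 34),   c(78, 71, 28),     c(84, 94, 28),      # S3
    c(66, 64, 41),   c(72, 62, 31),     c(53, 57, 27),      # S4
    c(66.5, 53, 34), c(68, 65, 29),     c(64, 68, 32.9),    # S5
    c(72, 48, 36),   c(59.7, 66, 29),   c(75.4, 91, 38))    # S6
  data.frame(
    sample_id = rep(rep(paste0("S", 1:6), each = 3), each = 3),
    temperature_C = rep(rep(c(5, 20, 35), times = 6), each = 3),
    day = rep(1:3, times = 18),
    stability_pct = as.vector(t(pct)))
}

#' Study kinetic-fit table (stability decay)
#'
#' The published zero- and first-order fits per sample and temperature:
#' intercepts, slopes (per day, negative for decay) and R^2.
#'
#' @return Data frame `sample_id, temperature_C, order, intercept, slope,
#'   r_squared`, 36 rows.
#' @export
study_kinetics_table <- function() {
  # columns: zero intercept, zero slope, zero R2, first intercept,
  # first slope, first R2 — one row per sample x temperature
  m <- rbind(
    c(147,   -34, 0.98, 153, -0.35, 0.98),
    c(136.0, -25, 0.75, 135, -0.23, 0.87),
    c(149,   -33, 0.78, 146, -0.28, 0.88),
    c(188,   -38, 0.91, 189, -0.27, 0.85),
    c(218,   -55, 0.93, 221, -0.38, 0.87),
    c(177,   -34, 0.91, 177, -0.24, 0.81),
    c(205,   -41, 0.89, 210, -0.29, 0.89),
    c(206.8, -44, 0.91, 207, -0.29, 0.84),
    c(156,   -29, 0.64, 158, -0.26, 0.77),
    c(219,   -41, 0.89, 225, -0.26, 0.91),
    c(214,   -47, 0.96, 219, -0.32, 0.94),
    c(298,   -71, 0.90, 314, -0.39, 0.93),
    c(224,   -49, 0.95, 233, -0.34, 0.98),
    c(224,   -49, 0.92, 228, -0.32, 0.89),
    c(235,   -49, 0.93, 241, -0.31, 0.92),
    c(225,   -50, 0.97, 234, -0.34, 0.99),
    c(259,   -58, 0.94, 267, -0.34, 0.94),
    c(204,   -38, 0.88, 203, -0.24, 0.82))
  base <- data.frame(
    sample_id = rep(paste0("S", 1:6), each = 3),
    temperature_C = rep(c(5, 20, 35), times = 6))
  rbind(
    cbind(base, order = 0L, intercept = m[, 1], slope = m[, 2],
          r_squared = m[, 3]),
    cbind(base, order = 1L, intercept = m[, 4], slope = m[, 5],
          r_squared = m[, 6]))
}

#' Study powder table (yield and encapsulation efficiency)
#'
#' @return Data frame `sample_id, process_yield, encapsulation_efficiency`
#'   in percent (g/100 g).
#' @export
study_powder_table <- function() {
  data.frame(
    sample_id = paste0("S", 1:6),
    process_yield = c(74, 72, 77, 78, 75, 75),
    encapsulation_efficiency = c(36.3, 59.5, 50.3, 74.4, 69.3, 62.0))
}

#' Study release-modeling table
#'
#' Published first-order release fits and the two diffusivity routes for
#' each monolith at 35 degC: releasable mass `M0_g`, rate `k_per_min`,
#' kinetic-route diffusivity `D_from_k`, truncated-Fickian `D_eff_fick`
#' (both in m^2/s), and the two R^2 values.
#'
#' @return Data frame with one row per sample.
#' @export
study_release_table <- function() {
  data.frame(
    sample_id = paste0("S", 1:6),
    M0_g = c(0.3456, 0.5746, 0.4817, 0.7194, 0.6652, 0.5952),
    k_per_min = c(1.46e-3, 6.69e-4, 7.75e-4, 4.16e-4, 4.83e-4, 6.06e-4),
    D_from_k = c(9.8, 4.5, 5.2, 3.5, 3.4, 4.1) * 1e-10,
    r2_k = c(0.9541, 0.9389, 0.9606, 0.9463, 0.9186, 0.9385),
    D_eff_fick = c(2.4, 1.1, 1.3, 0.7, 0.82, 1.0) * 1e-10,
    r2_fick = c(0.9928, 0.9125, 0.9321, 0.8935, 0.8234, 0.8852))
}

#' Reconstructed study stability trajectories
#'
#' Applies [reconstruct_trajectory()] to every sample x temperature of the
#' study tables: day 0 at the measured activity, later days at
#' `activity * stability / 100`.
#'
#' @return Named list of 18 [decay_series()], names `"<sample>_T<temp>"`.
#' @export
study_trajectories <- function() {
  act <- study_activity()
  stab <- study_stability()
  out <- list()
  for (i in seq_len(nrow(act))) {
    id <- act$sample_id[i]; temp <- act$temperature_C[i]
    s <- stab[stab$sample_id == id & stab$temperature_C == temp, ]
    s <- s[order(s$day), ]
    out[[paste0(id, "_T", temp)]] <-
      reconstruct_trajectory(act$activity[i], s$stability_pct,
                             sample_id = id, condition = paste0("T", temp))
  }
  out
}
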