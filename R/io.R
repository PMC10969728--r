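#' Read a tidy time-series CSV
#'
#' Two schemas are understood. `"stability"` expects columns
#' `sample_id, temperature_C, day, absorbance` (one series per
#' sample x temperature, absorbance in AU, day 0 = activity).
#' `"release"` expects `sample_id, time_min, weight_g` (one gravimetric
#' series per sample). Rows with unparseable numbers are dropped with a
#' warning that reports their line numbers; a missing column is a hard
#' schema error.
#'
#' @param path CSV path (comma-separated, header required, `.` decimal).
#' @param schema `"stability"` or `"release"`.
#' @return A named list of [decay_series()]: names `"<sample>_T<temp>"` for
#'   stability, `"<sample>"` for release.
#' @export
read_timeseries <- function(path, schema = c("stability", "release")) {
  schema <- match.arg(schema)
  cols <- switch(schema,
                 stability = c("sample_id", "temperature_C", "day", "absorbance"),
                 release = c("sample_id", "time_min", "weight_g"))
  df <- utils::read.csv(path, colClasses = "character")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop_relkin("schema_error",
                sprintf("%s: missing column(s): %s", path,
                        paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0L) {
    warn_relkin("empty_input", sprintf("%s: no data rows", path))
    return(structure(list(), names = character(0)))
  }
  num_cols <- setdiff(cols, "sample_id")
  bad <- rep(FALSE, nrow(df))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- bad | is.na(v)
    df[[cc]] <- v
  }
  if (any(bad)) {
    # +1 for the header line
    warn_relkin("bad_rows",
                sprintf("%s: dropped %d unparseable row(s) at line(s) %s",
                        path, sum(bad),
                        paste(which(bad) + 1L, collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
  }
  out <- list()
  if (schema == "stability") {
    for (key in unique(paste0(df$sample_id, "_T", df$temperature_C))) {
      sub <- df[paste0(df$sample_id, "_T", df$temperature_C) == key, ]
      sub <- sub[order(sub$day), ]
      out[[key]] <- decay_series(sub$day, sub$absorbance,
                                 sample_id = sub$sample_id[1],
                                 condition = paste0("T", sub$temperature_C[1]),
                                 time_unit = "day")
    }
  } else {
    for (id in unique(df$sample_id)) {
      sub <- df[df$sample_id == id, ]
      sub <- sub[order(sub$time_min), ]
      out[[id]] <- decay_series(sub$time_min, sub$weight_g,
                                sample_id = id, condition = "release",
                                time_unit = "min")
    }
  }
  out
}

#' Write a collection of decay series as tidy CSV
#'
#' Inverse of [read_timeseries()]: writes the schema the reader expects.
#'
#' @param series named list of [decay_series()].
#' @param path output CSV path.
#' @param schema `"stability"` or `"release"`.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path, schema = c("stability", "release")) {
  schema <- match.arg(schema)
  rows <- lapply(series, function(s) {
    if (schema == "stability") {
      data.frame(sample_id = attr(s, "sample_id"),
                 temperature_C = as.numeric(sub("^T", "", attr(s, "condition"))),
                 day = s$time, absorbance = s$value)
    } else {
      data.frame(sample_id = attr(s, "sample_id"),
                 time_min = s$time, weight_g = s$value)
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles and validates everything [run_pipeline()] needs. The stability
#' input may be a CSV path (see [read_timeseries()]) or omitted to use the
#' built-in study tables. Release-side diffusivities come either from a raw
#' gravimetric CSV (then both `L_kinetic` and `L_fick` are mandatory and
#' validated here, before any computation) or from a precomputed
#' `diffusivity_table` (`sample_id, D_from_k, D_eff_fick`), e.g. the
#' published fits.
#'
#' @param out_dir output directory (created if absent).
#' @param stability_csv optional stability CSV path.
#' @param release_csv optional release CSV path.
#' @param diffusivity_table optional data frame of precomputed diffusivities.
#' @param powder_table data frame `sample_id, encapsulation_efficiency`;
#'   defaults to the built-in study table.
#' @param L_kinetic,L_fick characteristic lengths (m) for the two
#'   diffusivity routes; required with `release_csv`.
#' @param plateau_mass non-volatile carrier mass (g): a single number, a
#'   vector named by sample, or `NULL` to estimate it per sample as the
#'   mean of the detected plateau triple.
#' @param plateau_tolerance balance tolerance (g) for plateau detection.
#' @param aggregation temperature-aggregation mode for the parameter table.
#' @param seed integer seed recorded in the run log (the pipeline itself is
#'   deterministic; the seed is threaded to any simulation inputs).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       stability_csv = NULL,
                       release_csv = NULL,
                       diffusivity_table = NULL,
                       powder_table = study_powder_table(),
                       L_kinetic = NULL, L_fick = NULL,
                       plateau_mass = NULL,
                       plateau_tolerance = 1e-4,
                       aggregation = c("mean", "T5", "T20", "T35"),
                       seed = 1L) {
  aggregation <- match.arg(aggregation)
  if (!is.null(release_csv)) {
    if (is.null(L_kinetic) || is.null(L_fick)) {
      stop_relkin("invalid_config",
                  "release analysis requires explicit `L_kinetic` and `L_fick`")
    }
    if (L_kinetic <= 0 || L_fick <= 0) {
      stop_relkin("invalid_geometry", "characteristic lengths must be positive")
    }
  }
  if (is.null(release_csv) && is.null(diffusivity_table)) {
    stop_relkin("invalid_config",
                "need `release_csv` or a precomputed `diffusivity_table`")
  }
  structure(list(out_dir = out_dir, stability_csv = stability_csv,
                 release_csv = release_csv,
                 diffusivity_table = diffusivity_table,
                 powder_table = powder_table,
                 L_kinetic = L_kinetic, L_fick = L_fick,
                 plateau_mass = plateau_mass,
                 plateau_tolerance = plateau_tolerance,
                 aggregation = aggregation, seed = as.integer(seed)),
            class = "run_config")
}

fit_stability_series <- function(trajectories) {
  rows <- lapply(names(trajectories), function(key) {
    s <- trajectories[[key]]
    z <- fit_zero_order(s)
    f <- tryCatch(fit_first_order(s),
                  relkin_fit_failure = function(e) e$fit)
    data.frame(sample_id = attr(s, "sample_id"),
               temperature_C = as.numeric(sub("^T", "", attr(s, "condition"))),
               zero_intercept = z$intercept,
               zero_slope = z$direction * z$rate,
               zero_r_squared = z$r_squared,
               first_intercept = f$intercept,
               first_slope = f$direction * f$rate,
               first_r_squared = f$r_squared,
               first_converged = f$converged)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the chain end to end: stability trajectories are fitted
#' with both kinetic orders (a fits CSV mirrors the published kinetics
#' table); release curves — when given — are trimmed, normalized and fitted
#' for both diffusivity routes (a release CSV mirrors the published release
#' table, with the length conventions recorded per estimate); the
#' per-sample parameter table is assembled and its Pearson correlation
#' matrix written as square and long CSVs; and a plain-text run log records
#' package version, seed, aggregation and geometry. Any stage failure
#' aborts with the stage name in the error message.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `stability_fits`, `diffusivities`,
#'   `parameter_table`, `correlations`, and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_relkin("stage_failure",
                  sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  trajectories <- stage("stability-input", {
    if (is.null(config$stability_csv)) study_trajectories()
    else read_timeseries(config$stability_csv, "stability")
  })
  fits <- stage("stability-fits", fit_stability_series(trajectories))
  fits_path <- file.path(config$out_dir, "stability_fits.csv")
  utils::write.csv(fits, fits_path, row.names = FALSE)

  diffusivities <- stage("release", {
    if (!is.null(config$release_csv)) {
      curves <- read_timeseries(config$release_csv, "release")
      rows <- lapply(names(curves), function(id) {
        w <- curves[[id]]
        pm <- plateau_mass_for(config$plateau_mass, id, w,
                               config$plateau_tolerance)
        analyze_release(w, plateau_mass = pm,
                        L_kinetic = config$L_kinetic,
                        L_fick = config$L_fick,
                        plateau_tolerance = config$plateau_tolerance)
      })
      do.call(rbind, rows)
    } else {
      config$diffusivity_table
    }
  })
  rel_path <- file.path(config$out_dir, "release_diffusivity.csv")
  utils::write.csv(diffusivities, rel_path, row.names = FALSE)

  ptab <- stage("parameter-table", {
    activity <- do.call(rbind, lapply(trajectories, function(s) {
      data.frame(sample_id = attr(s, "sample_id"),
                 temperature_C = as.numeric(sub("^T", "", attr(s, "condition"))),
                 activity = s$value[1])
    }))
    rates <- data.frame(sample_id = fits$sample_id,
                        temperature_C = fits$temperature_C,
                        zero_order_rate = abs(fits$zero_slope),
                        first_order_rate = abs(fits$first_slope))
    build_parameter_table(activity, rates,
                          diffusivities[, c("sample_id", "D_from_k", "D_eff_fick")],
                          config$powder_table,
                          aggregation = config$aggregation)
  })
  ptab_path <- file.path(config$out_dir, "parameter_table.csv")
  utils::write.csv(ptab, ptab_path, row.names = FALSE)

  cm <- stage("correlation", correlation_matrix(ptab))
  cm_path <- file.path(config$out_dir, "correlation_matrix.csv")
  write_correlation(cm, cm_path)

  log_path <- file.path(config$out_dir, "run_log.txt")
  writeLines(c(
    sprintf("relkin %s", as.character(utils::packageVersion("relkin"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d", config$seed),
    sprintf("aggregation: %s", config$aggregation),
    sprintf("L_kinetic (m): %s", format(config$L_kinetic %||% NA)),
    sprintf("L_fick (m): %s", format(config$L_fick %||% NA)),
    sprintf("plateau tolerance (g): %g", config$plateau_tolerance)),
    log_path)

  invisible(list(stability_fits = fits, diffusivities = diffusivities,
                 parameter_table = ptab, correlations = cm,
                 paths = c(stability = fits_path, release = rel_path,
                           parameters = ptab_path, correlation = cm_path,
                           log = log_path)))
}

plateau_mass_for <- function(plateau_mass, id, weights, tolerance) {
  if (is.null(plateau_mass)) {
    # estimate the non-volatile mass as the mean of the detected plateau
    # triple; fall back to the final reading if the record never levels off
    w <- weights$value
    for (i in seq_len(max(length(w) - 2L, 0L))) {
      trio <- w[i:(i + 2L)]
      if (max(trio) - min(trio) <= tolerance) return(mean(trio))
    }
    return(w[length(w)])
  }
  if (!is.null(names(plateau_mass))) {
    if (!id %in% names(plateau_mass)) {
      stop_relkin("invalid_config",
                  sprintf("no plateau_mass entry for sample %s", id))
    }
    return(plateau_mass[[id]])
  }
  plateau_mass[[1]]
}
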