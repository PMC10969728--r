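#' Sample Pearson correlation coefficient
#'
#' Thin, validated wrapper around [stats::cor()]: both vectors must have
#' equal length of at least 3 and be nonconstant (the coefficient is
#' undefined for a zero-variance argument).
#'
#' @param x,y numeric vectors.
#' @return Correlation in `[-1, 1]`.
#' @export
#' @examples
#' pearson_r(c(9.8, 4.5, 5.2, 3.5, 3.4, 4.1),
#'           c(2.4, 1.1, 1.3, 0.7, 0.82, 1.0))  # ~0.995
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop_relkin("invalid_input", "`x` and `y` must have equal length")
  }
  if (length(x) < 3L) {
    stop_relkin("insufficient_data", "need >= 3 observations")
  }
  if (anyNA(x) || anyNA(y)) {
    stop_relkin("invalid_input", "missing values are not allowed")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_relkin("undefined_correlation",
                "correlation undefined for a constant vector")
  }
  stats::cor(x, y)
}

#' Assemble the per-sample parameter table
#'
#' Joins the sample-level outputs of the whole pipeline — emulsion activity,
#' stability-decay rate constants, the two diffusivity routes, and
#' encapsulation efficiency — into one row per sample, ready for
#' correlation analysis. Temperature-resolved quantities (activity and the
#' stability rates) are collapsed per the `aggregation` mode: the mean over
#' the storage temperatures, or a single temperature. The mode used is
#' stamped into the result's `aggregation` attribute.
#'
#' @param activity data frame `sample_id, temperature_C, activity`.
#' @param stability_rates data frame `sample_id, temperature_C,
#'   zero_order_rate, first_order_rate` (rate magnitudes per day).
#' @param diffusivities data frame `sample_id, D_from_k, D_eff_fick`.
#' @param powder data frame `sample_id, encapsulation_efficiency`.
#' @param aggregation `"mean"`, `"T5"`, `"T20"` or `"T35"`.
#' @return A data frame with one row per sample and columns
#'   `emulsion_activity`, `zero_order_rate`, `first_order_rate`,
#'   `D_from_k`, `D_eff_fick`, `encapsulation_efficiency`, ordered by
#'   `sample_id`.
#' @export
build_parameter_table <- function(activity, stability_rates, diffusivities,
                                  powder,
                                  aggregation = c("mean", "T5", "T20", "T35")) {
  aggregation <- match.arg(aggregation)
  ids <- sort(unique(activity$sample_id))
  for (nm in c("stability_rates", "diffusivities", "powder")) {
    df <- get(nm)
    missing_ids <- setdiff(ids, df$sample_id)
    extra_ids <- setdiff(df$sample_id, ids)
    if (length(missing_ids) || length(extra_ids)) {
      stop_relkin("join_failure",
                  sprintf("`%s` does not cover the same samples (missing: %s; extra: %s)",
                          nm,
                          paste(missing_ids, collapse = ", ") %|e|% "none",
                          paste(extra_ids, collapse = ", ") %|e|% "none"))
    }
  }
  collapse <- function(df, col) {
    vapply(ids, function(id) {
      rows <- df[df$sample_id == id, , drop = FALSE]
      if (aggregation == "mean") return(mean(rows[[col]]))
      temp <- as.numeric(sub("^T", "", aggregation))
      sel <- rows[rows$temperature_C == temp, , drop = FALSE]
      if (nrow(sel) != 1L) {
        stop_relkin("join_failure",
                    sprintf("sample %s has no unique row at %g degC", id, temp))
      }
      sel[[col]]
    }, numeric(1))
  }
  one_per <- function(df, col) {
    vapply(ids, function(id) {
      v <- df[[col]][df$sample_id == id]
      if (length(v) != 1L) {
        stop_relkin("join_failure",
                    sprintf("sample %s must have exactly one `%s`", id, col))
      }
      v
    }, numeric(1))
  }
  out <- data.frame(
    sample_id = ids,
    emulsion_activity = collapse(activity, "activity"),
    zero_order_rate = collapse(stability_rates, "zero_order_rate"),
    first_order_rate = collapse(stability_rates, "first_order_rate"),
    D_from_k = one_per(diffusivities, "D_from_k"),
    D_eff_fick = one_per(diffusivities, "D_eff_fick"),
    encapsulation_efficiency = one_per(powder, "encapsulation_efficiency"),
    row.names = NULL)
  attr(out, "aggregation") <- aggregation
  out
}

`%|e|%` <- function(a, b) if (nzchar(a)) a else b

#' Pearson correlation matrix of a parameter table
#'
#' All pairwise [pearson_r()] values of the numeric parameter columns;
#' symmetric with a unit diagonal by construction.
#'
#' @param table a [build_parameter_table()] result, or any data frame whose
#'   non-`sample_id` columns are complete numeric parameters.
#' @param columns optional character vector restricting/ordering the columns.
#' @return A matrix of class `correlation_matrix` with `n` (sample count)
#'   and `aggregation` attributes.
#' @export
correlation_matrix <- function(table, columns = NULL) {
  cols <- columns %||% setdiff(names(table), "sample_id")
  m <- as.matrix(table[, cols, drop = FALSE])
  if (anyNA(m)) {
    stop_relkin("invalid_input", "no missing cells allowed in correlated columns")
  }
  if (nrow(m) < 3L) {
    stop_relkin("insufficient_data", "need >= 3 samples for correlations")
  }
  p <- length(cols)
  r <- diag(1, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i < j) r[i, j] <- r[j, i] <- pearson_r(m[, i], m[, j])
    }
  }
  dimnames(r) <- list(cols, cols)
  structure(r, class = c("correlation_matrix", "matrix", "array"),
            n = nrow(m), aggregation = attr(table, "aggregation"))
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<correlation_matrix> n = %d%s\n", attr(x, "n"),
              if (!is.null(attr(x, "aggregation")))
                paste0(", aggregation = ", attr(x, "aggregation")) else ""))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Write a correlation matrix as CSV
#'
#' Writes the square labels-by-labels matrix and a long-format companion
#' (`var1, var2, r`) next to it.
#'
#' @param cm a [correlation_matrix()].
#' @param path CSV path for the square matrix; the long format goes to
#'   `<path minus .csv>_long.csv`.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(cm, path) {
  m <- unclass(cm)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  long <- expand.grid(var1 = rownames(m), var2 = colnames(m),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$r <- as.vector(m)
  utils::write.csv(long, sub("\\.csv$", "_long.csv", path), row.names = FALSE)
  invisible(path)
}
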