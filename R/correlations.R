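#' Characteristic phase-diagram points per water model
#'
#' Loads the bundled table of characteristic points in the phase diagram of
#' the 11 registry models at 1 bar: critical point (`T_C`, `rho_C`), point
#' of maximum density (`T_MD`, `rho_MD`) and temperature of spontaneous
#' evaporation (`T_evap`, obtained with stochastic cell-rescaling pressure
#' coupling), each with its block-splitting (or repeat-run) standard
#' deviation. The last row holds the experimental reference values where
#' available.
#'
#' @param include_experiment Keep the experimental reference row
#'   (default TRUE). Cross-model fits exclude it regardless via
#'   `source == "model"`.
#' @param path Optional path to an alternative CSV with the same layout.
#' @return A tibble with one row per model plus (optionally) the
#'   experimental row, and a `source` column (`"model"` / `"experiment"`).
#' @export
phase_diagram_points <- function(include_experiment = TRUE, path = NULL) {
  path <- path %||% system.file("extdata", "phase_diagram_points.csv",
                                package = "aquacoex", mustWork = FALSE)
  if (is.null(path) || !nzchar(path) || !file.exists(path)) {
    abort("bundled phase-diagram table not found; installation is corrupted",
          class = "aquacoex_config_error")
  }
  tbl <- as_tibble(readr::read_csv(path, show_col_types = FALSE))
  tbl$source <- dplyr::if_else(tbl$name == "Experiment", "experiment", "model")
  if (!include_experiment) tbl <- dplyr::filter(tbl, .data$source == "model")
  tbl
}

new_correlation_result <- function(x_name, y_name, n, slope, intercept, r2,
                                   fit_kind) {
  tibble(x_name = x_name, y_name = y_name, n = n, slope = slope,
         intercept = intercept, r2 = r2, fit_kind = fit_kind)
}

#' Ordinary least-squares fit between two model properties
#'
#' Fits `y = slope * x + intercept` by OLS and reports the squared Pearson
#' correlation as `r2`. A constant `y` yields `r2 = 0` by convention; a
#' constant `x` is a degenerate design and errors.
#'
#' @param data A data frame.
#' @param x,y Column names (tidy-eval) of the predictor and response.
#' @return A one-row correlation tibble (`x_name`, `y_name`, `n`, `slope`,
#'   `intercept`, `r2`, `fit_kind = "full-linear"`).
#' @examples
#' phase_diagram_points(include_experiment = FALSE) |> linear_fit(T_C, rho_C)
#' @export
linear_fit <- function(data, x, y) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  linear_fit_xy(xv, yv,
                x_name = rlang::as_label(rlang::enquo(x)),
                y_name = rlang::as_label(rlang::enquo(y)))
}

linear_fit_xy <- function(xv, yv, x_name = "x", y_name = "y") {
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3) abort("need at least three complete pairs")
  if (sd(xv) == 0) abort("predictor has zero variance",
                         class = "aquacoex_domain_error")
  fit <- lm(yv ~ xv)
  r2 <- if (sd(yv) == 0) 0 else stats::cor(xv, yv)^2
  new_correlation_result(
    x_name = x_name, y_name = y_name,
    n = length(xv), slope = coef(fit)[[2]], intercept = coef(fit)[[1]],
    r2 = r2, fit_kind = "full-linear")
}

#' Offset-only fit between two model properties
#'
#' Fits the one-parameter model `y = x + c` with `c = mean(y - x)` and
#' reports `r2 = 1 - SS_res / SS_tot` with `SS_tot` taken about `mean(y)`.
#' Because this model is nested in the full linear fit, its `r2` can never
#' exceed the full-linear one. A good offset-only fit means the two
#' temperatures track each other one-to-one apart from a constant shift.
#'
#' @inheritParams linear_fit
#' @return A one-row correlation tibble with `slope = 1`, `intercept = c`
#'   and `fit_kind = "offset-only"`.
#' @examples
#' phase_diagram_points(include_experiment = FALSE) |> offset_fit(T_C, T_evap)
#' @export
offset_fit <- function(data, x, y) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 2) abort("need at least two complete pairs")
  cc <- mean(yv - xv)
  ss_res <- sum((yv - (xv + cc))^2)
  ss_tot <- sum((yv - mean(yv))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  new_correlation_result(
    x_name = rlang::as_label(rlang::enquo(x)),
    y_name = rlang::as_label(rlang::enquo(y)),
    n = length(xv), slope = 1, intercept = cc, r2 = r2,
    fit_kind = "offset-only")
}

#' Correlate every model parameter with a target property
#'
#' Joins the water-model registry (plus derived dipole and quadrupole
#' moments) with a per-model summary table and runs one [linear_fit()] per
#' predictor in `d_OH`, `phi_HOH`, `sigma_O`, `epsilon_O`, `q_H`, `mu`,
#' `Q_T`, ranked by decreasing `r2`. Predictors with zero variance (or too
#' few complete pairs) are skipped with a warning.
#'
#' @param summaries Per-model table with a `name` column and the target
#'   column (e.g. [phase_diagram_points()]).
#' @param target Name of the target column (string or tidy-eval),
#'   e.g. `T_evap`.
#' @param models Registry table (default [water_models()]).
#' @return Correlation tibble, one row per usable predictor, sorted by `r2`.
#' @examples
#' property_scan(phase_diagram_points(include_experiment = FALSE), T_evap)
#' @export
property_scan <- function(summaries, target, models = water_models()) {
  target_name <- rlang::as_name(rlang::ensym(target))
  if (!target_name %in% names(summaries)) {
    abort(paste0("target column '", target_name, "' not found in summaries"))
  }
  preds <- dplyr::left_join(models, derived_moments(models), by = "name")
  joined <- dplyr::inner_join(preds, summaries[, c("name", target_name)],
                              by = "name")
  predictors <- c("d_OH", "phi_HOH", "sigma_O", "epsilon_O", "q_H", "mu", "Q_T")
  rows <- purrr::map(predictors, function(p) {
    xv <- joined[[p]]
    yv <- joined[[target_name]]
    keep <- is.finite(xv) & is.finite(yv)
    dropped <- sum(!keep)
    if (dropped > 0) {
      warn(sprintf("predictor %s: dropped %d incomplete pair(s)", p, dropped))
    }
    if (sum(keep) < 3 || sd(xv[keep]) == 0) {
      warn(sprintf("predictor %s skipped (zero variance or too few pairs)", p))
      return(NULL)
    }
    linear_fit_xy(xv[keep], yv[keep], x_name = p, y_name = target_name)
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) abort("no usable predictors")
  dplyr::arrange(out, dplyr::desc(.data$r2))
}

#' Scatter plot of one cross-model correlation
#'
#' @param data Per-model table.
#' @param x,y Columns to correlate (tidy-eval).
#' @param fit `"full-linear"` or `"offset-only"` trend line.
#' @return A ggplot with points labelled by model name and the fitted line.
#' @export
plot_correlation <- function(data, x, y, fit = c("full-linear", "offset-only")) {
  fit <- match.arg(fit)
  res <- if (fit == "full-linear") {
    linear_fit(data, {{ x }}, {{ y }})
  } else {
    offset_fit(data, {{ x }}, {{ y }})
  }
  ggplot2::ggplot(data, ggplot2::aes(x = {{ x }}, y = {{ y }})) +
    ggplot2::geom_abline(slope = res$slope, intercept = res$intercept,
                         linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(subtitle = sprintf("%s fit: R² = %.3f", res$fit_kind,
                                     res$r2)) +
    ggplot2::theme_minimal()
}
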