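# Grayscale <-> concentration calibration with inverse prediction.
#
# Classical calibration: the signal is regressed on concentration by
# ordinary least squares, and unknowns are quantified by algebraic
# inversion of the fitted line. Precision is profiled per level as the CV
# of the back-calculated concentrations.

#' Fit the linear calibration curve
#'
#' @param points Data frame of calibration standards: `concentration`
#'   (mIU/mL), `signal` (grayscale units), optional `replicate_id`.
#' @param log_concentration Regress on `log(concentration)` instead
#'   (default `FALSE`; the response is linear in concentration over the
#'   working range).
#' @param polarity Recorded signal convention: `"net"`
#'   (background-corrected, increases with concentration; default) or
#'   `"raw"` (band grayscale, decreases). Informational; either monotone
#'   orientation fits and inverts.
#' @return An object of class `calibration_model`: `slope`, `intercept`
#'   (grayscale per mIU/mL and grayscale units), `r_squared`,
#'   `residual_sd` (n-2 divisor), `range` (fitted concentration range),
#'   `accepted` (`FALSE` for a flat, non-invertible fit), plus the data
#'   and the underlying `lm` fit.
#' @export
fit_calibration <- function(points, log_concentration = FALSE,
                            polarity = c("net", "raw")) {
  polarity <- match.arg(polarity)
  points <- tibble::as_tibble(points)
  if (!all(c("concentration", "signal") %in% names(points))) {
    abort_input("`points` needs `concentration` and `signal` columns.")
  }
  points <- points[!is.na(points$signal), ]
  if (length(unique(points$concentration)) < 2) {
    abort("calibration needs at least 2 distinct concentrations.",
          class = "lfaquant_error_degenerate")
  }
  x <- if (log_concentration) log(points$concentration) else points$concentration
  fit <- lm(points$signal ~ x)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((points$signal - mean(points$signal))^2)
  if (ss_tot == 0) slope <- 0  # flat signal: no usable response
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  n <- nrow(points)
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         residual_sd = if (n > 2) sqrt(ss_res / (n - 2)) else 0,
         range = range(points$concentration), polarity = polarity,
         log_concentration = log_concentration,
         accepted = is.finite(slope) && slope != 0,
         n = n, data = points, fit = fit),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration: signal = %.4g + %.4g * %s | R^2 = %.4f | range %g-%g mIU/mL%s>\n",
    x$intercept, x$slope,
    if (x$log_concentration) "log(conc)" else "conc",
    x$r_squared, x$range[1], x$range[2],
    if (x$accepted) "" else " | REJECTED (flat)"))
  invisible(x)
}

#' Predicted signal at given concentrations
#'
#' @param object A `calibration_model`.
#' @param concentration Concentrations, mIU/mL.
#' @param ... Unused.
#' @return Predicted signals (grayscale units).
#' @export
predict.calibration_model <- function(object, concentration, ...) {
  x <- if (object$log_concentration) log(concentration) else concentration
  object$intercept + object$slope * x
}

#' @export
tidy.calibration_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std.error = s[, "Std. Error"],
                 statistic = s[, "t value"],
                 p.value = s[, "Pr(>|t|)"])
}

#' @export
glance.calibration_model <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, residual_sd = x$residual_sd,
                 slope = x$slope, intercept = x$intercept, n = x$n,
                 accepted = x$accepted)
}

#' @export
autoplot.calibration_model <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(
    concentration = seq(object$range[1], object$range[2], length.out = 100))
  grid$signal <- predict(object, grid$concentration)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$concentration, y = .data$signal)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "concentration (mIU/mL)",
                  y = sprintf("signal (%s grayscale)", object$polarity),
                  title = "Calibration curve",
                  subtitle = sprintf("R² = %.4f", object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Invert the calibration curve to quantify unknowns
#'
#' @param model An accepted `calibration_model` (or the path/list from
#'   [read_model_json()]).
#' @param signal Measured signals, grayscale units.
#' @param truth Optional known concentrations (recycled), to report
#'   percent error.
#' @return A tibble `signal`, `estimate` (mIU/mL), `in_range` (within the
#'   fitted concentration range; estimates outside it are extrapolations),
#'   and `percent_error` when `truth` is given.
#' @export
invert_calibration <- function(model, signal, truth = NULL) {
  stopifnot(inherits(model, "calibration_model"))
  if (!model$accepted || model$slope == 0) {
    abort("calibration model is not invertible (zero slope).",
          class = "lfaquant_error_degenerate")
  }
  est <- (signal - model$intercept) / model$slope
  if (model$log_concentration) est <- exp(est)
  out <- tibble::tibble(
    signal = signal, estimate = est,
    in_range = !is.na(est) & est >= model$range[1] & est <= model$range[2])
  if (!is.null(truth)) {
    out$truth <- rep_len(truth, nrow(out))
    out$percent_error <- 100 * abs(out$estimate - out$truth) / out$truth
  }
  out
}

#' Per-level precision of back-calculated concentrations
#'
#' Back-calculates every replicate through the calibration curve and
#' summarises each nominal level: the CV (100 * sd / mean of the
#' estimated concentrations) and the percent error of the mean estimate
#' against the nominal value. Levels with a single replicate have no CV
#' and are flagged.
#'
#' @param points Calibration replicates (`concentration`, `signal`).
#' @param model An accepted `calibration_model`.
#' @return A tibble per level: `concentration`, `n`, `mean_estimate`,
#'   `cv`, `percent_error`, `cv_defined`.
#' @export
precision_profile <- function(points, model) {
  points <- tibble::as_tibble(points)
  points <- points[!is.na(points$signal), ]
  est <- invert_calibration(model, points$signal)$estimate
  points$estimate <- est
  points |>
    dplyr::group_by(.data$concentration) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_estimate = mean(.data$estimate),
      cv = ifelse(dplyr::n() > 1,
                  100 * sd(.data$estimate) / mean(.data$estimate), NA_real_),
      .groups = "drop") |>
    dplyr::mutate(
      percent_error = 100 * abs(.data$mean_estimate - .data$concentration) /
        .data$concentration,
      cv_defined = !is.na(.data$cv))
}
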