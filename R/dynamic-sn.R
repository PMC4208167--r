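# The dynamic signal-to-noise statistic.
#
# A strip reader is a measurement system: it should report grayscale y
# proportional to a known reference grayscale M (ideal slope 1). Each
# screening run therefore fits y_i = beta * M_i and summarises quality as
#   S/N = -10 log10(Sd^2 / beta^2)   [dB, larger is better]
# where beta is the fitted slope and Sd the residual spread about the line.

#' Fit the dynamic (reference-proportional) response of one run
#'
#' Fits measured grayscales against reference grayscales. The default is
#' the zero-point-proportional regression through the origin, the standard
#' dynamic characteristic: `beta = sum(M*y)/sum(M^2)`, with residual spread
#' `sd = sqrt(sum((y - beta*M)^2)/(n - 1))`. `method = "intercept"` fits an
#' ordinary straight line instead (slope taken as beta, residual spread
#' with an n-2 divisor).
#'
#' @param standard Reference grayscales `M` (numeric, length >= 2).
#' @param measured Measured grayscales `y` (same length).
#' @param method `"origin"` (default) or `"intercept"`.
#' @return A list of class `dynamic_fit` with `beta`, `sd`, `n`, `method`.
#' @examples
#' fit_dynamic(c(247, 249, 251, 253, 255), c(248, 248, 252, 252, 255))
#' @export
fit_dynamic <- function(standard, measured, method = c("origin", "intercept")) {
  method <- match.arg(method)
  if (!is.numeric(standard) || !is.numeric(measured)) {
    abort_input("`standard` and `measured` must be numeric vectors.")
  }
  n <- length(standard)
  if (length(measured) != n) {
    abort_input("`standard` and `measured` must have equal length.")
  }
  if (n < 2) abort_input("at least 2 signal pairs are required.")
  if (anyNA(standard) || anyNA(measured)) abort_input("signals contain NA.")
  if (all(standard == 0)) {
    abort("all reference signals are zero: slope is undefined.",
          class = "lfaquant_error_degenerate")
  }
  if (method == "origin") {
    beta <- sum(standard * measured) / sum(standard^2)
    resid <- measured - beta * standard
    s <- sqrt(sum(resid^2) / (n - 1))
  } else {
    fit <- lm(measured ~ standard)
    beta <- unname(coef(fit)[2])
    resid <- stats::residuals(fit)
    s <- if (n > 2) sqrt(sum(resid^2) / (n - 2)) else 0
  }
  structure(list(beta = beta, sd = s, n = n, method = method),
            class = "dynamic_fit")
}

#' @export
print.dynamic_fit <- function(x, ...) {
  cat(sprintf("<dynamic fit (%s): beta = %.6g, sd = %.6g, n = %d>\n",
              x$method, x$beta, x$sd, x$n))
  invisible(x)
}

#' @export
tidy.dynamic_fit <- function(x, ...) {
  tibble::tibble(beta = x$beta, sd = x$sd, n = x$n, method = x$method,
                 sn_db = sn_dynamic(x$beta, x$sd))
}

#' Dynamic signal-to-noise ratio in decibels
#'
#' `S/N = -10 log10(sd^2 / beta^2) = 20 log10(|beta| / sd)`, the
#' larger-the-better dynamic characteristic. Strictly increasing in
#' `|beta|` and strictly decreasing in `sd`. A perfect fit (`sd = 0`) is an
#' unbounded-S/N outcome and is returned as `Inf`.
#'
#' @param beta Fitted slope (nonzero), or a `dynamic_fit` object.
#' @param sd Residual spread (>= 0). Ignored when `beta` is a `dynamic_fit`.
#' @return S/N in dB (`Inf` for a perfect fit).
#' @examples
#' sn_dynamic(1, 0.1) # 20 dB
#' @export
sn_dynamic <- function(beta, sd) {
  if (inherits(beta, "dynamic_fit")) {
    sd <- beta$sd
    beta <- beta$beta
  }
  if (!is.numeric(beta) || !is.numeric(sd)) {
    abort_input("`beta` and `sd` must be numeric.")
  }
  if (any(beta == 0)) {
    abort("slope beta = 0: S/N is undefined.",
          class = "lfaquant_error_degenerate")
  }
  if (any(sd < 0)) abort_input("`sd` must be >= 0.")
  ifelse(sd == 0, Inf, -10 * log10(sd^2 / beta^2))
}

#' Per-run dynamic responses for a screening experiment
#'
#' Takes a run table in wide form -- one row per run with measured
#' grayscale columns `y_1..y_k` (and optionally reference columns
#' `M_1..M_k`; otherwise `targets` is used for every run) -- and returns
#' each run's fitted slope, residual spread and S/N.
#'
#' Signals are divided by 255 before fitting by default, so residual
#' spreads (and hence S/N values) are on the normalized 0--1 grayscale
#' scale on which dynamic S/N values of strip readers are conventionally
#' quoted; the slope is unaffected by this choice.
#'
#' @param run_data Data frame with a `run` (or `run_index`) column and
#'   `y_1..y_k` measured-signal columns; optional `M_1..M_k` columns.
#' @param targets Reference grayscales used when no `M_*` columns are
#'   present. Defaults to [reference_targets()].
#' @param normalize Divide signals by 255 before fitting (default `TRUE`).
#' @param method Passed to [fit_dynamic()].
#' @return A tibble with columns `run`, `beta`, `sd`, `sn_db`.
#' @export
run_responses <- function(run_data, targets = reference_targets(),
                          normalize = TRUE,
                          method = c("origin", "intercept")) {
  method <- match.arg(method)
  run_data <- tibble::as_tibble(run_data)
  run_col <- intersect(c("run", "run_index"), names(run_data))[1]
  if (is.na(run_col)) abort_input("run data needs a `run` or `run_index` column.")
  y_cols <- grep("^y_\\d+$", names(run_data), value = TRUE)
  m_cols <- grep("^M_\\d+$", names(run_data), value = TRUE)
  if (length(y_cols) == 0) abort_input("run data has no `y_*` measured-signal columns.")
  y_cols <- y_cols[order(as.integer(sub("^y_", "", y_cols)))]
  if (length(m_cols) > 0) {
    m_cols <- m_cols[order(as.integer(sub("^M_", "", m_cols)))]
    if (length(m_cols) != length(y_cols)) {
      abort_input("`M_*` and `y_*` column counts differ.")
    }
  }
  scale <- if (normalize) 255 else 1
  purrr::map_dfr(seq_len(nrow(run_data)), function(i) {
    y <- as.numeric(run_data[i, y_cols])
    m <- if (length(m_cols) > 0) as.numeric(run_data[i, m_cols]) else targets
    fit <- fit_dynamic(m / scale, y / scale, method = method)
    tibble::tibble(run = run_data[[run_col]][i], beta = fit$beta,
                   sd = fit$sd, sn_db = sn_dynamic(fit))
  })
}
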