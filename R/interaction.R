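# Two-factor interaction diagnostics from the screening runs.

#' Interaction cell means for a pair of design columns
#'
#' Crosses the two columns' levels, averages the run S/N in each of the
#' four cells (each holds exactly `n_runs/4` runs by orthogonality) and
#' summarises non-parallelism of the two level profiles:
#' `|(m22 - m21) - (m12 - m11)|`, which is zero exactly when the profiles
#' are parallel (no interaction).
#'
#' For a 12-run Plackett-Burman design a warning (class
#' `lfaquant_l12_confounding`) is always raised: in that design two-factor
#' interactions are partially confounded with the main effects of *all*
#' other columns, so the cell means are screening evidence only. The
#' documented workflow for a suspected interaction is a dedicated 2x2
#' full-factorial follow-up experiment at re-chosen level values.
#'
#' @param design A `taguchi_oa` object.
#' @param sn Run S/N vector, length `n_runs`.
#' @param col_a,col_b Distinct column indices.
#' @return An object of class `sn_interaction`: list with `columns`,
#'   `cell_means` (2x2 matrix, rows = `col_a` level), `cell_n`,
#'   `nonparallelism` (dB), `best_cell` (levels of the maximal cell; ties
#'   resolve to the lexicographically smallest pair), `confounded` flag.
#' @export
interaction_cells <- function(design, sn, col_a, col_b) {
  stopifnot(inherits(design, "taguchi_oa"))
  if (!is.numeric(sn) || length(sn) != design$n_runs) {
    abort_input(sprintf("`sn` must be a numeric vector of length %d.",
                        design$n_runs))
  }
  cols <- c(col_a, col_b)
  if (any(cols < 1 | cols > design$n_columns)) {
    abort_input("column index outside the design.")
  }
  if (col_a == col_b) abort_input("`col_a` and `col_b` must differ.")
  a <- design$cells[, col_a]
  b <- design$cells[, col_b]
  m <- matrix(NA_real_, 2, 2,
              dimnames = list(paste0("a", 1:2), paste0("b", 1:2)))
  n <- matrix(0L, 2, 2)
  for (la in 1:2) for (lb in 1:2) {
    idx <- a == la & b == lb
    n[la, lb] <- sum(idx)
    m[la, lb] <- mean(sn[idx])
  }
  nonpar <- abs((m[2, 2] - m[2, 1]) - (m[1, 2] - m[1, 1]))
  best <- which(m == max(m), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  confounded <- design$name == "L12"
  if (confounded) {
    warn(paste("L12 is a Plackett-Burman design: two-factor interactions",
               "are partially confounded across all columns; treat these",
               "cell means as screening evidence and confirm with a 2x2",
               "full-factorial follow-up."),
         class = "lfaquant_l12_confounding")
  }
  structure(
    list(columns = c(col_a, col_b), cell_means = m, cell_n = n,
         nonparallelism = nonpar,
         best_cell = c(level_a = unname(best[1]), level_b = unname(best[2])),
         confounded = confounded),
    class = "sn_interaction")
}

#' @export
print.sn_interaction <- function(x, ...) {
  cat(sprintf("<interaction cols %d x %d | nonparallelism %.3f dB | best cell (%d,%d)%s>\n",
              x$columns[1], x$columns[2], x$nonparallelism,
              x$best_cell[1], x$best_cell[2],
              if (x$confounded) " | confounded (L12)" else ""))
  print(round(x$cell_means, 4))
  invisible(x)
}

#' @export
tidy.sn_interaction <- function(x, ...) {
  tidyr::expand_grid(level_a = 1:2, level_b = 1:2) |>
    dplyr::mutate(mean_sn = purrr::map2_dbl(.data$level_a, .data$level_b,
                                            ~ x$cell_means[.x, .y]),
                  n = purrr::map2_int(.data$level_a, .data$level_b,
                                      ~ x$cell_n[.x, .y]))
}

#' @export
autoplot.sn_interaction <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$level_a),
                                  y = .data$mean_sn,
                                  group = factor(.data$level_b),
                                  colour = factor(.data$level_b))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("column %d level", object$columns[1]),
                  y = "mean S/N (dB)",
                  colour = sprintf("column %d", object$columns[2]),
                  title = "Interaction plot",
                  subtitle = if (object$confounded)
                    "L12: interactions partially confounded; screening evidence only"
                  else NULL) +
    ggplot2::theme_minimal()
}
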