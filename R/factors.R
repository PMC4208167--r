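# Factor definitions: which camera parameter sits on which array column,
# and the two concrete settings compared at levels 1 and 2. Level values
# are opaque labels (boolean, numeric or tokens such as "Auto"); the
# engine never interprets them.

#' Build a factor assignment table
#'
#' @param factor_id Unique short ids (letters by convention).
#' @param name Human-readable parameter names.
#' @param level1,level2 The concrete settings at each level (coerced to
#'   character; values are opaque labels).
#' @param column Design column per factor (defaults to 1, 2, ...).
#' @return A tibble `factor_id`, `name`, `column`, `level1`, `level2`.
#' @export
factor_table <- function(factor_id, name = factor_id,
                         level1, level2, column = seq_along(factor_id)) {
  if (anyDuplicated(factor_id)) abort_input("factor ids must be unique.")
  if (anyDuplicated(column)) abort_input("columns must be unique.")
  tibble::tibble(factor_id = as.character(factor_id),
                 name = as.character(name),
                 column = as.integer(column),
                 level1 = as.character(level1),
                 level2 = as.character(level2))
}

#' The ten CMOS camera parameters screened for the hCG strip reader
#'
#' The acquisition parameters of a USB CMOS camera module that affect the
#' captured strip image, with the two settings compared in the reference
#' screening experiment: backlight compensation, brightness, contrast,
#' exposure, gain, gamma, hue, saturation, sharpness and white balance,
#' assigned to columns 1--10 of a 12-run array (column 11 left spare as
#' the error column).
#'
#' @return A factor table (see [factor_table()]).
#' @export
hcg_camera_factors <- function() {
  factor_table(
    factor_id = LETTERS[1:10],
    name = c("backlight_compensation", "brightness", "contrast", "exposure",
             "gain", "gamma", "hue", "saturation", "sharpness",
             "white_balance"),
    level1 = c("TRUE", "-8", "0.4", "0.4", "2", "1", "0", "50", "0", "Auto"),
    level2 = c("FALSE", "-4", "0.5", "0.3", "0", "3", "0.4", "100", "3", "2800"))
}

.extdata <- function(file) {
  system.file("extdata", file, package = "lfaquant", mustWork = TRUE)
}

#' Level-mean S/N summary of the reference hCG reader screening
#'
#' The per-factor level means (dB) measured in the reference L12 screening
#' of the ten camera parameters (plus the spare error column `K`), shipped
#' as the package's worked example. Feed it to [as_response_table()] to
#' obtain a full response table.
#'
#' @return A tibble `term`, `column`, `level1_mean`, `level2_mean`.
#' @export
hcg_screening_table <- function() {
  readr::read_csv(.extdata("hcg_screening_levels.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Confirmation-run summaries of the reference hCG reader
#'
#' Five-replicate confirmation summaries at the baseline camera settings,
#' at the first optimized settings (backlight compensation, gamma and
#' sharpness moved to their best levels) and at the refined optimum found
#' by the follow-up sharpness interaction experiment. `beta`/`sd` are the
#' fitted dynamic slope and residual spread (normalized grayscale);
#' `sn_db` the reported mean S/N.
#'
#' @return A tibble `condition`, `beta`, `sd`, `sn_db`.
#' @export
hcg_confirmation_runs <- function() {
  readr::read_csv(.extdata("hcg_confirmation_runs.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Promote a level-mean table to a response table
#'
#' Computes effects, ranges and ranks from published level means, with the
#' grand mean taken as the average of the per-row level-mean midpoints
#' (identical across rows for a balanced design, up to printing).
#'
#' @param levels A data frame with `term`, `column`, `level1_mean`,
#'   `level2_mean`.
#' @return An `sn_response_table`.
#' @export
as_response_table <- function(levels) {
  levels <- tibble::as_tibble(levels)
  need <- c("term", "column", "level1_mean", "level2_mean")
  if (!all(need %in% names(levels))) {
    abort_input(paste("level table needs columns:", paste(need, collapse = ", ")))
  }
  effect <- levels$level2_mean - levels$level1_mean
  rng <- abs(effect)
  rk <- integer(length(rng))
  rk[order(-rng, seq_along(rng))] <- seq_along(rng)
  out <- tibble::tibble(term = levels$term, column = as.integer(levels$column),
                        level1_mean = levels$level1_mean,
                        level2_mean = levels$level2_mean,
                        effect = effect, range = rng, rank = rk)
  structure(out, class = c("sn_response_table", class(out)),
            grand_mean = mean((levels$level1_mean + levels$level2_mean) / 2),
            design_name = sprintf("L%d_levels", nrow(levels) + 1))
}

#' Main-effects (response) graph
#'
#' @param object An `sn_response_table`.
#' @param ... Unused.
#' @return A ggplot: level means per factor with the grand mean as a
#'   reference line.
#' @export
autoplot.sn_response_table <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("level1_mean", "level2_mean"),
                        names_to = "level", values_to = "mean_sn") |>
    dplyr::mutate(level = ifelse(.data$level == "level1_mean", 1L, 2L))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$level), y = .data$mean_sn,
                                  group = .data$term)) +
    ggplot2::geom_hline(yintercept = attr(object, "grand_mean"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~term, nrow = 1) +
    ggplot2::labs(x = "level", y = "mean S/N (dB)",
                  title = "Response graph") +
    ggplot2::theme_minimal()
}
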