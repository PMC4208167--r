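# Response-table (main-effects) analysis of a screening experiment.

.term_labels <- function(design, assignment = NULL) {
  labels <- sprintf("col%d", seq_len(design$n_columns))
  n_err <- 0L
  if (!is.null(assignment)) {
    assignment <- tibble::as_tibble(assignment)
    stopifnot(all(c("factor_id", "column") %in% names(assignment)))
    if (anyDuplicated(assignment$factor_id) || anyDuplicated(assignment$column)) {
      abort_input("factor ids and columns in an assignment must be unique.")
    }
    if (any(assignment$column < 1 | assignment$column > design$n_columns)) {
      abort_input("assignment refers to a column outside the design.")
    }
    labels[assignment$column] <- assignment$factor_id
    err <- setdiff(seq_len(design$n_columns), assignment$column)
    labels[err] <- sprintf("err%d", seq_along(err))
  }
  labels
}

#' Response table: per-factor level means of the run S/N
#'
#' For every column of the design, averages the run S/N values over the
#' runs held at level 1 and at level 2. The effect is the level-2 mean
#' minus the level-1 mean, the range its absolute value, and columns are
#' ranked by descending range (ties broken by column order). Because the
#' design is balanced, the average of the two level means equals the grand
#' mean for every column.
#'
#' @param design A `taguchi_oa` object.
#' @param sn Numeric vector of run S/N values (dB), length `n_runs`.
#' @param assignment Optional factor assignment: data frame with
#'   `factor_id` and `column` columns. Unassigned columns are retained and
#'   labelled `err1`, `err2`, ... (they estimate experimental error).
#' @return A tibble of class `sn_response_table` with columns `term`,
#'   `column`, `level1_mean`, `level2_mean`, `effect`, `range`, `rank`,
#'   and attribute `grand_mean`.
#' @export
sn_response_table <- function(design, sn, assignment = NULL) {
  stopifnot(inherits(design, "taguchi_oa"))
  if (!is.numeric(sn) || length(sn) != design$n_runs) {
    abort_input(sprintf("`sn` must be a numeric vector of length %d.",
                        design$n_runs))
  }
  m <- design$cells
  l1 <- vapply(seq_len(ncol(m)), function(j) mean(sn[m[, j] == 1L]), numeric(1))
  l2 <- vapply(seq_len(ncol(m)), function(j) mean(sn[m[, j] == 2L]), numeric(1))
  effect <- l2 - l1
  rng <- abs(effect)
  # descending range; ties keep column order
  rk <- integer(length(rng))
  rk[order(-rng, seq_along(rng))] <- seq_along(rng)
  out <- tibble::tibble(
    term = .term_labels(design, assignment),
    column = seq_len(design$n_columns),
    level1_mean = l1, level2_mean = l2,
    effect = effect, range = rng, rank = rk)
  structure(out,
            class = c("sn_response_table", class(out)),
            grand_mean = mean(sn), design_name = design$name)
}

#' Grand mean of a response table
#' @param table An `sn_response_table`.
#' @return The grand-mean S/N (dB).
#' @export
grand_mean <- function(table) attr(table, "grand_mean")

#' @export
print.sn_response_table <- function(x, ...) {
  cat(sprintf("# Response table (%s design), grand mean %.4f dB\n",
              attr(x, "design_name") %||% "?", attr(x, "grand_mean")))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Best level per factor under the larger-the-better rule
#'
#' @param table An `sn_response_table`.
#' @return A tibble `term`, `column`, `best_level` where `best_level` is
#'   the level with the larger mean S/N (ties resolve to level 1).
#' @export
best_levels <- function(table) {
  stopifnot(inherits(table, "sn_response_table"))
  tibble::tibble(
    term = table$term, column = table$column,
    best_level = ifelse(table$level2_mean > table$level1_mean, 2L, 1L))
}

#' Rebuild a run-S/N vector from a grand mean and column effects
#'
#' Constructs the additive model `sn_i = grand + sum_j effect_j/2 * s_ij`
#' with `s = -1/+1` at level 1/2. By orthogonality the resulting vector
#' reproduces the given effects and grand mean exactly through
#' [sn_response_table()]; it is the canonical reconstruction of a run
#' vector consistent with a published level-mean table.
#'
#' @param design A `taguchi_oa` object.
#' @param grand Grand-mean S/N (dB).
#' @param effects Numeric vector of per-column effects (level-2 mean minus
#'   level-1 mean), length `n_columns`.
#' @return Numeric vector of `n_runs` S/N values.
#' @export
sn_from_effects <- function(design, grand, effects) {
  stopifnot(inherits(design, "taguchi_oa"))
  if (length(effects) != design$n_columns) {
    abort_input("`effects` must have one entry per design column.")
  }
  signs <- ifelse(design$cells == 2L, 1, -1)
  as.numeric(grand + signs %*% (effects / 2))
}

#' Choose optimal levels, adjusting only the significant factors
#'
#' Implements the baseline-preserving optimal-level rule: factors screened
#' as significant are moved to their best level; every other factor keeps
#' its baseline setting. The predicted S/N at the chosen condition is the
#' additive estimate `grand_mean + sum over significant factors of
#' (chosen-level mean - grand_mean)`.
#'
#' @param table An `sn_response_table`.
#' @param significant Character vector of significant factor terms
#'   (possibly empty), e.g. from [significant_factors()].
#' @param baseline Named integer vector of baseline levels per factor term;
#'   `NULL` means level 1 for every non-error term in `table`.
#' @return An object of class `optimal_selection`: list with `levels`
#'   (tibble `term`, `column`, `baseline`, `chosen`, `chosen_mean`),
#'   `significant`, `predicted_sn`, `grand_mean`.
#' @export
select_optimal <- function(table, significant = character(), baseline = NULL) {
  stopifnot(inherits(table, "sn_response_table"))
  factors <- if (is.null(baseline)) {
    grep("^(col|err)\\d+$", table$term, value = TRUE, invert = TRUE)
  } else names(baseline)
  if (length(factors) == 0) factors <- table$term
  if (is.null(baseline)) baseline <- setNames(rep(1L, length(factors)), factors)
  unknown <- setdiff(significant, table$term)
  if (length(unknown) > 0) {
    abort_input(paste0("unknown factor id(s) in `significant`: ",
                       paste(unknown, collapse = ", ")))
  }
  if (!all(factors %in% table$term)) {
    abort_input("`baseline` names must match response-table terms.")
  }
  tab <- table[match(factors, table$term), ]
  best <- ifelse(tab$level2_mean > tab$level1_mean, 2L, 1L)
  chosen <- ifelse(factors %in% significant, best, as.integer(baseline[factors]))
  chosen_mean <- ifelse(chosen == 2L, tab$level2_mean, tab$level1_mean)
  gm <- attr(table, "grand_mean")
  predicted <- gm + sum((chosen_mean - gm)[factors %in% significant])
  structure(
    list(levels = tibble::tibble(term = factors, column = tab$column,
                                 baseline = as.integer(baseline[factors]),
                                 chosen = chosen, chosen_mean = chosen_mean),
         significant = significant, predicted_sn = predicted, grand_mean = gm),
    class = "optimal_selection")
}

#' @export
print.optimal_selection <- function(x, ...) {
  lv <- x$levels
  cat(sprintf("<optimal selection: %s | predicted S/N %.2f dB>\n",
              paste0(lv$term, lv$chosen, collapse = " "), x$predicted_sn))
  if (length(x$significant)) {
    cat("  adjusted (significant):", paste(x$significant, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.optimal_selection <- function(x, ...) x$levels

#' @export
glance.optimal_selection <- function(x, ...) {
  tibble::tibble(predicted_sn = x$predicted_sn, grand_mean = x$grand_mean,
                 n_adjusted = length(x$significant))
}
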