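# ANOVA factor screening on the run S/N values.
#
# In a saturated two-level orthogonal array every column carries one
# degree of freedom with SS = (n_runs/4) * effect^2, and the column sums
# of squares decompose the total SS about the grand mean exactly. Columns
# left unassigned (plus optionally the weakest factors) estimate
# experimental error; each factor is then tested as F = MS_factor /
# MS_error and reported as a confidence 100*(1 - p).

#' ANOVA screening of factor effects on the S/N
#'
#' @param design A `taguchi_oa` object.
#' @param sn Numeric vector of run S/N values (length `n_runs`).
#' @param assignment Factor assignment (data frame `factor_id`, `column`).
#'   At least one design column must be left unassigned, or pooling must
#'   free error degrees of freedom, for an F-test to exist.
#' @param pool `"below_error"` (default) pools into error any assigned
#'   factor whose range falls below the largest unassigned-column range --
#'   the spare column acts as the yardstick for noise; `"none"` pools only
#'   unassigned columns.
#' @param min_error_df After the pooling rule, keep pooling the
#'   smallest-range factors until the error term has at least this many
#'   degrees of freedom (default 2).
#' @param threshold Confidence threshold (%) echoed in the table attribute.
#' @return A tibble of class `sn_anova` with one row per column plus
#'   `(error)` and `(total)` rows; columns `term`, `column`, `ss`, `df`,
#'   `ms`, `f_ratio`, `confidence`, `pooled`.
#' @export
sn_anova <- function(design, sn, assignment = NULL,
                     pool = c("below_error", "none"),
                     min_error_df = 2, threshold = 95) {
  pool <- match.arg(pool)
  stopifnot(inherits(design, "taguchi_oa"))
  if (!is.numeric(sn) || length(sn) != design$n_runs) {
    abort_input(sprintf("`sn` must be a numeric vector of length %d.",
                        design$n_runs))
  }
  rt <- sn_response_table(design, sn, assignment)
  ss <- (design$n_runs / 4) * rt$effect^2
  assigned_cols <- if (is.null(assignment)) seq_len(design$n_columns)
                   else tibble::as_tibble(assignment)$column
  unassigned <- setdiff(seq_len(design$n_columns), assigned_cols)

  pooled <- rep(FALSE, design$n_columns)
  pooled[unassigned] <- TRUE
  if (pool == "below_error" && length(unassigned) > 0) {
    thr <- max(rt$range[unassigned])
    pooled[rt$range < thr] <- TRUE
  }
  # top up the error pool with the weakest remaining factors
  while (sum(pooled) < min_error_df && sum(pooled) < design$n_columns) {
    cand <- which(!pooled)
    pooled[cand[which.min(rt$range[cand])]] <- TRUE
  }
  # on pure-noise data the spare column can top the ranges and the rule
  # would pool everything; keep the strongest assigned factor testable
  if (all(pooled)) {
    keep <- assigned_cols[which.max(rt$range[assigned_cols])]
    pooled[keep] <- FALSE
  }
  if (sum(pooled) == 0) {
    abort(paste("no error degrees of freedom: leave a column unassigned",
                "or pool weak factors (see `min_error_df`)."),
          class = "lfaquant_error_pooling")
  }

  error_ss <- sum(ss[pooled])
  error_df <- sum(pooled)
  ms_error <- error_ss / error_df
  f <- ifelse(pooled, NA_real_,
              if (ms_error == 0) Inf else ss / ms_error)
  conf <- ifelse(is.na(f), NA_real_,
                 ifelse(is.infinite(f), 100, 100 * pf(f, 1, error_df)))

  rows <- tibble::tibble(term = rt$term, column = rt$column, ss = ss,
                         df = 1L, ms = ss, f_ratio = f, confidence = conf,
                         pooled = pooled)
  extra <- tibble::tibble(
    term = c("(error)", "(total)"), column = NA_integer_,
    ss = c(error_ss, sum(ss)), df = c(error_df, design$n_columns),
    ms = c(ms_error, NA_real_), f_ratio = NA_real_, confidence = NA_real_,
    pooled = NA)
  out <- dplyr::bind_rows(rows, extra)
  structure(out, class = c("sn_anova", class(out)),
            error_df = error_df, error_ss = error_ss,
            threshold = threshold, design_name = design$name)
}

#' Factors passing the confidence screen
#'
#' @param anova An `sn_anova` table.
#' @param threshold Confidence threshold in percent (default 95): a factor
#'   is retained when its confidence is strictly greater.
#' @return Character vector of factor terms, ordered by descending F.
#' @export
significant_factors <- function(anova, threshold = 95) {
  stopifnot(inherits(anova, "sn_anova"))
  tested <- anova[!is.na(anova$confidence) & !anova$pooled %in% TRUE, ]
  hits <- tested[tested$confidence > threshold, ]
  hits$term[order(-hits$f_ratio)]
}

#' @export
print.sn_anova <- function(x, ...) {
  cat(sprintf("# S/N ANOVA (%s design), error df = %d\n",
              attr(x, "design_name") %||% "?", attr(x, "error_df")))
  NextMethod()
}
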