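# Readers and report writers. Reports carry a one-line provenance header
# (tool version, seed, config hash) as a `#` comment; all readers skip
# such comments, so written reports round-trip exactly.

.provenance <- function(seed = NULL, config = NULL) {
  sprintf("# lfaquant %s | seed=%s | config=%s",
          as.character(packageVersion("lfaquant")),
          if (is.null(seed)) "NA" else format(seed),
          if (is.null(config)) "NA" else rlang::hash(config))
}

.write_report_csv <- function(x, path, seed = NULL, config = NULL) {
  writeLines(.provenance(seed, config), path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

.read_report_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Read a screening run-data CSV
#'
#' Expected columns: `run` (or `run_index`), the array column levels
#' `col1..coln` (values 1/2), and the signal pairs `M_1..M_k`,
#' `y_1..y_k` (the `M_*` columns may be omitted when the standard
#' reference grayscales apply). Lines starting with `#` are skipped.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_run_csv <- function(path) {
  d <- .read_report_csv(path)
  if (!any(c("run", "run_index") %in% names(d))) {
    abort("run CSV must have a `run` or `run_index` column.",
          class = "lfaquant_error_schema")
  }
  if (!any(grepl("^y_\\d+$", names(d))) && !"sn_db" %in% names(d)) {
    abort("run CSV must have `y_*` signal columns or an `sn_db` column.",
          class = "lfaquant_error_schema")
  }
  d
}

#' Read a factor definition file (YAML or JSON)
#'
#' The file is a list of factor records with fields `id`, `name`,
#' `level1`, `level2` (optional `column`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A factor table (see [factor_table()]).
#' @export
read_factor_file <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("factor file not found: %s", path),
          class = "lfaquant_error_io")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = FALSE),
    abort(sprintf("unsupported factor-file format '.%s'.", ext),
          class = "lfaquant_error_io"))
  if (!is.list(raw) || length(raw) == 0) {
    abort("factor file must contain a non-empty list of factor records.",
          class = "lfaquant_error_schema")
  }
  need <- c("id", "name", "level1", "level2")
  recs <- purrr::imap(raw, function(rec, i) {
    missing <- setdiff(need, names(rec))
    if (length(missing) > 0) {
      abort(sprintf("factor record %s is missing field(s): %s",
                    i, paste(missing, collapse = ", ")),
            class = "lfaquant_error_schema")
    }
    rec
  })
  factor_table(
    factor_id = purrr::map_chr(recs, ~ as.character(.x$id)),
    name = purrr::map_chr(recs, ~ as.character(.x$name)),
    level1 = purrr::map_chr(recs, ~ as.character(.x$level1)),
    level2 = purrr::map_chr(recs, ~ as.character(.x$level2)),
    column = purrr::map_int(
      recs, function(r, i) as.integer(r$column %||% NA_integer_)) |>
      (\(col) if (all(is.na(col))) seq_along(col) else col)())
}

#' Write / read a response-table report
#'
#' The grand mean travels as an extra column so the round trip is exact.
#'
#' @param table An `sn_response_table`.
#' @param path CSV path.
#' @param seed,config Provenance fields for the report header.
#' @return The path, invisibly (`write_response_table`); the rebuilt
#'   `sn_response_table` (`read_response_table`).
#' @export
write_response_table <- function(table, path, seed = NULL, config = NULL) {
  stopifnot(inherits(table, "sn_response_table"))
  out <- tibble::as_tibble(table)
  out$grand_mean <- attr(table, "grand_mean")
  .write_report_csv(out, path, seed, config)
}

#' @rdname write_response_table
#' @export
read_response_table <- function(path) {
  d <- .read_report_csv(path)
  gm <- d$grand_mean[1]
  d$grand_mean <- NULL
  structure(d, class = c("sn_response_table", class(d)),
            grand_mean = gm, design_name = "file")
}

#' Write an ANOVA report
#'
#' @param anova An `sn_anova` table.
#' @param path CSV path.
#' @param seed,config Provenance fields.
#' @return The path, invisibly.
#' @export
write_anova <- function(anova, path, seed = NULL, config = NULL) {
  stopifnot(inherits(anova, "sn_anova"))
  .write_report_csv(tibble::as_tibble(anova), path, seed, config)
}

#' Write a chosen-levels report as JSON
#'
#' @param selection An `optimal_selection`.
#' @param path JSON path.
#' @param seed Provenance seed.
#' @return The path, invisibly.
#' @export
write_levels_json <- function(selection, path, seed = NULL) {
  stopifnot(inherits(selection, "optimal_selection"))
  payload <- list(
    tool = paste("lfaquant", as.character(packageVersion("lfaquant"))),
    seed = seed,
    grand_mean = selection$grand_mean,
    predicted_sn = selection$predicted_sn,
    significant = as.list(selection$significant),
    levels = selection$levels)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Persist / load a calibration model as JSON
#'
#' The JSON stores the fitted coefficients and metadata (not the raw
#' `lm` object); a loaded model predicts and inverts identically.
#'
#' @param model A `calibration_model`.
#' @param path JSON path.
#' @return The path, invisibly (`write_model_json`); a
#'   `calibration_model` (`read_model_json`).
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  payload <- list(
    tool = paste("lfaquant", as.character(packageVersion("lfaquant"))),
    slope = model$slope, intercept = model$intercept,
    r_squared = model$r_squared, residual_sd = model$residual_sd,
    range = model$range, polarity = model$polarity,
    log_concentration = model$log_concentration, accepted = model$accepted,
    n = model$n)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("model file not found: %s", path),
          class = "lfaquant_error_io")
  }
  p <- jsonlite::fromJSON(path)
  structure(
    list(slope = p$slope, intercept = p$intercept, r_squared = p$r_squared,
         residual_sd = p$residual_sd, range = as.numeric(p$range),
         polarity = p$polarity, log_concentration = isTRUE(p$log_concentration),
         accepted = isTRUE(p$accepted), n = p$n, data = NULL, fit = NULL),
    class = "calibration_model")
}
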