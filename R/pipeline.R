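# Pipeline commands tying the modules into the optimize -> calibrate ->
# quantify workflow, plus the strict configuration loader. Each command is
# an ordinary function (testable, pipeable); inst/cli/lfaquant.R wraps
# them for the shell.

.config_keys <- c("factors", "array", "polarity", "lane", "orientation",
                  "min_depth", "calibration_levels", "seed", "out_dir")

#' Load a pipeline configuration file
#'
#' YAML (or JSON) with keys among: `factors` (factor-file path), `array`,
#' `polarity`, `lane`, `orientation`, `min_depth`, `calibration_levels`,
#' `seed`, `out_dir`. Unknown keys are rejected; referenced paths must
#' exist.
#'
#' @param path Config file path.
#' @return A list of class `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config not found: %s", path), class = "lfaquant_error_io")
  }
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") jsonlite::fromJSON(path) else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "lfaquant_error_schema")
  }
  if (!is.null(cfg$factors) && !file.exists(cfg$factors)) {
    abort(sprintf("config key `factors` points to a missing file: %s",
                  cfg$factors), class = "lfaquant_error_io")
  }
  defaults <- list(polarity = "net", orientation = "control_last",
                   min_depth = 5,
                   calibration_levels = c(6.25, 12.5, 25, 37.5, 50),
                   seed = 1, out_dir = ".")
  structure(modifyList(defaults, cfg), class = "pipeline_config")
}

.as_strip_config <- function(cfg) {
  strip_config(lane = cfg$lane, orientation = cfg$orientation,
               min_depth = cfg$min_depth, polarity = cfg$polarity)
}

#' Write the run sheet for a screening design
#'
#' Picks the smallest catalogued array for the factor table and writes one
#' row per run with each factor's concrete level value.
#'
#' @param factors A factor table (see [factor_table()]) or the path of a
#'   factor file.
#' @param out Output CSV path.
#' @param seed Provenance seed for the report header.
#' @return The run sheet tibble, invisibly.
#' @export
cmd_design <- function(factors, out, seed = NULL) {
  if (is.character(factors)) factors <- read_factor_file(factors)
  design <- oa_array(nrow(factors))
  message(sprintf("design: %s (%d runs) for %d factors",
                  design$name, design$n_runs, nrow(factors)))
  sheet <- tibble::tibble(run = seq_len(design$n_runs))
  for (i in seq_len(nrow(factors))) {
    lev <- design$cells[, factors$column[i]]
    sheet[[factors$factor_id[i]]] <-
      ifelse(lev == 1L, factors$level1[i], factors$level2[i])
  }
  .write_report_csv(sheet, out, seed = seed, config = factors)
  invisible(sheet)
}

.infer_design <- function(n_runs) {
  name <- c(`4` = "L4", `8` = "L8", `12` = "L12")[as.character(n_runs)]
  if (is.na(name)) {
    abort(sprintf("run count %d matches no catalogued array (4, 8 or 12 runs).",
                  n_runs), class = "lfaquant_error_schema")
  }
  design <- oa_array(c(L4 = 3, L8 = 7, L12 = 11)[[name]])
  stopifnot(design$name == name)
  design
}

#' Analyze a screening experiment from a run CSV
#'
#' Reads run data (see [read_run_csv()]), computes per-run dynamic S/N
#' (or uses a precomputed `sn_db` column), and writes three reports to
#' `out_dir`: `response_table.csv`, `anova.csv` and
#' `optimal_levels.json`.
#'
#' @param run_csv Run-data CSV path.
#' @param out_dir Output directory (created if needed).
#' @param assignment Factor assignment; `NULL` assigns letters `A`, `B`,
#'   ... to all columns but the last, which is kept as the error column.
#' @param threshold ANOVA confidence threshold, percent.
#' @param normalize Passed to [run_responses()].
#' @param seed Provenance seed.
#' @return A list with `responses`, `response_table`, `anova`,
#'   `selection`, invisibly.
#' @export
cmd_analyze <- function(run_csv, out_dir = ".", assignment = NULL,
                        threshold = 95, normalize = TRUE, seed = NULL) {
  d <- read_run_csv(run_csv)
  design <- .infer_design(nrow(d))
  if (is.null(assignment)) {
    nf <- design$n_columns - 1L
    assignment <- tibble::tibble(factor_id = LETTERS[seq_len(nf)],
                                 column = seq_len(nf))
  }
  if ("sn_db" %in% names(d)) {
    responses <- tibble::tibble(run = d[[intersect(c("run", "run_index"),
                                                   names(d))[1]]],
                                sn_db = d$sn_db)
  } else {
    responses <- run_responses(d, normalize = normalize)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rt <- sn_response_table(design, responses$sn_db, assignment)
  at <- sn_anova(design, responses$sn_db, assignment, threshold = threshold)
  sig <- significant_factors(at, threshold)
  sel <- select_optimal(rt, sig)
  write_response_table(rt, file.path(out_dir, "response_table.csv"), seed)
  write_anova(at, file.path(out_dir, "anova.csv"), seed)
  write_levels_json(sel, file.path(out_dir, "optimal_levels.json"), seed)
  message(sprintf("analyze: %s | grand mean %.3f dB | significant: %s",
                  design$name, attr(rt, "grand_mean"),
                  if (length(sig)) paste(sig, collapse = ", ") else "(none)"))
  invisible(list(responses = responses, response_table = rt, anova = at,
                 selection = sel))
}

#' Fit and persist a calibration model
#'
#' @param points_csv CSV with `concentration`, `signal` (optional
#'   `replicate_id`).
#' @param out_model Output JSON path for the model.
#' @param polarity Signal convention recorded in the model.
#' @return The fitted `calibration_model`, invisibly.
#' @export
cmd_calibrate <- function(points_csv, out_model, polarity = c("net", "raw")) {
  pts <- .read_report_csv(points_csv)
  model <- fit_calibration(pts, polarity = match.arg(polarity))
  write_model_json(model, out_model)
  message(sprintf("calibrate: R^2 = %.4f, slope = %.4g over %g-%g mIU/mL",
                  model$r_squared, model$slope, model$range[1], model$range[2]))
  invisible(model)
}

#' Quantify unknowns from images or a signal CSV
#'
#' Runs densitometry when `input` is one or more image paths (PNG/TIFF),
#' or reads a CSV with a `signal` column, then inverts the calibration
#' curve. Invalid strips (no control line) get no concentration;
#' out-of-range estimates are flagged as extrapolations.
#'
#' @param input Image path(s) or a signal CSV path.
#' @param model A `calibration_model` or a model JSON path.
#' @param out Output CSV path.
#' @param config A [strip_config()] for densitometry.
#' @param seed Provenance seed.
#' @return The report tibble, invisibly.
#' @export
cmd_quantify <- function(input, model, out, config = strip_config(),
                         seed = NULL) {
  if (is.character(model)) model <- read_model_json(model)
  is_image <- grepl("\\.(png|tif|tiff)$", tolower(input))
  if (all(is_image)) {
    meas <- measure_strips(input, config)
    signals <- meas$measured_grayscale
    ids <- meas$image
    valid <- meas$valid
  } else {
    d <- .read_report_csv(input[1])
    if (!"signal" %in% names(d)) {
      abort("signal CSV must have a `signal` column.",
            class = "lfaquant_error_schema")
    }
    signals <- d$signal
    ids <- if ("image" %in% names(d)) d$image else sprintf("row_%d", seq_along(signals))
    valid <- if ("valid" %in% names(d)) d$valid else rep(TRUE, length(signals))
  }
  quant <- invert_calibration(model, ifelse(valid, signals, NA_real_))
  report <- tibble::tibble(image = ids, valid = valid, signal = signals,
                           estimate = ifelse(valid, quant$estimate, NA_real_),
                           in_range = ifelse(valid, quant$in_range, FALSE))
  .write_report_csv(report, out, seed = seed)
  message(sprintf("quantify: %d strip(s), %d valid, %d in range",
                  nrow(report), sum(report$valid), sum(report$in_range)))
  invisible(report)
}

#' Render a synthetic strip gallery
#'
#' @param out_dir Gallery directory.
#' @param seed Seed of the first strip.
#' @param ... Passed to [write_strip_gallery()].
#' @return The manifest tibble, invisibly.
#' @export
cmd_simulate <- function(out_dir, seed = 1, ...) {
  manifest <- write_strip_gallery(out_dir, seed = seed, ...)
  message(sprintf("simulate: wrote %d strip(s) to %s", nrow(manifest), out_dir))
  invisible(manifest)
}

#' Batch densitometry to CSV
#'
#' @param images Image paths.
#' @param out Output CSV path.
#' @param config A [strip_config()].
#' @param seed Provenance seed.
#' @return The measurement tibble, invisibly.
#' @export
cmd_densitometry <- function(images, out, config = strip_config(), seed = NULL) {
  meas <- measure_strips(images, config)
  .write_report_csv(meas, out, seed = seed, config = config)
  invisible(meas)
}
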