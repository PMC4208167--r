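# Strip densitometry: from a strip image to background-corrected control-
# and test-line grayscale signals.
#
# The membrane is light; antibody-captured gold-nanoparticle bands are
# dark. We average grayscale across the lane width to get a longitudinal
# profile, call bands as dips below the background (median of non-band
# rows), and report each band's mean grayscale together with the
# background-corrected net signal (background - band mean), which
# increases with analyte concentration.

#' Read a strip image from PNG or TIFF
#'
#' @param path Path to an 8-bit PNG or TIFF image.
#' @return An integer array on the 0--255 scale: `H x W` (gray) or
#'   `H x W x 3` (RGB; an alpha channel, if present, is dropped).
#' @export
read_strip <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("image not found: %s", path), class = "lfaquant_error_io")
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("unsupported image format '.%s' (PNG or TIFF expected).", ext),
          class = "lfaquant_error_io"))
  if (length(dim(img)) == 3 && dim(img)[3] >= 3) img <- img[, , 1:3, drop = FALSE]
  if (length(dim(img)) == 3 && dim(img)[3] == 1) img <- img[, , 1]
  out <- round_half_up(img * 255)
  storage.mode(out) <- "integer"
  out
}

#' Convert an image to 8-bit grayscale
#'
#' RGB images are converted with the BT.601 luma weights
#' `0.299 R + 0.587 G + 0.114 B`, rounded half-up to integers; grayscale
#' input passes through unchanged.
#'
#' @param image `H x W` or `H x W x 3` array on the 0--255 scale.
#' @return Integer `H x W` grayscale matrix.
#' @examples
#' to_grayscale(array(c(255, 0, 0), dim = c(1, 1, 3))) # pure red -> 76
#' @export
to_grayscale <- function(image) {
  if (length(image) == 0) abort_input("empty image.")
  d <- dim(image)
  if (is.null(d) || length(d) < 2) abort_input("`image` must be a matrix or array.")
  if (length(d) == 2) {
    out <- round_half_up(image)
  } else if (length(d) == 3 && d[3] == 3) {
    out <- round_half_up(0.299 * image[, , 1] + 0.587 * image[, , 2] +
                           0.114 * image[, , 3])
    dim(out) <- d[1:2]
  } else {
    abort_input("`image` must be H x W (gray) or H x W x 3 (RGB).")
  }
  storage.mode(out) <- "integer"
  out
}

#' Longitudinal grayscale profile of a lane
#'
#' Averages grayscale across the lane width for every row along the flow
#' axis.
#'
#' @param image Strip image (gray or RGB, 0--255).
#' @param lane Optional list with `rows = c(first, last)` and/or
#'   `cols = c(first, last)` restricting the lane; `NULL` uses the whole
#'   image.
#' @return A tibble `row`, `gray` (one row per lane row), with attribute
#'   `axis_origin` = first lane row.
#' @export
longitudinal_profile <- function(image, lane = NULL) {
  g <- to_grayscale(image)
  rows <- c(1L, nrow(g))
  cols <- c(1L, ncol(g))
  if (!is.null(lane)) {
    if (!is.null(lane$rows)) rows <- as.integer(lane$rows)
    if (!is.null(lane$cols)) cols <- as.integer(lane$cols)
  }
  if (rows[1] < 1 || rows[2] > nrow(g) || cols[1] < 1 || cols[2] > ncol(g) ||
      rows[1] > rows[2] || cols[1] > cols[2]) {
    abort_input("lane lies outside the image bounds.")
  }
  sub <- g[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  out <- tibble::tibble(row = rows[1]:rows[2], gray = rowMeans(sub))
  attr(out, "axis_origin") <- rows[1]
  out
}

#' Call bands in a longitudinal profile
#'
#' Bands are maximal runs of rows whose grayscale drops at least
#' `min_depth` below the background. The background is the median of
#' non-band rows, estimated in two passes: first the median of the whole
#' profile, then the median after excluding the provisionally called band
#' rows. Up to `expected` bands are kept (the deepest ones), ordered along
#' the flow axis. Zero bands is a legal outcome (an invalid strip).
#'
#' @param profile A profile tibble from [longitudinal_profile()] (at
#'   least 5 rows).
#' @param expected Maximum number of bands to return (default 2:
#'   test + control).
#' @param min_depth Minimum dip below background, grayscale units.
#' @return A tibble with one row per band: `center` (midpoint of the extent), `start`,
#'   `end`, `mean_gray`, `background`, `net_signal`
#'   (`background - mean_gray`), `depth` (`background - min gray`).
#' @export
detect_bands <- function(profile, expected = 2, min_depth = 5) {
  p <- profile$gray
  if (length(p) < 5) abort_input("profile must have at least 5 rows.")
  bg <- median(p)
  in_band <- (bg - p) >= min_depth
  if (any(!in_band)) {
    bg <- median(p[!in_band])
    in_band <- (bg - p) >= min_depth
  }
  empty <- tibble::tibble(center = integer(), start = integer(),
                          end = integer(), mean_gray = numeric(),
                          background = numeric(), net_signal = numeric(),
                          depth = numeric())
  if (!any(in_band)) return(empty)
  r <- rle(in_band)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  bands <- purrr::map_dfr(runs, function(k) {
    idx <- starts[k]:ends[k]
    lo <- idx[which.min(p[idx])]
    mid <- round_half_up((profile$row[idx[1]] + profile$row[idx[length(idx)]]) / 2)
    tibble::tibble(center = as.integer(mid), start = profile$row[idx[1]],
                   end = profile$row[idx[length(idx)]],
                   mean_gray = mean(p[idx]), background = bg,
                   net_signal = bg - mean(p[idx]), depth = bg - p[lo])
  })
  bands <- bands[order(-bands$depth), ][seq_len(min(nrow(bands), expected)), ]
  bands[order(bands$center), ]
}

#' Densitometry configuration
#'
#' @param lane Lane region (see [longitudinal_profile()]); `NULL` = whole
#'   image.
#' @param orientation `"control_last"` (default; the control line sits at
#'   the higher row index, toward the absorbent pad) or `"control_first"`.
#' @param min_depth Band-call threshold, grayscale units (default 5,
#'   chosen so a test line at the 6.25 mIU/mL detection limit — a dip of
#'   about 10 grayscale units — is called with a 2x margin).
#' @param polarity `"net"` (default) reports the background-corrected test
#'   signal, which increases with analyte concentration; `"raw"` reports
#'   the raw test-band mean grayscale, which decreases.
#' @return A list of class `strip_config`.
#' @export
strip_config <- function(lane = NULL,
                         orientation = c("control_last", "control_first"),
                         min_depth = 5, polarity = c("net", "raw")) {
  structure(list(lane = lane, orientation = match.arg(orientation),
                 min_depth = min_depth, polarity = match.arg(polarity)),
            class = "strip_config")
}

#' Extract control- and test-line signals from a strip image
#'
#' Composes grayscale conversion, lane profiling and band calling, then
#' assigns roles by position: the band nearer the absorbent-pad end is the
#' control line, the band nearer the sample pad the test line. A strip is
#' `valid` only if a control band is called; with a single called band,
#' the band is taken as the control when it lies in the control half of
#' the lane. `measured_grayscale` is the calibration signal for the test
#' line under the configured polarity (0 net signal when the strip is
#' valid but no test band is visible, as for a blank sample).
#'
#' @param image A strip image array, or a path readable by [read_strip()].
#' @param config A [strip_config()].
#' @return A one-row tibble: `valid`, `n_bands`, `background`,
#'   `control_center`, `control_mean`, `control_net`, `test_center`,
#'   `test_mean`, `test_net`, `measured_grayscale`.
#' @export
extract_line_signal <- function(image, config = strip_config()) {
  if (is.character(image)) image <- read_strip(image)
  stopifnot(inherits(config, "strip_config"))
  profile <- longitudinal_profile(image, config$lane)
  bands <- detect_bands(profile, expected = 2, min_depth = config$min_depth)
  mid <- mean(range(profile$row))
  last_is_control <- config$orientation == "control_last"

  control <- test <- NULL
  if (nrow(bands) == 2) {
    ctrl_idx <- if (last_is_control) which.max(bands$center) else which.min(bands$center)
    control <- bands[ctrl_idx, ]
    test <- bands[-ctrl_idx, ]
  } else if (nrow(bands) == 1) {
    in_control_half <- if (last_is_control) bands$center[1] > mid
                       else bands$center[1] < mid
    if (in_control_half) control <- bands else test <- bands
  }
  valid <- !is.null(control)
  measured <- NA_real_
  if (valid) {
    if (!is.null(test)) {
      measured <- if (config$polarity == "net") test$net_signal else test$mean_gray
    } else if (config$polarity == "net") {
      measured <- 0
    }
  }
  tibble::tibble(
    valid = valid, n_bands = nrow(bands),
    background = if (nrow(bands) > 0) bands$background[1] else median(profile$gray),
    control_center = if (valid) control$center else NA_integer_,
    control_mean = if (valid) control$mean_gray else NA_real_,
    control_net = if (valid) control$net_signal else NA_real_,
    test_center = if (!is.null(test)) test$center else NA_integer_,
    test_mean = if (!is.null(test)) test$mean_gray else NA_real_,
    test_net = if (!is.null(test)) test$net_signal else NA_real_,
    measured_grayscale = measured)
}

#' Densitometry over a batch of strip images
#'
#' @param images Character vector of image paths, or a list of image
#'   arrays.
#' @param config A [strip_config()].
#' @return A tibble with one row per image (an `image` id column followed
#'   by the [extract_line_signal()] columns).
#' @export
measure_strips <- function(images, config = strip_config()) {
  ids <- if (is.character(images)) images else
    sprintf("image_%d", seq_along(images))
  purrr::map2_dfr(images, ids, function(img, id) {
    dplyr::bind_cols(tibble::tibble(image = id),
                     extract_line_signal(img, config))
  })
}

#' Plot a lane profile with called bands
#'
#' @param profile A tibble from [longitudinal_profile()].
#' @param bands Optional band table from [detect_bands()].
#' @return A ggplot of grayscale against the flow axis.
#' @export
plot_profile <- function(profile, bands = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$row, y = .data$gray)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "row (flow axis)", y = "mean grayscale",
                  title = "Longitudinal lane profile") +
    ggplot2::theme_minimal()
  if (!is.null(bands) && nrow(bands) > 0) {
    p <- p +
      ggplot2::geom_rect(data = bands,
                         ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                      ymin = -Inf, ymax = Inf),
                         inherit.aes = FALSE, alpha = 0.15, fill = "red") +
      ggplot2::geom_vline(xintercept = bands$center, linetype = "dotted")
  }
  p
}
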