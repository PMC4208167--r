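# Seed-controlled synthetic strips and simulated screening experiments.
#
# The generator emulates the measurement situation of an hCG strip reader:
# a light nitrocellulose membrane, a fixed control line, and a test line
# whose darkening is linear in analyte concentration over 0--50 mIU/mL
# (sandwich immunoassay: more analyte, more gold aggregated, darker line;
# beyond 50 the response is clamped, a crude hook-saturation stand-in).
# Bands are reddish, as colloidal-gold lines are: the red channel drops
# least, and the channel drops are weighted so the *luma* drop equals the
# nominal band depth exactly.

# Channel weights of the band colour; luma(0.299,0.587,0.114) . u == 1.
.band_chroma <- c(0.5, 1.2, (1 - 0.299 * 0.5 - 0.587 * 1.2) / 0.114)

#' Camera acquisition parameters
#'
#' One field per screened acquisition parameter. Defaults are neutral:
#' the camera pipeline is then an identity (up to 8-bit quantization).
#'
#' @param backlight_compensation Logical; `TRUE` compresses highlights
#'   above grayscale 240 (knee with slope 0.5).
#' @param brightness Additive offset, grayscale units.
#' @param contrast Gain about mid-gray 127.5 (1 = neutral).
#' @param exposure Multiplicative scale (1 = neutral).
#' @param gain Amplification applied after exposure; amplifies pixel noise
#'   along with the signal (1 = neutral).
#' @param gamma Power-law exponent on the 0--1 scale (> 0; 1 = neutral).
#' @param hue Hue rotation in radians (0 = neutral; RGB images only).
#' @param saturation Chroma scale in percent about the luma (100 =
#'   neutral; >= 0).
#' @param sharpness Unsharp-mask strength (0 = neutral); the mask is a
#'   3x3 box blur and the sharpened image is `v + 0.1 * sharpness *
#'   (v - blur(v))`.
#' @param white_balance `"Auto"` (neutral) or a colour temperature in
#'   Kelvin; lower temperatures warm the image (red gain up, blue down).
#' @return A list of class `camera_params`.
#' @export
camera_params <- function(backlight_compensation = FALSE, brightness = 0,
                          contrast = 1, exposure = 1, gain = 1, gamma = 1,
                          hue = 0, saturation = 100,
                          sharpness = 0, white_balance = "Auto") {
  if (gamma <= 0) abort_input("`gamma` must be > 0.")
  if (saturation < 0) abort_input("`saturation` must be >= 0.")
  structure(list(backlight_compensation = isTRUE(backlight_compensation),
                 brightness = brightness, contrast = contrast,
                 exposure = exposure, gain = gain, gamma = gamma, hue = hue,
                 saturation = saturation, sharpness = sharpness,
                 white_balance = white_balance),
            class = "camera_params")
}

.box_blur3 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  pad <- m[c(1, seq_len(n), n), c(1, seq_len(k), k)]
  acc <- matrix(0, n, k)
  for (dr in 0:2) for (dc in 0:2) {
    acc <- acc + pad[dr + seq_len(n), dc + seq_len(k)]
  }
  acc / 9
}

# Apply the camera transforms in the fixed documented order:
# exposure -> gain -> brightness -> contrast -> gamma -> white balance ->
# hue/saturation -> sharpness -> backlight compensation; then clip to
# [0, 255]. `img` is an H x W x 3 float array on the 0--255 scale.
apply_camera <- function(img, params) {
  stopifnot(inherits(params, "camera_params"))
  v <- img * params$exposure * params$gain + params$brightness
  v <- 127.5 + params$contrast * (v - 127.5)
  v <- 255 * (pmax(v, 0) / 255)^params$gamma
  if (!identical(params$white_balance, "Auto")) {
    temp <- as.numeric(params$white_balance)
    v[, , 1] <- v[, , 1] * (6500 / temp)^0.2
    v[, , 3] <- v[, , 3] * (temp / 6500)^0.2
  }
  if (params$hue != 0 || params$saturation != 100) {
    y <- 0.299 * v[, , 1] + 0.587 * v[, , 2] + 0.114 * v[, , 3]
    iq1 <- 0.596 * v[, , 1] - 0.274 * v[, , 2] - 0.322 * v[, , 3]
    iq2 <- 0.211 * v[, , 1] - 0.523 * v[, , 2] + 0.312 * v[, , 3]
    th <- params$hue
    i2 <- iq1 * cos(th) - iq2 * sin(th)
    q2 <- iq1 * sin(th) + iq2 * cos(th)
    s <- params$saturation / 100
    i2 <- i2 * s; q2 <- q2 * s
    v[, , 1] <- y + 0.956 * i2 + 0.621 * q2
    v[, , 2] <- y - 0.272 * i2 - 0.647 * q2
    v[, , 3] <- y - 1.106 * i2 + 1.703 * q2
  }
  if (params$sharpness != 0) {
    for (ch in 1:3) {
      v[, , ch] <- v[, , ch] +
        0.1 * params$sharpness * (v[, , ch] - .box_blur3(v[, , ch]))
    }
  }
  if (params$backlight_compensation) {
    v <- ifelse(v > 240, 240 + (v - 240) * 0.5, v)
  }
  pmin(pmax(v, 0), 255)
}

#' Synthetic strip specification
#'
#' @param concentration Analyte concentration, mIU/mL (>= 0).
#' @param control_depth Luma drop of the control line, grayscale units.
#' @param test_depth_at_50 Luma drop of the test line at 50 mIU/mL; the
#'   drop scales linearly as `test_depth_at_50 * min(concentration/50, 1)`
#'   and is zero at concentration 0.
#' @param band_centers Named row indices `c(test = ..., control = ...)`.
#' @param band_width Band height in rows.
#' @param membrane_gray Membrane background luma, grayscale units.
#' @param noise_sd Gaussian pixel-noise standard deviation, grayscale
#'   units (default 1).
#' @param depth_cv Relative strip-to-strip variability of the realized
#'   band depths (default 0.04), emulating inter-strip line-intensity
#'   variation of a real lateral-flow lot.
#' @param height,width Image dimensions in pixels.
#' @return A list of class `strip_spec`.
#' @export
strip_spec <- function(concentration = 25, control_depth = 60,
                       test_depth_at_50 = 80,
                       band_centers = c(test = 40, control = 85),
                       band_width = 8, membrane_gray = 200, noise_sd = 1,
                       depth_cv = 0.04, height = 120, width = 60) {
  if (concentration < 0) abort_input("`concentration` must be >= 0.")
  if (band_width < 1 || height < 2 * band_width) {
    abort_input("image height must be at least twice the band width.")
  }
  if (!all(c("test", "control") %in% names(band_centers))) {
    abort_input("`band_centers` needs named entries `test` and `control`.")
  }
  structure(list(concentration = concentration, control_depth = control_depth,
                 test_depth_at_50 = test_depth_at_50,
                 band_centers = band_centers, band_width = band_width,
                 membrane_gray = membrane_gray, noise_sd = noise_sd,
                 depth_cv = depth_cv, height = height, width = width),
            class = "strip_spec")
}

.band_rows <- function(center, width, height) {
  start <- max(1L, as.integer(center) - floor(width / 2))
  end <- min(height, start + as.integer(width) - 1L)
  start:end
}

#' Render a synthetic strip image
#'
#' Draws the membrane background with Gaussian pixel noise, darkens the
#' control band and (for nonzero concentration) the test band, then runs
#' the camera transform pipeline and quantizes to 8-bit RGB. Bit-identical
#' for a fixed (spec, params, seed).
#'
#' @param spec A [strip_spec()].
#' @param params A [camera_params()].
#' @param seed Integer seed (all randomness of the render).
#' @return An integer `H x W x 3` image on 0--255, with attribute `truth`
#'   (realized band rows and depths) for recovery tests.
#' @export
render_strip <- function(spec, params = camera_params(), seed = NULL) {
  stopifnot(inherits(spec, "strip_spec"))
  with_seed(seed, {
    h <- spec$height; w <- spec$width
    test_depth <- spec$test_depth_at_50 * min(spec$concentration / 50, 1)
    jitter_c <- if (spec$depth_cv > 0) rnorm(1, 0, spec$depth_cv) else 0
    jitter_t <- if (spec$depth_cv > 0) rnorm(1, 0, spec$depth_cv) else 0
    depth_c <- spec$control_depth * (1 + jitter_c)
    depth_t <- test_depth * (1 + jitter_t)
    luma <- matrix(spec$membrane_gray, h, w)
    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) img[, , ch] <- luma
    rows_c <- .band_rows(spec$band_centers[["control"]], spec$band_width, h)
    rows_t <- .band_rows(spec$band_centers[["test"]], spec$band_width, h)
    for (ch in 1:3) {
      img[rows_c, , ch] <- img[rows_c, , ch] - depth_c * .band_chroma[ch]
      if (depth_t > 0) {
        img[rows_t, , ch] <- img[rows_t, , ch] - depth_t * .band_chroma[ch]
      }
    }
    if (spec$noise_sd > 0) {
      noise <- matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
      for (ch in 1:3) img[, , ch] <- img[, , ch] + noise
    }
    out <- round_half_up(apply_camera(img, params))
    storage.mode(out) <- "integer"
    attr(out, "truth") <- list(
      control_center = spec$band_centers[["control"]],
      test_center = if (test_depth > 0) spec$band_centers[["test"]] else NA,
      control_depth = depth_c, test_depth = depth_t)
    out
  })
}

#' Standard reference grayscales for dynamic screening
#'
#' The five reference grayscale levels used as the signal factor of the
#' dynamic characteristic: near-white patches stepping by 2 grayscale
#' units from 247 up to 255, emulating the faint test line of a
#' low-concentration strip.
#'
#' @return Numeric vector `c(247, 249, 251, 253, 255)`.
#' @export
reference_targets <- function() c(247, 249, 251, 253, 255)

#' Render one uniform reference patch
#'
#' @param gray Nominal patch grayscale (0--255).
#' @param params A [camera_params()].
#' @param noise_sd Pixel noise sd, grayscale units.
#' @param size Patch dimensions `c(rows, cols)`.
#' @param seed Integer seed.
#' @return Integer `H x W x 3` image.
#' @export
render_reference_patch <- function(gray, params = camera_params(),
                                   noise_sd = 0, size = c(24, 24),
                                   seed = NULL) {
  with_seed(seed, {
    img <- array(gray, dim = c(size[1], size[2], 3))
    if (noise_sd > 0) {
      noise <- matrix(rnorm(prod(size), 0, noise_sd), size[1], size[2])
      for (ch in 1:3) img[, , ch] <- img[, , ch] + noise
    }
    out <- round_half_up(apply_camera(img, params))
    storage.mode(out) <- "integer"
    out
  })
}

#' Measure a reference patch
#'
#' Mean grayscale over the whole patch (pixel noise dithers the 8-bit
#' quantization, so the mean resolves well below one grayscale unit).
#'
#' @param image Patch image.
#' @return Mean grayscale (numeric scalar).
#' @export
measure_patch <- function(image) mean(to_grayscale(image))

#' Ground-truth effect model for simulated screenings
#'
#' Declares, per factor, the true contribution (dB) of moving from level 1
#' to level 2 to the run S/N, plus optional pairwise interaction terms and
#' the run-to-run noise. Influential factors must have |effect| >= 3 dB
#' and non-influential ones |effect| <= 0.5 dB, so the two groups are
#' separated by construction.
#'
#' @param effects Named numeric vector of per-factor effects (dB); factors
#'   omitted get effect 0.
#' @param noise_sd Run-to-run S/N noise sd, dB (default 0.5).
#' @param base_sn Baseline (grand-mean) S/N, dB.
#' @param interactions Optional tibble `factor_a`, `factor_b`,
#'   `coefficient` adding `coefficient * s_a * s_b` (s = -1/+1) to the run
#'   S/N.
#' @return A list of class `effect_model`.
#' @export
effect_model <- function(effects = numeric(), noise_sd = 0.5, base_sn = 43.3,
                         interactions = NULL) {
  bad <- abs(effects) > 0.5 & abs(effects) < 3
  if (any(bad)) {
    abort_input(paste0(
      "effects must be influential (|effect| >= 3 dB) or weak ",
      "(|effect| <= 0.5 dB); offending: ",
      paste(names(effects)[bad], collapse = ", ")))
  }
  structure(list(effects = effects, noise_sd = noise_sd, base_sn = base_sn,
                 interactions = interactions,
                 influential = names(effects)[abs(effects) >= 3]),
            class = "effect_model")
}

#' Default effect model mirroring the reference screening
#'
#' Backlight compensation (A), gamma (F) and sharpness (I) influential at
#' the effect sizes seen in the reference experiment (+3.15, -7.36 and
#' +3.87 dB); the other seven parameters inert.
#'
#' @return An [effect_model()].
#' @export
hcg_effect_model <- function() {
  effect_model(effects = c(A = 3.15, F = -7.36, I = 3.87),
               noise_sd = 0.5, base_sn = 43.3)
}

# Deterministic part of each run's S/N under an effect model.
.true_run_sn <- function(design, assignment, effects) {
  stopifnot(inherits(effects, "effect_model"))
  assignment <- tibble::as_tibble(assignment)
  eff_col <- rep(0, design$n_columns)
  known <- intersect(names(effects$effects), assignment$factor_id)
  eff_col[assignment$column[match(known, assignment$factor_id)]] <-
    effects$effects[known]
  sn <- sn_from_effects(design, effects$base_sn, eff_col)
  if (!is.null(effects$interactions)) {
    it <- tibble::as_tibble(effects$interactions)
    for (i in seq_len(nrow(it))) {
      ca <- assignment$column[assignment$factor_id == it$factor_a[i]]
      cb <- assignment$column[assignment$factor_id == it$factor_b[i]]
      sa <- ifelse(design$cells[, ca] == 2L, 1, -1)
      sb <- ifelse(design$cells[, cb] == 2L, 1, -1)
      sn <- sn + it$coefficient[i] * sa * sb
    }
  }
  sn
}

#' Simulate run S/N values for a screening design
#'
#' Draws each run's S/N directly from the additive effect model plus
#' Gaussian run-to-run noise: the fast simulation route used for
#' large-replication factor-recovery studies. (See [simulate_l12()] for
#' the full image-rendering route.)
#'
#' @param design A `taguchi_oa`.
#' @param assignment Factor assignment table.
#' @param effects An [effect_model()].
#' @param seed Integer seed.
#' @return A tibble `run`, `sn_db`, with attribute `truth` (the
#'   deterministic S/N part).
#' @export
simulate_run_sn <- function(design, assignment, effects = hcg_effect_model(),
                            seed = NULL) {
  truth <- .true_run_sn(design, assignment, effects)
  with_seed(seed, {
    sn <- truth + rnorm(design$n_runs, 0, effects$noise_sd)
    out <- tibble::tibble(run = seq_len(design$n_runs), sn_db = sn)
    attr(out, "truth") <- truth
    out
  })
}

#' Simulate a full rendered screening experiment
#'
#' For each run, draws a target S/N from the effect model (deterministic
#' part + run noise), translates it into a residual spread on the
#' normalized grayscale scale, renders the five reference patches at
#' reference value plus a residual constructed to realize exactly that
#' spread (slope held at 1), measures each patch densitometrically, and
#' fits the dynamic response. Camera transforms are held neutral so the
#' declared effect model *is* the ground truth and remains retrievable;
#' rendering still exposes the measurement chain (pixel noise, 8-bit
#' quantization, ROI averaging) to the fit.
#'
#' @param design A `taguchi_oa`.
#' @param assignment Factor assignment table.
#' @param effects An [effect_model()].
#' @param replicates Patch-set replicates per run (>= 1).
#' @param seed Integer seed.
#' @param targets Reference grayscales (default [reference_targets()]).
#' @param pixel_noise_sd Pixel noise of the patch render (default 1).
#' @return A tibble `run`, `beta`, `sd`, `sn_db` (one row per run) with
#'   attributes `truth` (deterministic run S/N) and `target_sn` (run S/N
#'   including run noise). `sd`/`sn_db` are on the normalized 0--1 scale.
#' @export
simulate_l12 <- function(design, assignment, effects = hcg_effect_model(),
                         replicates = 1, seed = NULL,
                         targets = reference_targets(), pixel_noise_sd = 1) {
  if (replicates < 1) abort_input("`replicates` must be >= 1.")
  truth <- .true_run_sn(design, assignment, effects)
  with_seed(seed, {
    target_sn <- truth + rnorm(design$n_runs, 0, effects$noise_sd)
    k <- length(targets)
    res <- purrr::map_dfr(seq_len(design$n_runs), function(r) {
      sd_raw <- 255 * 10^(-target_sn[r] / 20)
      mm <- rep(targets, replicates)
      yy <- numeric(0)
      for (rep_i in seq_len(replicates)) {
        e <- rnorm(k)
        e <- e - targets * sum(targets * e) / sum(targets^2)
        delta <- e * sd_raw * sqrt(k - 1) / sqrt(sum(e^2))
        y <- vapply(seq_len(k), function(i) {
          measure_patch(render_reference_patch(
            targets[i] + delta[i], noise_sd = pixel_noise_sd))
        }, numeric(1))
        yy <- c(yy, y)
      }
      fit <- fit_dynamic(mm / 255, yy / 255)
      tibble::tibble(run = r, beta = fit$beta, sd = fit$sd,
                     sn_db = sn_dynamic(fit))
    })
    attr(res, "truth") <- truth
    attr(res, "target_sn") <- target_sn
    res
  })
}

#' Render and measure a synthetic calibration replicate set
#'
#' The package's default desk-scale calibration study: for each
#' concentration level, renders `replicates` strips (per-strip seeds
#' `seed`, `seed + 1`, ...), runs densitometry and returns the
#' calibration points.
#'
#' @param concentrations Concentration levels, mIU/mL.
#' @param replicates Strips per level.
#' @param spec Base [strip_spec()]; its `concentration` field is
#'   overridden per level.
#' @param params A [camera_params()].
#' @param config A [strip_config()].
#' @param seed Integer seed of the first strip.
#' @return A tibble `concentration`, `signal`, `replicate_id`, `valid`.
#' @export
simulate_calibration_points <- function(
    concentrations = c(6.25, 12.5, 25, 37.5, 50), replicates = 3,
    spec = strip_spec(), params = camera_params(),
    config = strip_config(), seed = 1) {
  grid <- tidyr::expand_grid(concentration = concentrations,
                             replicate_id = seq_len(replicates))
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    sp <- spec
    sp$concentration <- grid$concentration[i]
    img <- render_strip(sp, params, seed = seed + i - 1)
    sig <- extract_line_signal(img, config)
    tibble::tibble(concentration = grid$concentration[i],
                   signal = sig$measured_grayscale,
                   replicate_id = grid$replicate_id[i], valid = sig$valid)
  })
}

#' Write a gallery of synthetic strips with a manifest
#'
#' @param dir Output directory (created if needed).
#' @param concentrations Levels to render.
#' @param replicates Strips per level.
#' @param spec,params Generator settings.
#' @param seed Seed of the first strip (per-strip seeds increment).
#' @return The manifest tibble (`file`, `concentration`, `replicate_id`,
#'   `seed`), also written to `manifest.csv` in `dir`.
#' @export
write_strip_gallery <- function(dir, concentrations = c(0, 6.25, 12.5, 25, 37.5, 50),
                                replicates = 1, spec = strip_spec(),
                                params = camera_params(), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- tidyr::expand_grid(concentration = concentrations,
                             replicate_id = seq_len(replicates))
  manifest <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    sp <- spec
    sp$concentration <- grid$concentration[i]
    s <- seed + i - 1
    img <- render_strip(sp, params, seed = s)
    file <- sprintf("strip_c%s_r%d.png",
                    gsub("[.]", "p", format(grid$concentration[i])),
                    grid$replicate_id[i])
    png::writePNG(img / 255, file.path(dir, file))
    tibble::tibble(file = file, concentration = grid$concentration[i],
                   replicate_id = grid$replicate_id[i], seed = s)
  })
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}
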