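test_that("grayscale conversion uses BT.601 luma with half-up rounding", {
  px <- function(r, g, b) to_grayscale(array(c(r, g, b), dim = c(1, 1, 3)))[1, 1]
  expect_equal(px(255, 255, 255), 255L)
  expect_equal(px(0, 0, 0), 0L)
  expect_equal(px(255, 0, 0), 76L)     # 0.299*255 = 76.245
  expect_equal(px(0, 255, 0), 150L)    # 0.587*255 = 149.685
  # gray input passes through
  m <- matrix(c(10, 20, 30, 40), 2, 2)
  expect_equal(to_grayscale(m), matrix(as.integer(m), 2, 2))
  expect_error(to_grayscale(matrix(numeric(0), 0, 0)),
               class = "lfaquant_error_input")
})

test_that("longitudinal profiles average across the lane width", {
  img <- matrix(200, 30, 10)
  prof <- longitudinal_profile(img)
  expect_equal(prof$gray, rep(200, 30))
  # one-pixel lane equals that pixel column
  img[, 3] <- 77
  prof1 <- longitudinal_profile(img, lane = list(cols = c(3, 3)))
  expect_equal(prof1$gray, rep(77, 30))
  expect_error(longitudinal_profile(img, lane = list(rows = c(0, 5))),
               class = "lfaquant_error_input")
  expect_error(longitudinal_profile(img, lane = list(cols = c(5, 99))),
               class = "lfaquant_error_input")
})

test_that("band calling finds dips and tolerates a flat profile", {
  flat <- tibble::tibble(row = 1:50, gray = rep(200, 50))
  expect_equal(nrow(detect_bands(flat, min_depth = 10)), 0)

  p <- rep(200, 100)
  p[36:43] <- 180   # test band, depth 20
  p[81:88] <- 140   # control band, depth 60
  prof <- tibble::tibble(row = 1:100, gray = p)
  bands <- detect_bands(prof, expected = 2, min_depth = 10)
  expect_equal(nrow(bands), 2)
  expect_equal(bands$center, c(40L, 85L), tolerance = 1)
  expect_equal(bands$background, c(200, 200))
  expect_equal(bands$net_signal, c(20, 60))
  # only the deepest `expected` bands are kept
  one <- detect_bands(prof, expected = 1, min_depth = 10)
  expect_equal(one$center, 85L)
})

test_that("band calling is invariant to a constant offset", {
  p <- rep(180, 100)
  p[36:43] <- 160
  p[81:88] <- 120
  b0 <- detect_bands(tibble::tibble(row = 1:100, gray = p), min_depth = 10)
  b1 <- detect_bands(tibble::tibble(row = 1:100, gray = p + 30), min_depth = 10)
  expect_equal(b1$center, b0$center)
  expect_equal(b1$net_signal, b0$net_signal)
})

test_that("line signals carry role assignment and the validity rule", {
  # blank-analyte strip: control only, valid, zero net test signal
  blank <- render_strip(strip_spec(concentration = 0), seed = 21)
  s0 <- extract_line_signal(blank)
  expect_true(s0$valid)
  expect_equal(s0$n_bands, 1L)
  expect_true(is.na(s0$test_mean))
  expect_equal(s0$measured_grayscale, 0)

  s50 <- extract_line_signal(render_strip(strip_spec(concentration = 50), seed = 22))
  s6 <- extract_line_signal(render_strip(strip_spec(concentration = 6.25), seed = 23))
  expect_true(s50$valid && s6$valid)
  expect_lt(s50$test_mean, s6$test_mean)       # darker line at high dose
  expect_gt(s50$measured_grayscale, s6$measured_grayscale)  # net polarity

  # featureless image: no control line, invalid
  s_none <- extract_line_signal(matrix(200, 120, 60))
  expect_false(s_none$valid)
  expect_true(is.na(s_none$measured_grayscale))

  # raw polarity reports the band grayscale itself
  raw <- extract_line_signal(render_strip(strip_spec(concentration = 50), seed = 22),
                             strip_config(polarity = "raw"))
  expect_equal(raw$measured_grayscale, raw$test_mean)
})

test_that("test-line grayscale decreases with concentration (seed-averaged)", {
  concs <- c(6.25, 12.5, 25, 37.5, 50)
  mean_gray <- sapply(concs, function(cc) {
    mean(sapply(1:8, function(s) {
      sig <- extract_line_signal(render_strip(strip_spec(concentration = cc),
                                              seed = 100 + s))
      sig$test_mean
    }))
  })
  expect_true(all(diff(mean_gray) < 0))
})

test_that("band centers are recovered within one row on 100 seeded strips", {
  hits <- sapply(1:100, function(s) {
    img <- render_strip(strip_spec(concentration = 25), seed = s)
    truth <- attr(img, "truth")
    sig <- extract_line_signal(img)
    abs(sig$control_center - truth$control_center) <= 1 &&
      abs(sig$test_center - truth$test_center) <= 1
  })
  expect_true(all(hits))
})

test_that("batch densitometry returns one row per image", {
  imgs <- list(render_strip(strip_spec(concentration = 25), seed = 1),
               render_strip(strip_spec(concentration = 0), seed = 2))
  out <- measure_strips(imgs)
  expect_equal(nrow(out), 2)
  expect_equal(out$valid, c(TRUE, TRUE))
  expect_equal(out$image, c("image_1", "image_2"))
})
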