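exact_points <- function() {
  tidyr::expand_grid(concentration = c(6.25, 12.5, 25, 37.5, 50),
                     replicate_id = 1:2) |>
    dplyr::mutate(signal = 2 * concentration + 5)
}

test_that("an exact line is recovered with unit R-squared", {
  m <- fit_calibration(exact_points())
  expect_equal(m$slope, 2)
  expect_equal(m$intercept, 5)
  expect_equal(m$r_squared, 1)
  expect_equal(m$residual_sd, 0)
  expect_true(m$accepted)
  expect_equal(m$range, c(6.25, 50))
})

test_that("degenerate designs and flat signals are rejected", {
  flat <- tibble::tibble(concentration = c(6.25, 12.5, 25), signal = 40)
  m <- fit_calibration(flat)
  expect_equal(m$slope, 0)
  expect_false(m$accepted)
  expect_error(invert_calibration(m, 40), class = "lfaquant_error_degenerate")
  one <- tibble::tibble(concentration = rep(25, 3), signal = c(1, 2, 3))
  expect_error(fit_calibration(one), class = "lfaquant_error_degenerate")
})

test_that("inversion is exact algebra with range flagging", {
  m <- fit_calibration(exact_points())
  q <- invert_calibration(m, 25)
  expect_equal(q$estimate, 10)
  expect_true(q$in_range)
  expect_false(invert_calibration(m, 2 * 60 + 5)$in_range)  # above 50
  # round trip on the fitted line
  for (cc in c(6.25, 19, 50)) {
    expect_equal(invert_calibration(m, predict(m, cc))$estimate, cc,
                 tolerance = 1e-9)
  }
  q_err <- invert_calibration(m, predict(m, 20), truth = 25)
  expect_equal(q_err$percent_error, 100 * 5 / 25)
})

test_that("log-concentration calibration inverts through exp", {
  pts <- tibble::tibble(concentration = c(6.25, 12.5, 25, 50),
                        signal = 3 + 7 * log(c(6.25, 12.5, 25, 50)))
  m <- fit_calibration(pts, log_concentration = TRUE)
  expect_equal(m$r_squared, 1)
  expect_equal(invert_calibration(m, predict(m, 25))$estimate, 25,
               tolerance = 1e-9)
})

test_that("precision profiling computes per-level CV and percent error", {
  m <- fit_calibration(exact_points())
  pts <- tibble::tibble(concentration = 25,
                        signal = predict(m, c(24, 25, 26)),
                        replicate_id = 1:3)
  pp <- precision_profile(pts, m)
  expect_equal(pp$cv, 100 * sd(c(24, 25, 26)) / 25)
  expect_equal(pp$percent_error, 0)
  expect_true(pp$cv_defined)
  # identical replicates: zero CV
  same <- tibble::tibble(concentration = 25, signal = rep(predict(m, 25), 3))
  expect_equal(precision_profile(same, m)$cv, 0)
  # a single replicate has no CV and is flagged
  single <- tibble::tibble(concentration = 12.5, signal = predict(m, 12))
  pp1 <- precision_profile(single, m)
  expect_true(is.na(pp1$cv))
  expect_false(pp1$cv_defined)
})

test_that("R-squared degrades monotonically with injected noise (seed-averaged)", {
  conc <- rep(c(6.25, 12.5, 25, 37.5, 50), each = 3)
  r2_at <- function(noise_sd) {
    mean(sapply(1:20, function(s) {
      set.seed(1000 + s)
      pts <- tibble::tibble(concentration = conc,
                            signal = 1.6 * conc + rnorm(length(conc), 0, noise_sd))
      fit_calibration(pts)$r_squared
    }))
  }
  r2 <- sapply(c(0.5, 4, 16), r2_at)
  expect_true(all(diff(r2) < 0))
  expect_equal(r2_at(0), 1)
})

test_that("the fitted slope falls within 3 standard errors of truth", {
  conc <- rep(c(6.25, 12.5, 25, 37.5, 50), each = 3)
  hits <- sapply(1:200, function(s) {
    set.seed(s)
    pts <- tibble::tibble(concentration = conc,
                          signal = -3 + 1.6 * conc + rnorm(length(conc), 0, 2))
    m <- fit_calibration(pts)
    se <- tidy(m)$std.error[2]
    abs(m$slope - 1.6) <= 3 * se
  })
  expect_gte(mean(hits), 0.95)
})

test_that("tidy and glance summarise the calibration fit", {
  m <- fit_calibration(exact_points())
  # lm warns about the exact fit when summarising; that is the point here
  td <- suppressWarnings(tidy(m))
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(td$estimate, c(5, 2))
  gl <- glance(m)
  expect_equal(gl$r_squared, 1)
  expect_equal(gl$n, 10)
})
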