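targets <- c(247, 249, 251, 253, 255)

test_that("the through-origin dynamic fit matches closed-form cases", {
  f <- fit_dynamic(targets, targets)
  expect_equal(f$beta, 1)
  expect_equal(f$sd, 0)

  f <- fit_dynamic(c(1, 2), c(2, 4))
  expect_equal(f$beta, 2)
  expect_equal(f$sd, 0)

  # alternating unit perturbation on the reference ladder
  f <- fit_dynamic(targets, targets + c(1, -1, 1, -1, 0))
  expect_equal(f$beta, 0.9999873, tolerance = 1e-6)
  expect_equal(f$sd, 1.0000, tolerance = 1e-4)
})

test_that("fit_dynamic agrees with an independent RSS-minimizing oracle", {
  set.seed(42)
  for (i in 1:25) {
    m <- runif(5, 1, 255)
    y <- runif(1, 0.5, 2) * m + rnorm(5, 0, 2)
    f <- fit_dynamic(m, y)
    o <- oracle_dynamic_sn(m, y)
    expect_equal(f$beta, o$beta, tolerance = 1e-8)
    expect_equal(f$sd, o$sd, tolerance = 1e-8)
  }
})

test_that("degenerate and malformed fits are rejected", {
  expect_error(fit_dynamic(1:3, 1:2), class = "lfaquant_error_input")
  expect_error(fit_dynamic(1, 1), class = "lfaquant_error_input")
  expect_error(fit_dynamic(c(0, 0), c(1, 2)),
               class = "lfaquant_error_degenerate")
})

test_that("the intercept-form alternative fits an ordinary line", {
  m <- c(1, 2, 3, 4)
  y <- 3 + 2 * m
  f <- fit_dynamic(m, y, method = "intercept")
  expect_equal(f$beta, 2)
  expect_equal(f$sd, 0)
})

test_that("sn_dynamic evaluates the dynamic S/N formula", {
  expect_equal(sn_dynamic(1, 0.1), 20)
  # confirmation-run values, normalized-grayscale scale
  expect_equal(sn_dynamic(1.0037, 0.0063), 44.0453, tolerance = 1e-4)
  expect_equal(sn_dynamic(1.0004, 0.0035), 49.1221, tolerance = 1e-4)
})

test_that("a perfect fit is an unbounded-S/N outcome, not a number", {
  expect_identical(sn_dynamic(1, 0), Inf)
  expect_identical(sn_dynamic(fit_dynamic(targets, 3 * targets)), Inf)
  expect_error(sn_dynamic(0, 1), class = "lfaquant_error_degenerate")
  expect_error(sn_dynamic(1, -1), class = "lfaquant_error_input")
})

test_that("S/N is invariant under joint (beta, sd) scaling and monotone", {
  base <- sn_dynamic(1.2, 0.05)
  for (c in c(0.1, 2, 17)) {
    expect_equal(sn_dynamic(c * 1.2, c * 0.05), base)
  }
  expect_gt(sn_dynamic(1.5, 0.05), base)   # larger |beta|
  expect_lt(sn_dynamic(1.2, 0.2), base)    # larger sd
  # exact proportionality stays a perfect fit under any slope
  for (k in c(-2, 0.3, 5)) {
    expect_identical(sn_dynamic(fit_dynamic(targets, k * targets)), Inf)
  }
})

test_that("run_responses computes per-run S/N on the normalized scale", {
  run_data <- tibble::tibble(
    run = 1:2,
    M_1 = 247, M_2 = 249, M_3 = 251, M_4 = 253, M_5 = 255,
    y_1 = c(247, 248), y_2 = c(249, 248), y_3 = c(251, 252),
    y_4 = c(253, 252), y_5 = c(255, 255))
  out <- run_responses(run_data)
  expect_equal(nrow(out), 2)
  expect_identical(out$sn_db[1], Inf)
  # dividing both signals by 255 shifts S/N by +20*log10(255)
  raw <- run_responses(run_data, normalize = FALSE)
  expect_equal(out$sn_db[2], raw$sn_db[2] + 20 * log10(255))
  expect_equal(out$beta, raw$beta)
})
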