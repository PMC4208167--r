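test_that("rendering is bit-identical for a fixed seed and spec", {
  a <- render_strip(strip_spec(), seed = 9)
  b <- render_strip(strip_spec(), seed = 9)
  expect_identical(a, b)
  c <- render_strip(strip_spec(), seed = 10)
  expect_false(identical(a, c))
})

test_that("a neutral noiseless render hits membrane minus depth exactly", {
  sp <- strip_spec(concentration = 50, noise_sd = 0, depth_cv = 0)
  g <- to_grayscale(render_strip(sp, seed = 1))
  expect_equal(g[5, 5], 200L)                      # membrane
  expect_equal(g[40, 30], 200L - 80L)              # test band luma drop
  expect_equal(g[85, 30], 200L - 60L)              # control band luma drop
  # zero concentration leaves no test band in the noiseless limit
  sp0 <- strip_spec(concentration = 0, noise_sd = 0, depth_cv = 0)
  g0 <- to_grayscale(render_strip(sp0, seed = 1))
  expect_equal(g0[40, 30], 200L)
  expect_equal(g0[85, 30], 140L)
})

test_that("the dose-response is clamped above 50 mIU/mL", {
  g50 <- to_grayscale(render_strip(strip_spec(concentration = 50, noise_sd = 0,
                                              depth_cv = 0), seed = 1))
  g99 <- to_grayscale(render_strip(strip_spec(concentration = 99, noise_sd = 0,
                                              depth_cv = 0), seed = 1))
  expect_equal(g50[40, 30], g99[40, 30])
})

test_that("reference patches reproduce the standard grayscales under neutral params", {
  expect_equal(reference_targets(), c(247, 249, 251, 253, 255))
  measured <- sapply(reference_targets(), function(g)
    measure_patch(render_reference_patch(g)))
  expect_equal(measured, reference_targets())
  # a non-neutral gamma bends the measured values away from the targets
  warped <- sapply(reference_targets(), function(g)
    measure_patch(render_reference_patch(g, camera_params(gamma = 3))))
  expect_true(all(warped[1:4] < reference_targets()[1:4]))
  expect_equal(warped[5], 255)  # full white is a gamma fixed point
})

test_that("camera transforms act as documented", {
  flat <- array(100, dim = c(10, 10, 3))
  m <- function(p) mean(apply_camera_for_tests(flat, p))
  expect_equal(m(camera_params()), 100)
  expect_equal(m(camera_params(brightness = 20)), 120)
  expect_equal(m(camera_params(exposure = 1.5)), 150)
  # contrast pivots about mid-gray
  expect_equal(m(camera_params(contrast = 0.5)), 127.5 + 0.5 * (100 - 127.5))
  # gamma = 1 is neutral, gamma > 1 darkens midtones
  expect_lt(m(camera_params(gamma = 2)), 100)
  # highlight knee only affects values above 240
  bright <- array(250, dim = c(4, 4, 3))
  expect_equal(mean(apply_camera_for_tests(bright,
    camera_params(backlight_compensation = TRUE))), 245)
  expect_error(camera_params(gamma = 0), class = "lfaquant_error_input")
  expect_error(camera_params(saturation = -5), class = "lfaquant_error_input")
})

test_that("effect models separate influential from weak factors", {
  em <- effect_model(c(A = 3, B = -0.4))
  expect_equal(em$influential, "A")
  expect_error(effect_model(c(A = 1.5)), class = "lfaquant_error_input")
})

test_that("simulated run S/N carries the declared ground truth", {
  d <- l12()
  asg <- hcg_assignment()
  em <- effect_model(c(A = 4, F = -6), noise_sd = 0, base_sn = 45)
  sim <- simulate_run_sn(d, asg, em, seed = 1)
  rt <- sn_response_table(d, sim$sn_db, asg)
  expect_equal(rt$effect[rt$term == "A"], 4, tolerance = 1e-9)
  expect_equal(rt$effect[rt$term == "F"], -6, tolerance = 1e-9)
  expect_equal(grand_mean(rt), 45, tolerance = 1e-9)
  # an injected dominant factor tops the ranking under noise
  em8 <- effect_model(c(D = 8), noise_sd = 0.5)
  sim8 <- simulate_run_sn(d, asg, em8, seed = 2)
  rt8 <- sn_response_table(d, sim8$sn_db, asg)
  expect_equal(rt8$term[rt8$rank == 1], "D")
})

test_that("declared interactions enter the simulated response", {
  d <- l12()
  asg <- hcg_assignment()
  em <- effect_model(c(A = 3), noise_sd = 0,
                     interactions = tibble::tibble(factor_a = "A",
                                                   factor_b = "I",
                                                   coefficient = 1))
  sim <- simulate_run_sn(d, asg, em, seed = 1)
  ic <- suppressWarnings(interaction_cells(d, sim$sn_db, 1, 9))
  expect_equal(ic$nonparallelism, 4, tolerance = 1e-9)
})

test_that("the rendered screening simulation realizes its target S/N", {
  d <- l12()
  asg <- hcg_assignment()
  sim <- simulate_l12(d, asg, hcg_effect_model(), seed = 5)
  target <- attr(sim, "target_sn")
  expect_equal(sim$sn_db, target, tolerance = 0.02)
  expect_equal(sim$beta, rep(1, 12), tolerance = 1e-3)
  rt <- sn_response_table(d, sim$sn_db, asg)
  expect_setequal(rt$term[rt$rank <= 3], c("A", "F", "I"))
  expect_error(simulate_l12(d, asg, replicates = 0),
               class = "lfaquant_error_input")
})

test_that("a zero-error effect model makes every rendered run a perfect fit", {
  d <- l12()
  em <- effect_model(noise_sd = 0, base_sn = Inf)
  sim <- simulate_l12(d, hcg_assignment(), em, seed = 1, pixel_noise_sd = 0)
  expect_true(all(is.infinite(sim$sn_db)))
  expect_equal(sim$sd, rep(0, 12))
})

test_that("the strip gallery round-trips through PNG", {
  dir <- withr::local_tempdir()
  manifest <- write_strip_gallery(dir, concentrations = c(0, 25),
                                  replicates = 1, seed = 4)
  expect_equal(nrow(manifest), 2)
  expect_true(all(file.exists(file.path(dir, manifest$file))))
  img <- render_strip(strip_spec(concentration = 25), seed = manifest$seed[2])
  reread <- read_strip(file.path(dir, manifest$file[2]))
  expect_equal(reread, img, ignore_attr = TRUE)
})
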