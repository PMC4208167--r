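test_that("column sums of squares follow (n/4) * effect^2 and decompose the total", {
  d <- l12()
  set.seed(3)
  for (i in 1:10) {
    sn <- rnorm(12, 43, 2)
    rt <- sn_response_table(d, sn)
    at <- sn_anova(d, sn, hcg_assignment())
    cols <- at[!is.na(at$column), ]
    expect_equal(cols$ss[order(cols$column)], 3 * rt$effect^2,
                 tolerance = 1e-9)
    total <- at$ss[at$term == "(total)"]
    expect_equal(total, sum((sn - mean(sn))^2), tolerance = 1e-6)
    expect_equal(sum(cols$ss[!cols$pooled]) + at$ss[at$term == "(error)"],
                 total, tolerance = 1e-6)
  }
})

test_that("the published screening column A has SS near 29.75 dB^2", {
  at <- sn_anova(l12(), published_run_sn(), hcg_assignment())
  expect_equal(at$ss[at$term == "A"], 3 * 3.1489^2, tolerance = 1e-3)
  expect_equal(at$ss[at$term == "A"], 29.75, tolerance = 0.01)
})

test_that("a constant response yields all-zero sums of squares", {
  at <- sn_anova(l12(), rep(40, 12), hcg_assignment())
  expect_true(all(at$ss[!is.na(at$column)] == 0))
})

test_that("an injected 8 dB effect clears 95% confidence under run noise", {
  d <- l12()
  asg <- hcg_assignment()
  em <- effect_model(effects = c(C = 8), noise_sd = 0.5)
  sim <- simulate_run_sn(d, asg, em, seed = 123)
  at <- sn_anova(d, sim$sn_db, asg)
  expect_gt(at$confidence[at$term == "C"], 95)
  expect_true("C" %in% significant_factors(at))
})

test_that("unassigned columns are always pooled and pooling tops up the error df", {
  d <- l12()
  sn <- published_run_sn()
  at <- sn_anova(d, sn, hcg_assignment(), min_error_df = 2)
  expect_true(at$pooled[at$term == "err1"])
  expect_equal(at$df[at$term == "(error)"], 2)
  at4 <- sn_anova(d, sn, hcg_assignment(), min_error_df = 4)
  expect_equal(at4$df[at4$term == "(error)"], 4)
  # the top-up takes the weakest factors
  pooled4 <- at4$term[which(at4$pooled)]
  expect_true(all(c("err1", "J", "B", "G") %in% pooled4))
})

test_that("a saturated assignment without pooling cannot be tested", {
  d <- oa_array(3)
  asg <- tibble::tibble(factor_id = c("A", "B", "C"), column = 1:3)
  expect_error(sn_anova(d, c(1, 2, 3, 4), asg, pool = "none",
                        min_error_df = 0),
               class = "lfaquant_error_pooling")
})

test_that("significant_factors filters strictly and orders by F", {
  at <- sn_anova(l12(), published_run_sn(), hcg_assignment())
  sig <- significant_factors(at, threshold = 95)
  expect_equal(sig, c("F", "I", "A"))  # descending F
  expect_equal(significant_factors(at, threshold = 99.9), character(0))
  # lower threshold admits more factors, still ordered
  sig90 <- significant_factors(at, threshold = 90)
  expect_true(all(c("F", "I", "A", "D") %in% sig90))
  expect_equal(sig90[1:3], c("F", "I", "A"))
})
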