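# Shared fixtures, all built in code.

l12 <- function() oa_array(10)

hcg_assignment <- function() hcg_camera_factors()

# Response table of the reference hCG screening experiment (shipped data).
published_rt <- function() as_response_table(hcg_screening_table())

# Canonical run-S/N vector consistent with the published level means.
published_run_sn <- function() {
  rt <- published_rt()
  sn_from_effects(l12(), grand_mean(rt), rt$effect[order(rt$column)])
}

# The raw camera pipeline (internal; exercised directly in tests).
apply_camera_for_tests <- function(img, params) {
  lfaquant:::apply_camera(img, params)
}

# Independent oracle for the dynamic fit: golden-section minimization of
# the residual sum of squares over the slope, plus the direct S/N formula.
oracle_dynamic_sn <- function(m, y) {
  rss <- function(b) sum((y - b * m)^2)
  guess <- sum(m * y) / sum(m^2)
  b <- stats::optimize(rss, interval = c(guess - 2, guess + 2),
                       tol = 1e-12)$minimum
  s <- sqrt(rss(b) / (length(m) - 1))
  list(beta = b, sd = s, sn = -10 * log10(s^2 / b^2))
}
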