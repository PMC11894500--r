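test_that("same seed gives bit-identical PSA runs", {
  p <- base_params
  a <- run_psa(p, n_draws = 300, seed = 7, keep_draws = TRUE)
  b <- run_psa(p, n_draws = 300, seed = 7, keep_draws = TRUE)
  expect_identical(a$summary, b$summary)
  expect_identical(a$draws, b$draws)
  c <- run_psa(p, n_draws = 300, seed = 8)
  expect_false(identical(a$summary, c$summary))
})

test_that("zero-variance PSA equals the deterministic evaluation", {
  p <- base_params
  psa <- run_psa(p, n_draws = 1, seed = 1, uncertainty_scale = 0)
  bc <- run_base_case(p)
  for (i in seq_len(nrow(psa$summary))) {
    row <- psa$summary[i, ]
    ref <- bc[bc$strategy == row$strategy & bc$perspective == row$perspective, ]
    expect_equal(row$hob_mean, ref$hob_per_1000)
    expect_equal(row$cost_mean, ref$total_cost_per_1000)
    expect_equal(row$hob_lo, row$hob_hi)
  }
})

test_that("PSA means converge to the point evaluation as spread shrinks", {
  p <- base_params
  psa <- run_psa(p, n_draws = 2000, seed = 3, uncertainty_scale = 0.01)
  bc <- run_base_case(p)
  for (i in seq_len(nrow(psa$summary))) {
    row <- psa$summary[i, ]
    ref <- bc[bc$strategy == row$strategy & bc$perspective == row$perspective, ]
    expect_equal(row$hob_mean, ref$hob_per_1000, tolerance = 1e-3)
    expect_equal(row$cost_mean, ref$total_cost_per_1000, tolerance = 1e-3)
  }
})

test_that("sampled parameters have the specified distributions", {
  p <- base_params
  set.seed(21)
  d <- decolcea:::sample_parameter_draws(p, 1e5)
  # beta risk for (device, MRSA+, surgical): mean 18/164 within 3 SE
  expect_lt(abs(mean(d$p_hob[, 1]) - 18 / 164),
            3 * sd(d$p_hob[, 1]) / sqrt(1e5))
  # treated HRR is exp(Normal(log 0.86, 0.059)): check on the log scale
  expect_lt(abs(mean(log(d$hrr_treated)) - log(0.86)),
            3 * 0.059 / sqrt(1e5))
  expect_lt(abs(median(d$hrr_treated) - 0.86), 0.002)
  # gamma cost mean
  expect_lt(abs(mean(d$chg_bed) - 5.52), 3 * 1.84 / sqrt(1e5))
  # payer cost: truncated at zero, inflated to 2022 scale
  expect_true(all(d$excess_payer >= 0))
  expect_equal(mean(d$excess_payer) /
                 (19643 * p$inflation_factor_2006_to_2022), 1,
               tolerance = 0.01)
  # length of stay: arithmetic mean 6.5
  expect_lt(abs(mean(d$los) - 6.5), 3 * sd(d$los) / sqrt(1e5))
})

test_that("single-draw sampling returns a valid substituted parameter set", {
  set.seed(5)
  sp <- sample_parameters(base_params)
  expect_s3_class(sp, "decol_params")
  expect_false(identical(sp$risk$p_hob, base_params$risk$p_hob))
  # fixed rows copied unchanged
  expect_identical(sp$mix, base_params$mix)
  expect_identical(sp$adherence, base_params$adherence)
  expect_identical(sp$costs$p_bed_bath, base_params$costs$p_bed_bath)
  expect_identical(sp$costs$excess_hob_hospital,
                   base_params$costs$excess_hob_hospital)
})

test_that("the log-normal HRR mean uplift is bounded by exp(sigma^2/2)", {
  p <- base_params
  psa <- run_psa(p, n_draws = 10000, seed = 13, which_perspectives = "payer")
  bc <- run_base_case(p, "payer")
  bound <- exp(max(p$effect$log_sd_treated, p$effect$log_sd_untreated)^2 / 2)
  for (nm in c("SOC", "TD", "UD")) {
    ratio <- psa$summary$hob_mean[psa$summary$strategy == nm] /
      bc$hob_per_1000[bc$strategy == nm]
    expect_lt(ratio, bound + 0.002)  # MC slack on a ~0.2% bound
    expect_gt(ratio, 1 - 0.005)
  }
})

test_that("doubling the number of draws halves the standard error", {
  p <- base_params
  means_at <- function(n, seeds) {
    vapply(seeds, function(s) {
      run_psa(p, n_draws = n, seed = s,
              which_perspectives = "payer")$summary$hob_mean[1]
    }, 0)
  }
  sd1 <- sd(means_at(150, 1:40))
  sd2 <- sd(means_at(600, 101:140))  # 4x draws -> half the SE
  expect_equal(sd1 / sd2, 2, tolerance = 0.35)
})

test_that("uncertainty intervals bracket their means, pairwise incrementals", {
  psa <- run_psa(base_params, n_draws = 2000, seed = 17)
  s <- psa$summary
  expect_true(all(s$hob_lo <= s$hob_mean & s$hob_mean <= s$hob_hi))
  expect_true(all(s$cost_lo <= s$cost_mean & s$cost_mean <= s$cost_hi))
  inc <- psa$incremental
  expect_true(all(inc$cost_diff_lo <= inc$cost_diff_mean &
                    inc$cost_diff_mean <= inc$cost_diff_hi))
  # paired differencing: the cost interval spans zero at base case
  expect_lt(inc$cost_diff_lo[inc$perspective == "payer"], 0)
  expect_gt(inc$cost_diff_hi[inc$perspective == "payer"], 0)
  # average ICER = ratio of means, not mean of ratios
  expect_equal(inc$icer, inc$cost_diff_mean / inc$hob_averted_mean)
  # optimal-strategy probabilities form a distribution per perspective
  po <- psa$prob_optimal
  for (pvn in unique(po$perspective)) {
    expect_equal(sum(po$prob_optimal[po$perspective == pvn]), 1)
  }
})
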