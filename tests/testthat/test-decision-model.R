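test_that("strategy rules follow the published assignment", {
  p <- base_params
  st <- strategy_set(p)
  s <- decol_strata()
  a <- p$adherence
  # SOC: CHG only for surgical strata at 50%, never mupirocin
  expect_equal(st$SOC$chg, ifelse(s$surgical, a$soc_surgical_chg, 0))
  expect_equal(st$SOC$mupirocin, rep(0, 8))
  # UD: CHG everywhere, mupirocin for MRSA history
  expect_equal(st$UD$chg, rep(a$ud_chg, 8))
  expect_equal(st$UD$mupirocin, ifelse(s$mrsa_history, a$ud_mupirocin, 0))
  # TD: device strata at relative adherence, SOC bathing otherwise
  expect_equal(st$TD$chg[s$has_device],
               rep(a$td_relative * a$ud_chg, 4))
  expect_equal(st$TD$chg[!s$has_device], st$SOC$chg[!s$has_device])
  expect_equal(st$TD$mupirocin > 0, s$has_device & s$mrsa_history)
})

test_that("expected HOB reduces to the weighted baseline when HRRs are 1", {
  p <- base_params
  p$effect$hrr_treated <- 1
  p$effect$hrr_untreated <- 1
  # independent oracle: brute-force weighted sum over the 8 strata
  w <- stratum_weights(p$mix)
  oracle <- 1000 * sum(w * p$risk$p_hob)
  for (st in strategy_set(p)) {
    expect_equal(expected_hob(st, p), oracle, tolerance = 1e-12)
  }
})

test_that("expected HOB is zero when all stratum risks are zero", {
  p <- base_params
  p$risk$p_hob <- rep(0, 8)
  for (st in strategy_set(p)) expect_equal(expected_hob(st, p), 0)
})

test_that("expected HOB is nonincreasing in CHG receipt for device strata", {
  p <- base_params
  st <- strategy_set(p)$UD
  vals <- vapply(seq(0, 1, by = 0.1), function(chg) {
    st$chg <- rep(chg, 8)
    expected_hob(st, p)
  }, 0)
  expect_true(all(diff(vals) < 0))  # strict: hrr_treated < hrr_untreated
})

test_that("the treatment effect depends only on receipt, not strategy label", {
  p <- base_params
  st <- strategy_set(p)
  td_like_ud <- st$TD
  td_like_ud$chg <- st$UD$chg
  expect_equal(expected_hob(td_like_ud, p), expected_hob(st$UD, p))
})

test_that("the SOC untreated-HRR convention switch changes only SOC", {
  p2 <- build_base_case(apply_untreated_hrr_under_soc = FALSE)
  st <- strategy_set(p2)
  # SOC: unbathed device patients revert to multiplier 1 -> lower HOB
  expect_lt(expected_hob(st$SOC, p2),
            expected_hob(strategy_set(base_params)$SOC, base_params))
  expect_equal(expected_hob(st$UD, p2),
               expected_hob(strategy_set(base_params)$UD, base_params))
})

test_that("upstream costs match hand-computed daily bathing arithmetic", {
  p <- base_params
  # standard-soap daily mixture: 0.78 x 2.11 + 0.22 x 0.44 = 1.7426/day
  p0 <- p
  p0$adherence$soc_surgical_chg <- 0
  soc0 <- strategy_set(p0)$SOC
  expect_equal(upstream_cost(soc0, p0), 1.7426 * 6.5 * 1000,
               tolerance = 1e-10)
  # full-adherence CHG mixture: 0.78 x 5.52 + 0.22 x 0.4375 = 4.40185/day
  full <- soc0
  full$chg <- rep(1, 8)
  expect_equal(upstream_cost(full, p0), 4.40185 * 6.5 * 1000,
               tolerance = 1e-10)
  # zero length of stay leaves only mupirocin costs
  pz <- p
  pz$costs$los_mean <- 0
  ud <- strategy_set(pz)$UD
  expect_equal(upstream_cost(ud, pz),
               1000 * 0.08 * pz$adherence$ud_mupirocin *
                 pz$costs$mupirocin_course)
})

test_that("mupirocin counts follow the eligibility and adherence products", {
  p <- base_params
  st <- strategy_set(p)
  expect_equal(mupirocin_treated(st$SOC, p), 0)
  expect_equal(mupirocin_treated(st$UD, p), 1000 * 0.08 * 0.88)
  expect_equal(mupirocin_treated(st$TD, p),
               1000 * 0.125 * 0.08 * 0.9 * 0.88)
})

test_that("outcomes are linear in unit costs and the excess HOB cost", {
  p <- base_params
  pv <- perspectives(p)$hospital
  st <- strategy_set(p)$TD
  o1 <- evaluate_strategy(st, p, pv)
  expect_identical(o1$total_cost_per_1000,
                   o1$upstream_cost_per_1000 + o1$downstream_cost_per_1000)
  # doubling the excess HOB cost doubles downstream, leaves upstream alone
  pv2 <- pv
  pv2$excess_hob_cost <- 2 * pv$excess_hob_cost
  o2 <- evaluate_strategy(st, p, pv2)
  expect_equal(o2$downstream_cost_per_1000, 2 * o1$downstream_cost_per_1000)
  expect_equal(o2$upstream_cost_per_1000, o1$upstream_cost_per_1000)
  # doubling every bathing unit cost doubles bathing upstream costs
  p2 <- p
  for (nm in c("chg_bed_bath_per_day", "chg_shower_bottle",
               "std_bed_bath_per_day", "std_shower_per_day",
               "mupirocin_course")) {
    p2$costs[[nm]] <- 2 * p$costs[[nm]]
  }
  expect_equal(upstream_cost(st, p2), 2 * upstream_cost(st, p))
})

test_that("strategies reject probabilities outside [0, 1]", {
  st <- strategy_set(base_params)$UD
  st$chg[1] <- 1.2
  expect_error(expected_hob(st, base_params), "\\[0, 1\\]")
})
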