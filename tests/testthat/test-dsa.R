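test_that("one-way curves pass through the base case and move as expected", {
  p <- base_params
  pv <- perspectives(p)$payer
  st <- strategy_set(p)
  base_averted <- expected_hob(st$TD, p) - expected_hob(st$UD, p)
  base_cost <- evaluate_strategy(st$UD, p, pv)$total_cost_per_1000 -
    evaluate_strategy(st$TD, p, pv)$total_cost_per_1000

  cur <- one_way_curve("p_device", c(0.125, 0.25, 0.375, 0.5), p, pv)
  expect_equal(cur$hob_averted_ud_vs_td[1], base_averted)
  expect_equal(cur$inc_cost_ud_vs_td[1], base_cost)
  # incremental HOB averted grows with device prevalence ...
  expect_true(all(diff(cur$hob_averted_ud_vs_td) > 0))
  # ... and shrinks as targeted adherence approaches universal adherence
  cur2 <- one_way_curve("td_relative_adherence", c(0.5, 0.7, 0.9, 1), p, pv)
  expect_true(all(diff(cur2$hob_averted_ud_vs_td) < 0))
  expect_error(one_way_curve("not_a_parameter", 1, p, pv), "unknown")
})

test_that("equal targeted and universal adherence leaves no device effect", {
  p <- base_params
  pv <- perspectives(p)$payer
  cur <- one_way_curve("td_relative_adherence", 1, p, pv)
  # receipt equal on device strata; HRRs touch nothing else
  expect_equal(cur$hob_averted_ud_vs_td, 0, tolerance = 1e-12)
  # costs still differ: non-device strata are bathed differently
  expect_gt(cur$inc_cost_ud_vs_td, 0)
})

test_that("grid search honors WTP zero and the cell cap", {
  p <- base_params
  pv <- perspectives(p)$payer
  g <- grid_search(list(wtp = 0, p_device = c(0.125, 0.3, 0.5)), p, pv)
  # at zero willingness-to-pay the cheapest strategy wins each cell
  for (i in seq_len(nrow(g))) {
    mod <- decolcea:::apply_dsa_value(p, "p_device", g$p_device[i])$params
    bc <- run_base_case(mod, "payer")
    expect_equal(g$optimal[i],
                 bc$strategy[which.min(bc$total_cost_per_1000)])
  }
  expect_error(grid_search(list(wtp = 1:101, p_device = 1:101 / 202), p, pv,
                           max_cells = 100), "cap")
  expect_error(grid_search(list(bogus = 1), p, pv), "unknown")
})

test_that("cells evaluated singly match cells evaluated in batch", {
  p <- base_params
  pv <- perspectives(p)$hospital
  axes <- list(p_device = c(0.125, 0.5), wtp = c(0, 50000))
  batch <- grid_search(axes, p, pv)
  for (i in seq_len(nrow(batch))) {
    single <- grid_search(list(p_device = batch$p_device[i],
                               wtp = batch$wtp[i]), p, pv)
    expect_equal(single$optimal, batch$optimal[i])
  }
})

test_that("the universal-decolonization region grows monotonically", {
  p <- base_params
  pv <- perspectives(p)$payer
  axes <- list(
    p_device = seq(0.125, 0.5, length.out = 5),
    hrr_reduction = seq(0, 0.5, length.out = 5),
    wtp = seq(0, 50000, length.out = 5),
    td_absolute_adherence = seq(0.40, 0.71, length.out = 5)
  )
  g <- grid_search(axes, p, pv)
  expect_true(all(g$optimal %in% c("SOC", "TD", "UD")))
  ud <- g$optimal == "UD"
  expect_true(any(ud) && !all(ud))
  # once UD is optimal it stays optimal as each favorable coordinate moves:
  # device prevalence up, effect size up, WTP up, TD adherence down
  along <- function(flag, key, increasing) {
    others <- setdiff(names(axes), key)
    for (grp in split(seq_len(nrow(g)), g[others])) {
      ord <- grp[order(g[[key]][grp], decreasing = !increasing)]
      expect_true(all(diff(flag[ord]) >= 0))
    }
  }
  along(ud, "p_device", increasing = TRUE)
  along(ud, "hrr_reduction", increasing = TRUE)
  along(ud, "wtp", increasing = TRUE)
  along(ud, "td_absolute_adherence", increasing = FALSE)
})

test_that("threshold regression slope equals minus the mean HOB averted", {
  p <- base_params
  th <- threshold_scatter(p, td_adherence_values = 0.40, n_draws = 4000,
                          seed = 41)[[1]]
  # closed form: incremental cost = upstream diff - averted x HOB cost,
  # so the slope estimates -E[HOB averted]
  mod <- decolcea:::apply_dsa_value(p, "td_absolute_adherence", 0.40)$params
  st <- strategy_set(mod)
  analytic <- expected_hob(st$TD, mod) - expected_hob(st$UD, mod)
  slope_se <- summary(th$fit)$coefficients["x", "Std. Error"]
  # small allowance for the log-normal HRR mean uplift absent from the
  # point evaluation (< 0.4% of the effect)
  expect_lt(abs(th$slope + analytic), 3 * slope_se + 0.005 * analytic)
  expect_error(threshold_scatter(p, hob_cost_range = c(1e4, 1e4)),
               "degenerate")
})

test_that("no treatment effect makes incremental cost insensitive to HOB cost", {
  p <- base_params
  p$effect$hrr_treated <- 1
  p$effect$hrr_untreated <- 1
  p$effect$log_sd_treated <- 1e-9
  p$effect$log_sd_untreated <- 1e-9
  th <- threshold_scatter(p, td_adherence_values = 0.40, n_draws = 2000,
                          seed = 43)[[1]]
  # slope indistinguishable from zero at its own sampling noise
  slope_se <- summary(th$fit)$coefficients["x", "Std. Error"]
  expect_lt(abs(th$slope), 3 * slope_se)
  # and tiny relative to the base-case effect (~0.36 averted per 1000)
  expect_lt(abs(th$slope), 0.02)
})
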