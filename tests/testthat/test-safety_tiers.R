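test_that("root-sum-of-squares combination matches hand arithmetic", {
  expect_equal(combine_uncertainties(uncertainty_budget(0, 0, 0)), 0)
  expect_equal(combine_uncertainties(budget_body_t2()),
               sqrt(0.4096 + 0.1521 + 0.0144), tolerance = 1e-12)
  expect_equal(round(combine_uncertainties(budget_body_t2()), 4), 0.7590)
  expect_equal(round(combine_uncertainties(budget_body_t3()), 4), 0.8714)
  expect_error(uncertainty_budget(-0.1, 0.2, 0.1), ">= 0")
})

test_that("safety factor, buffer, corrected pSAR behave as defined", {
  expect_equal(safety_factor(0), 1)
  expect_equal(round(safety_factor(0.7590), 1), 1.8)
  expect_equal(round(safety_factor(0.8714), 1), 1.9)
  expect_error(safety_factor(-0.1), ">= 0")
  expect_equal(apply_buffer(1.8, 2, 2), 3.6)
  expect_equal(apply_buffer(1.9, 3, 2), 1.9)
  expect_equal(apply_buffer(1.4, 2, 2), 2.8)
  expect_equal(apply_buffer(1.5, 1, 2), 1.5)
  expect_error(apply_buffer(1.8, 2, 0.5), "buffer")
  expect_equal(corrected_psar(2.3, 1), 2.3)
  expect_equal(round(corrected_psar(2.3, 1.8 * 2), 1), 8.3)
  expect_equal(round(corrected_psar(2.3, 1.9), 1), 4.4)
  expect_error(corrected_psar(0, 2), "> 0")
})

test_that("power limits reproduce the published arithmetic", {
  # body tier 2: corrected 8.3 W/kg at 8 W reference -> 19.3 W / 2.4 W/ch
  lim <- power_limit(8.3, 20, 8, 8)
  expect_equal(round(lim$total, 1), 19.3)
  expect_equal(round(lim$per_channel, 1), 2.4)
  # body tier 3: corrected 4.4 -> 36.4 W / 4.5 W/ch
  lim3 <- power_limit(4.4, 20, 8, 8)
  expect_equal(round(lim3$total, 1), 36.4)
  expect_equal(round(lim3$per_channel, 1), 4.5)
  # fixed point: corrected == limit -> total == reference
  expect_equal(power_limit(20, 20, 8, 8)$total, 8)
  expect_error(power_limit(0, 20, 8, 8), "> 0")
})

test_that("tier-1 limits follow the all-power-in-10-g rule", {
  l <- tier1_limit(20, 8, 0.010)
  expect_equal(l$total, 0.2)
  expect_equal(l$per_channel, 0.025)
  expect_equal(l$implied_sar_1w_per_channel, 800)
  expect_equal(tier1_limit(20, 1, 0.010)$per_channel, 0.2)
})

test_that("multiplicative comparator matches and dominates RSS", {
  b <- budget_body_t3()
  expect_equal(round(multiplicative_safety_factor(b), 1), 2.8)
  expect_equal(multiplicative_safety_factor(uncertainty_budget(0, 0, 0)), 1)
  expect_equal(multiplicative_safety_factor(uncertainty_budget(0.5, 0, 0)),
               1.5)
  # property: 1 + RSS <= product(1 + terms), equality iff <= 1 nonzero term
  set.seed(37)
  for (rep in 1:200) {
    t3 <- stats::runif(3, 0, 1.5)
    bb <- uncertainty_budget(t3[1], t3[2], t3[3])
    expect_lte(safety_factor(combine_uncertainties(bb)),
               multiplicative_safety_factor(bb) + 1e-12)
  }
  one <- uncertainty_budget(0.4, 0, 0)
  expect_equal(safety_factor(combine_uncertainties(one)),
               multiplicative_safety_factor(one))
})

test_that("combined uncertainty is bracketed by max and sum of terms", {
  set.seed(41)
  for (rep in 1:100) {
    t3 <- stats::runif(3, 0, 1)
    u <- combine_uncertainties(uncertainty_budget(t3[1], t3[2], t3[3]))
    expect_gte(u, max(t3) - 1e-12)
    expect_lte(u, sum(t3) + 1e-12)
  }
})

test_that("tier_config enforces tier-specific requirements", {
  expect_error(tier_config(2), "psar_sim_mean")
  expect_error(tier_config(1, psar_sim_mean = 2.3), "tier 1")
  expect_error(tier_config(4), "tier")
  expect_error(tier_config(2, psar_sim_mean = 2.3, buffer = 0.5), "buffer")
  expect_error(run_tier_assessment(tier_config(2, psar_sim_mean = 2.3)),
               "budget")
  # tier 3 with B1-only modeling evidence is refused
  expect_error(
    run_tier_assessment(tier_config(3, psar_sim_mean = 2.3),
                        uncertainty_budget(0.64, 0.39, 0.12,
                                           modeling_source = "B1")),
    "tier 3")
})

test_that("full assessments reproduce the published table rows", {
  # body tier 2
  a2 <- run_tier_assessment(tier_config(2, psar_sim_mean = 2.3),
                            budget_body_t2())
  expect_equal(a2$safety_factor, 1.8)
  expect_equal(a2$final_safety_factor, 3.6)
  expect_equal(a2$corrected_psar, 8.3)
  expect_equal(a2$total_power_limit, 19.3)
  expect_equal(a2$per_channel_power_limit, 2.4)
  # body tier 3
  a3 <- run_tier_assessment(tier_config(3, psar_sim_mean = 2.3),
                            budget_body_t3())
  expect_equal(a3$safety_factor, 1.9)
  expect_equal(a3$corrected_psar, 4.4)
  expect_equal(a3$total_power_limit, 36.4)
  expect_equal(a3$per_channel_power_limit, 4.5)
  # head tier 2
  ah <- run_tier_assessment(tier_config(2, psar_sim_mean = 2.7),
                            budget_head_t2())
  expect_equal(ah$safety_factor, 1.4)
  expect_equal(ah$corrected_psar, 7.6)
  expect_equal(ah$total_power_limit, 21.1)
  expect_equal(ah$per_channel_power_limit, 2.6)
  # tier 1
  a1 <- run_tier_assessment(tier_config(1))
  expect_equal(a1$per_channel_power_limit, 0.025)
  expect_equal(a1$total_power_limit, 0.2)
  expect_equal(a1$implied_sar_1w_per_channel, 800)
})

test_that("paper-rounding and full-precision chains stay within 5%", {
  cases <- list(
    list(b = budget_body_t2(), psar = 2.3, tier = 2),
    list(b = budget_body_t3(), psar = 2.3, tier = 3),
    list(b = budget_head_t2(), psar = 2.7, tier = 2),
    list(b = uncertainty_budget(0.64, 0.77, 0.12), psar = 3.6, tier = 2))
  for (cs in cases) {
    ap <- run_tier_assessment(
      tier_config(cs$tier, psar_sim_mean = cs$psar, rounding_mode = "paper"),
      cs$b)
    af <- run_tier_assessment(
      tier_config(cs$tier, psar_sim_mean = cs$psar,
                  rounding_mode = "full_precision"), cs$b)
    for (fld in c("safety_factor", "corrected_psar", "total_power_limit",
                  "per_channel_power_limit"))
      expect_lt(abs(ap[[fld]] / af[[fld]] - 1), 0.05)
  }
})

test_that("assessment outputs are monotone in every budget term", {
  base <- c(0.3, 0.3, 0.1)
  run <- function(t3) run_tier_assessment(
    tier_config(2, psar_sim_mean = 2.5, rounding_mode = "full_precision"),
    uncertainty_budget(t3[1], t3[2], t3[3]))
  a0 <- run(base)
  for (k in 1:3) {
    up <- base; up[k] <- up[k] + 0.2
    ak <- run(up)
    expect_gt(ak$safety_factor, a0$safety_factor)
    expect_gt(ak$corrected_psar, a0$corrected_psar)
    expect_lt(ak$total_power_limit, a0$total_power_limit)
    expect_lt(ak$per_channel_power_limit, a0$per_channel_power_limit)
  }
})
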