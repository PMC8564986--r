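test_that("ICER handles ratios and the dominance quadrants", {
  r <- icer(8656833, 2466.14)
  expect_equal(r$status, "ratio")
  expect_equal(r$value, 8656833 / 2466.14)
  expect_equal(icer(0, 5)$value, 0)
  expect_equal(icer(-100, 5)$status, "dominant")
  expect_equal(icer(100, 0)$status, "dominated")
  expect_equal(icer(100, -2)$status, "dominated")
  expect_equal(icer(0, 0)$status, "undefined")
})

test_that("INMB is the net-benefit line and flips sign exactly at lambda = ICER", {
  expect_equal(inmb(2808.5, 2566.93, 8278038), -1068815.095, tolerance = 1e-3)
  expect_equal(inmb(0, 10, 500), -500)
  expect_equal(inmb(1000, 0, 0), 0)
  set.seed(4)
  for (i in 1:10) {
    cost <- runif(1, 1e5, 1e7)
    eff <- runif(1, 10, 5000)
    lambda <- cost / eff
    expect_equal(inmb(lambda, eff, cost), 0, tolerance = 1e-6)
    expect_gt(inmb(lambda * 1.001, eff, cost), 0)
    expect_lt(inmb(lambda * 0.999, eff, cost), 0)
  }
})

test_that("death-aversion metrics divide cost and cohort by deaths averted", {
  m <- death_aversion_metrics(100, 10, 1000)
  expect_equal(m$cost_per_death_averted, 100)
  expect_equal(m$number_screened_per_death_averted, 10)
  m0 <- death_aversion_metrics(100000, 0, 1000)
  expect_true(is.na(m0$cost_per_death_averted))
  expect_true(is.na(m0$number_screened_per_death_averted))
})

test_that("the verdict uses a strict threshold and is monotone in lambda", {
  expect_equal(classify(icer(8656833, 2466.14), 2808.5), "not_cost_effective")
  expect_equal(classify(icer(0, 5), 100), "cost_effective")
  expect_equal(classify(icer(100, 0), 1e9), "not_cost_effective")
  expect_equal(classify(icer(-1, 1), 1), "cost_effective")
  # exactly at the threshold: not cost-effective (strict inequality)
  expect_equal(classify(list(value = 100, status = "ratio"), 100),
               "not_cost_effective")
  # raising lambda can only flip towards cost-effective
  set.seed(9)
  for (i in 1:20) {
    ic <- icer(runif(1, -100, 1e6), runif(1, 0, 100))
    lams <- sort(runif(2, 1, 1e5))
    v <- vapply(lams, function(l) classify(ic, l), character(1))
    expect_false(v[1] == "cost_effective" && v[2] == "not_cost_effective")
  }
})

test_that("blending is affine in the private share and preserves health outcomes", {
  cfg <- baseline_scenario()
  gov <- run_policy_cea(cfg, "40-49", private_share = 0, policy_name = "gov")
  priv <- run_policy_cea(cfg, "40-49", private_share = 1, policy_name = "priv")
  expect_equal(blend_policies(gov, priv, 0)$incremental_cost, gov$incremental_cost)
  expect_equal(blend_policies(gov, priv, 1)$incremental_cost, priv$incremental_cost)
  shares <- c(0.1, 0.25, 0.5, 0.9)
  for (s in shares) {
    b <- blend_policies(gov, priv, s)
    expect_equal(b$incremental_cost,
                 s * priv$incremental_cost + (1 - s) * gov$incremental_cost)
    expect_equal(b$lyg, gov$lyg)
    expect_equal(b$deaths_averted, gov$deaths_averted)
    # blended ICER is affine in share because lyg is fixed
    expect_equal(b$icer, (s * priv$incremental_cost +
                            (1 - s) * gov$incremental_cost) / gov$lyg)
    # blending the unit price inside the engine gives the same answer
    direct <- run_policy_cea(cfg, "40-49", private_share = s)
    expect_equal(b$incremental_cost, direct$incremental_cost, tolerance = 1e-9)
  }
  g2 <- run_policy_cea(cfg, "50-59", private_share = 0)
  expect_error(blend_policies(g2, priv, 0.5), "age group")
})

test_that("every CEA result satisfies its internal ratio identities", {
  smp <- scenario_sampler(seed = 21, rel_width = 0.4)
  for (i in 1:5) {
    cfg <- random_scenario(smp, i)
    res <- run_policy_cea(cfg, "50-59", private_share = 0.3)
    if (res$icer_status == "ratio") {
      expect_equal(res$icer * res$lyg, res$incremental_cost,
                   tolerance = 1e-9)
    }
    if (res$deaths_averted > 0) {
      expect_equal(res$number_screened_per_death_averted,
                   cfg$cohort_size / res$deaths_averted, tolerance = 1e-9)
      expect_equal(res$cost_per_death_averted,
                   res$incremental_cost / res$deaths_averted, tolerance = 1e-9)
    }
    expect_equal(res$inmb, res$wtp * res$lyg - res$incremental_cost,
                 tolerance = 1e-9)
  }
})

test_that("the policy table has one row per policy x age group with consistent columns", {
  cfg <- baseline_scenario()
  pt <- policy_table(cfg)
  expect_equal(nrow(pt), 8)
  expect_setequal(unique(pt$policy),
                  c("government", "private", "mixed_50%_private",
                    "mixed_10%_private"))
  expect_setequal(unique(pt$age_group), c("40-49", "50-59"))
  expect_equal(pt$icer_usd_per_lyg, pt$incremental_cost_usd / pt$lyg)
  expect_true(all(pt$verdict %in% c("cost_effective", "not_cost_effective")))
  # screening at private prices always costs more: ICER increases with share
  for (ag in c("40-49", "50-59")) {
    sub <- pt[pt$age_group == ag, ]
    ord <- c("government", "mixed_10%_private", "mixed_50%_private", "private")
    expect_true(all(diff(sub$icer_usd_per_lyg[match(ord, sub$policy)]) > 0))
  }
  # equal prices collapse all policies onto one ICER
  cfg2 <- baseline_scenario()
  cfg2$costs$mammography_private <- cfg2$costs$mammography_gov
  pt2 <- policy_table(cfg2)
  for (ag in c("40-49", "50-59")) {
    expect_equal(diff(range(pt2$icer_usd_per_lyg[pt2$age_group == ag])), 0,
                 tolerance = 1e-9)
  }
})
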