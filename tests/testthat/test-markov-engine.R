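test_that("transition matrices carry the published rates with a residual diagonal", {
  cfg <- baseline_scenario()
  P <- build_transition_matrix(cfg$transitions[["I_40-49"]])
  expect_equal(unname(P["remission", ]),
               c(1 - 0.01 - 0.000016, 0.01, 0.000016, 0, 0))
  expect_equal(unname(P["cancer_death", ]), c(0, 0, 0, 1, 0))
  expect_equal(unname(P["other_death", ]), c(0, 0, 0, 0, 1))
  P4 <- build_transition_matrix(cfg$transitions[["IV_50-59"]])
  expect_equal(unname(P4["distant_recurrence", ]), c(0, 0, 1 - 0.423, 0.423, 0))
  # other-cause mortality loads the other-death column of every alive row
  Pm <- build_transition_matrix(cfg$transitions[["I_40-49"]], 0.01)
  expect_equal(unname(Pm[1:3, "other_death"]), rep(0.01, 3))
  expect_equal(rowSums(Pm), setNames(rep(1, 5), rownames(Pm)))
  # infeasible rows are named in the error
  bad <- cfg$transitions[["I_40-49"]]
  bad$p_dist_death <- 0.999
  expect_error(build_transition_matrix(bad, 0.01), "distant_recurrence")
})

test_that("built matrices are row-stochastic and progression-only across random scenarios", {
  smp <- scenario_sampler(seed = 3, rel_width = 0.5)
  for (i in 1:20) {
    cfg <- random_scenario(smp, i)
    for (key in names(cfg$transitions)) {
      P <- build_transition_matrix(cfg$transitions[[key]],
                                   cfg$other_cause_mortality)
      expect_true(all(abs(rowSums(P) - 1) < 1e-12))
      expect_true(all(P >= 0 & P <= 1))
      # no route back to remission from any recurrence state
      expect_equal(unname(P[2:5, "remission"]), rep(0, 4))
    }
  }
})

test_that("degenerate cohorts behave trivially (no disease, no progression)", {
  cfg <- baseline_scenario()
  cfg$horizon_cycles <- 1L
  cfg$age_groups[["40-49"]]$annual_incidence <- 0
  tr <- run_cohort(cfg, "screened", "40-49")
  expect_true(all(tr$occupancy == 0))
  expect_equal(unname(tr$cost_stream[1, ]),
               c(100000 * (4.5 + 6), 100000 * (1 - 0.859) * 22, 0))
  # self-loop matrices: cases accumulate but never die
  cfg2 <- baseline_scenario()
  for (key in names(cfg2$transitions)) {
    for (nm in c("p_rem_local", "p_rem_dist", "p_local_dist",
                 "p_local_death", "p_dist_death")) {
      cfg2$transitions[[key]][[nm]] <- 0
    }
  }
  tr2 <- run_cohort(cfg2, "screened", "40-49")
  expect_equal(tr2$deaths_cancer_cum, rep(0, 10))
})

test_that("cohort mass is conserved: occupancy equals cumulative enrollment per stage", {
  smp <- scenario_sampler(seed = 5, rel_width = 0.5)
  for (i in 1:10) {
    cfg <- random_scenario(smp, i)
    cfg$cohort_size <- 50000
    for (arm in c("screened", "non_screened")) {
      tr <- run_cohort(cfg, arm, sample(names(cfg$age_groups), 1))
      for (t in seq_len(tr$horizon_cycles)) {
        expect_equal(unname(rowSums(tr$occupancy[t, , ])),
                     unname(tr$enrolled_cum[t, ]), tolerance = 1e-9)
      }
      expect_true(all(diff(tr$deaths_cancer_cum) >= -1e-12))
    }
  }
})

test_that("raising a death probability never lowers cumulative cancer deaths", {
  cfg <- baseline_scenario()
  deaths <- function(cfg) {
    run_cohort(cfg, "non_screened", "40-49")$deaths_cancer_cum[10]
  }
  base <- deaths(cfg)
  for (path in c("transitions.II_III_40-49.p_dist_death",
                 "transitions.I_40-49.p_local_death",
                 "transitions.IV_40-49.p_dist_death")) {
    up <- scenario_set(cfg, path, min(1, scenario_get(cfg, path) + 0.2))
    expect_gte(deaths(up), base - 1e-12)
  }
})

test_that("discounting matches the closed-form annuity and its bounds", {
  stream <- rep(1050000, 10)
  # (sum of 1.05^-t, t = 0..9) x 1,050,000 = 8,513,212.76
  expect_equal(discounted_sum(stream, 0.05, "begin_of_cycle"),
               1050000 * (1 - 1.05^-10) / 0.05 * 1.05, tolerance = 1e-12)
  expect_equal(discounted_sum(stream, 0.05, "begin_of_cycle"), 8513212.76,
               tolerance = 1e-8)
  expect_equal(discounted_sum(stream, 0.05, "end_of_cycle"),
               discounted_sum(stream, 0.05, "begin_of_cycle") / 1.05)
  expect_equal(discounted_sum(stream, 0), sum(stream))
  expect_equal(discounted_sum(c(123.4), 0.07, "begin_of_cycle"), 123.4)
  # discounted <= undiscounted for non-negative streams, equality iff rate 0
  set.seed(2)
  for (i in 1:10) {
    s <- runif(8, 0, 100)
    r <- runif(1, 0.01, 0.2)
    expect_lt(discounted_sum(s, r), sum(s))
  }
})

test_that("deaths averted is the final-cycle difference and guards horizons", {
  cfg <- baseline_scenario()
  tr_s <- run_cohort(cfg, "screened", "40-49")
  tr_ns <- run_cohort(cfg, "non_screened", "40-49")
  expect_equal(deaths_averted(tr_s, tr_s), 0)
  expect_equal(deaths_averted(tr_s, tr_ns),
               tr_ns$deaths_cancer_cum[10] - tr_s$deaths_cancer_cum[10])
  expect_gt(deaths_averted(tr_s, tr_ns), 0)
  cfg2 <- cfg
  cfg2$horizon_cycles <- 5L
  expect_error(deaths_averted(tr_s, run_cohort(cfg2, "non_screened", "40-49")),
               "horizon")
})

test_that("life-years gained supports both calibrated and life-table valuation", {
  cfg <- baseline_scenario()
  ag <- cfg$age_groups[["40-49"]]
  expect_equal(life_years_gained(0, ag, cfg$discounts), 0)
  expect_equal(life_years_gained(0, ag, cfg$discounts, "life_table"), 0)
  # the calibrated multiplier is years per death averted
  expect_equal(life_years_gained(78.55, ag, cfg$discounts), 78.55 * 31.3958)
  # one remaining year, undiscounted: each death averted is worth one year
  toy_ag <- list(label = "x", remaining_life_years = c(a = 1),
                 lyg_per_death_averted = NA_real_)
  expect_equal(
    life_years_gained(10, toy_ag, list(effect_rate = 0), "life_table"), 10)
  expect_error(life_years_gained(1, toy_ag, cfg$discounts,
                                 "calibrated_multiplier"), "not set")
  # life-table mode discounts a unit annuity over the remaining expectancy
  L <- mean(ag$remaining_life_years)
  tt <- 0:(ceiling(L) - 1)
  expect_equal(life_years_gained(2, ag, cfg$discounts, "life_table"),
               2 * sum(pmin(1, L - tt) / 1.03^tt))
  expect_error(
    life_years_gained(1, cfg$age_groups[["50-59"]], cfg$discounts, "life_table"),
    "not available")
})

test_that("tidy trace export reshapes occupancy and costs without loss", {
  cfg <- toy_fixture()
  tr <- run_cohort(cfg, "screened", "40-49")
  dfs <- trace_to_df(tr)
  expect_equal(nrow(dfs$occupancy), 2 * 4 * 5)
  expect_equal(sum(dfs$occupancy$expected_count), sum(tr$occupancy))
  expect_equal(sum(dfs$costs$cost_usd), sum(tr$cost_stream))
})
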