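# Shared helpers for the suite. Fixtures are built in code; nothing is read
# from disk except the packaged baseline YAML.

# Expect |observed - expected| <= k Monte Carlo standard errors (with a tiny
# absolute floor so exact-zero cells with zero SE still compare).
expect_within_se <- function(observed, expected, se, k = 3, floor = 1e-9,
                             label = NULL) {
  expect_true(all(abs(observed - expected) <= k * pmax(se, floor) + floor),
              info = label)
}

# Cohort-engine expectations aggregated the same way the microsim reports:
# person-cycles per state (post-transition), final cumulative cancer deaths,
# total undiscounted cost.
cohort_aggregates <- function(trace) {
  list(
    state_person_cycles = apply(trace$occupancy, 3, sum),
    deaths = trace$deaths_cancer_cum[trace$horizon_cycles],
    total_cost = sum(trace$cost_stream)
  )
}

# Cohort expectation vs the mean of `reps` independent microsim replicates of
# n women each (seeds seed, seed + 1000, ...). A single-replicate z-statistic
# is poorly calibrated for states visited by few women: a low draw drags its
# own empirical SE down with it, inflating the left tail. Averaging replicates
# and pooling their variances restores the nominal 3-SE coverage; the SE of
# the replicate mean is sqrt(mean(se_r^2) / reps).
compare_cohort_vs_microsim <- function(config, arm, n, seed, age_group,
                                       reps = 3) {
  cfg <- config
  cfg$cohort_size <- n
  tr <- run_cohort(cfg, arm, age_group)
  agg <- cohort_aggregates(tr)
  runs <- lapply(seq_len(reps) - 1L, function(r) {
    microsim_cohort(cfg, arm, n, seed = seed + 1000 * r, age_group = age_group)
  })
  pool <- function(get_val, get_se) {
    vals <- sapply(runs, get_val)
    ses <- sapply(runs, get_se)
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
    if (is.null(dim(ses))) ses <- matrix(ses, nrow = 1)
    list(mean = rowMeans(vals), se = sqrt(rowMeans(ses^2) / reps))
  }
  pc <- pool(function(m) m$state_person_cycles,
             function(m) m$state_person_cycles_se)
  expect_within_se(pc$mean, agg$state_person_cycles, pc$se,
                   label = paste("person-cycles,", arm, age_group))
  de <- pool(function(m) m$deaths_cancer_cum[cfg$horizon_cycles],
             function(m) m$deaths_se)
  expect_within_se(de$mean, agg$deaths, de$se,
                   label = paste("deaths,", arm, age_group))
  co <- pool(function(m) m$total_cost, function(m) m$cost_se)
  expect_within_se(co$mean, agg$total_cost, co$se,
                   label = paste("cost,", arm, age_group))
}
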