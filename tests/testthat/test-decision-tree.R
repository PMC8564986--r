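test_that("screening outcomes follow the expected-value arithmetic of the tree", {
  # hand computation: 100000 x 0.000878 = 87.8 cancers;
  # 87.8 x 0.821 = 72.0838 TP; (100000 - 87.8) x (1 - 0.859) = 14087.62 FP
  det <- screening_cycle_outcomes(100000, 0.000878, 0.821, 0.859)
  expect_equal(det$new_cancers, 87.8)
  expect_equal(det$true_positives, 72.0838)
  expect_equal(det$false_negatives, 87.8 * 0.179)
  expect_equal(det$false_positives, (100000 - 87.8) * (1 - 0.859))
  expect_equal(det$false_positives, 14087.62, tolerance = 1e-6)
  # perfect test and zero incidence limits
  perf <- screening_cycle_outcomes(1000, 0.1, 1, 1)
  expect_equal(perf$false_negatives, 0)
  expect_equal(perf$false_positives, 0)
  none <- screening_cycle_outcomes(1000, 0, 0.8, 0.9)
  expect_equal(none$new_cancers, 0)
  expect_equal(none$true_positives, 0)
  expect_equal(none$false_negatives, 0)
})

test_that("the tree partitions the at-risk population exactly", {
  set.seed(11)
  for (i in 1:25) {
    at_risk <- runif(1, 0, 2e5)
    det <- screening_cycle_outcomes(at_risk, runif(1), runif(1), runif(1))
    total <- det$true_positives + det$false_negatives +
      det$false_positives + det$true_negatives
    expect_equal(total, at_risk, tolerance = 1e-9)
    expect_lte(det$false_positives, at_risk - det$new_cancers + 1e-9)
  }
})

test_that("stage allocation splits cases by detection mode and conserves totals", {
  cfg <- baseline_scenario()
  det <- screening_cycle_outcomes(100000, 0.000878, 0.821, 0.859)
  det <- allocate_diagnosis_stages(det, cfg$stage_distributions$screened,
                                   cfg$stage_distributions$non_screened)
  expect_equal(sum(det$diagnoses_by_stage), det$new_cancers, tolerance = 1e-9)
  expect_equal(det$diagnoses_by_stage["screen_detected", "I"],
               72.0838 * 0.521 / 1.001, tolerance = 1e-9)
  # point mass clinical distribution sends every false negative to stage IV
  pm <- c(I = 0, II = 0, III = 0, IV = 1)
  det2 <- allocate_diagnosis_stages(det, cfg$stage_distributions$screened, pm)
  expect_equal(det2$diagnoses_by_stage["clinical", "IV"], det$false_negatives)
  # zero cases allocate to zero everywhere
  det0 <- screening_cycle_outcomes(0, 0.5, 0.5, 0.5)
  det0 <- allocate_diagnosis_stages(det0, pm, pm)
  expect_true(all(det0$diagnoses_by_stage == 0))
  expect_error(allocate_diagnosis_stages(det, c(0.5, 0.2, 0.2, 0.2), pm),
               "not normalized")
})

test_that("cycle costs follow the published unit prices and flag semantics", {
  cfg <- baseline_scenario()
  det <- screening_cycle_outcomes(100000, 0.000878, 0.821, 0.859)
  det <- allocate_diagnosis_stages(det, cfg$stage_distributions$screened,
                                   cfg$stage_distributions$non_screened)
  cc <- cycle_costs(det, cfg$costs, "screened", mammography_unit_cost = 4.5)
  expect_equal(cc[["screening"]], 100000 * (4.5 + 6))
  expect_equal(cc[["diagnostic"]],
               (det$true_positives + det$false_positives) * 22)
  cc_nofp <- cycle_costs(det, cfg$costs, "screened", mammography_unit_cost = 4.5,
                         include_fp_workup = FALSE)
  expect_equal(cc_nofp[["diagnostic"]], det$true_positives * 22)
  # non-screened arm: no screening component; doctor + FNAC per diagnosis
  cc_ns <- cycle_costs(det, cfg$costs, "non_screened")
  expect_equal(cc_ns[["screening"]], 0)
  expect_equal(cc_ns[["diagnostic"]], det$new_cancers * (6 + 22))
  # zero detection in the non-screened arm costs nothing
  det0 <- screening_cycle_outcomes(0, 0, 1, 1)
  det0 <- allocate_diagnosis_stages(det0, cfg$stage_distributions$screened,
                                    cfg$stage_distributions$non_screened)
  expect_true(all(cycle_costs(det0, cfg$costs, "non_screened") == 0))
})

test_that("cost components are linear in counts and unit costs", {
  cfg <- baseline_scenario()
  mk <- function(at_risk) {
    det <- screening_cycle_outcomes(at_risk, 0.001, 0.8, 0.9)
    allocate_diagnosis_stages(det, cfg$stage_distributions$screened,
                              cfg$stage_distributions$non_screened)
  }
  c1 <- cycle_costs(mk(50000), cfg$costs, "screened", mammography_unit_cost = 4.5)
  c2 <- cycle_costs(mk(100000), cfg$costs, "screened", mammography_unit_cost = 4.5)
  expect_equal(2 * c1, c2, tolerance = 1e-9)
  costs2 <- cfg$costs
  costs2$fnac <- 44
  c3 <- cycle_costs(mk(50000), costs2, "screened", mammography_unit_cost = 4.5)
  expect_equal(c3[["diagnostic"]], 2 * c1[["diagnostic"]])
  expect_equal(c3[["screening"]], c1[["screening"]])
  expect_equal(c3[["treatment"]], c1[["treatment"]])
  # with a perfect test the diagnostic spend is exactly new_cancers x fnac
  detp <- mk(0)  # rebuild with perfect test below
  detp <- screening_cycle_outcomes(80000, 0.002, 1, 1)
  detp <- allocate_diagnosis_stages(detp, cfg$stage_distributions$screened,
                                    cfg$stage_distributions$non_screened)
  for (fp_flag in c(TRUE, FALSE)) {
    cp <- cycle_costs(detp, cfg$costs, "screened", mammography_unit_cost = 4.5,
                      include_fp_workup = fp_flag)
    expect_equal(cp[["diagnostic"]], detp$new_cancers * cfg$costs$fnac)
  }
})
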