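#' Build a 5-state per-cycle transition matrix for one stage group
#'
#' States are ordered (remission, local recurrence, distant recurrence,
#' cancer death, other-cause death). The structure is progression-only: no
#' recurrence state transitions back to remission, both death states are
#' absorbing, and unlisted transitions are zero. Other-cause mortality is
#' applied uniformly to the three alive states; the diagonal takes the
#' residual so every row sums to exactly 1.
#'
#' @param rates One element of a scenario's `transitions` list.
#' @param other_cause_mortality Per-cycle probability of death from other
#'   causes, applied to all alive states (default 0).
#' @return A 5x5 row-stochastic matrix with state dimnames and attributes
#'   `stage_group` and `age_group`.
#' @export
#' @examples
#' cfg <- baseline_scenario()
#' build_transition_matrix(cfg$transitions[["I_40-49"]])
build_transition_matrix <- function(rates, other_cause_mortality = 0) {
  stopifnot(other_cause_mortality >= 0, other_cause_mortality < 1)
  ocm <- other_cause_mortality
  P <- matrix(0, 5, 5, dimnames = list(.STATES, .STATES))

  rows <- list(
    remission = c(local_recurrence = rates$p_rem_local,
                  distant_recurrence = rates$p_rem_dist),
    local_recurrence = c(distant_recurrence = rates$p_local_dist,
                         cancer_death = rates$p_local_death),
    distant_recurrence = c(cancer_death = rates$p_dist_death)
  )
  for (from in names(rows)) {
    out <- rows[[from]]
    P[from, names(out)] <- out
    P[from, "other_death"] <- P[from, "other_death"] + ocm
    resid <- 1 - sum(P[from, ])
    if (resid < -1e-12) {
      stop(sprintf(
        "infeasible transition matrix (stage %s, age %s): row '%s' sums to %.6g > 1",
        rates$stage_group, rates$age_group, from, sum(P[from, ])))
    }
    P[from, from] <- max(resid, 0)
  }
  P["cancer_death", "cancer_death"] <- 1
  P["other_death", "other_death"] <- 1
  attr(P, "stage_group") <- rates$stage_group
  attr(P, "age_group") <- rates$age_group
  P
}

.stage_matrix_set <- function(config, age_group) {
  ocm <- config$other_cause_mortality
  key <- function(sg) paste(sg, age_group, sep = "_")
  pick <- function(sg) {
    tr <- config$transitions[[key(sg)]]
    if (is.null(tr)) stop("no transition rates for ", key(sg))
    build_transition_matrix(tr, ocm)
  }
  # stages II and III share one rate set but are tracked as separate cohorts
  list(I = pick("I"), II = pick("II_III"), III = pick("II_III"), IV = pick("IV"))
}

# initial Markov state at diagnosis: stages I-III start in remission after
# primary treatment; stage IV disease is metastatic at diagnosis and enters
# in the distant-recurrence state (the only state its rates are defined for)
.initial_state <- c(I = "remission", II = "remission",
                    III = "remission", IV = "distant_recurrence")

#' Run the Markov cohort simulation for one arm
#'
#' Iterates the annual cycles of the scenario horizon. Each cycle: (a) the
#' decision tree yields expected new diagnoses — via screening in the
#' screened arm, purely clinically in the non-screened arm; (b) new cases
#' enroll into their stage cohort's initial state; (c) every stage cohort
#' advances one step through its transition matrix; (d) undiscounted costs
#' and life-years accrue. Life-years count the alive-state occupancy of the
#' diagnosed cohorts at the start of each cycle (after enrollment, before
#' the transition). The at-risk pool is depleted by cumulative diagnoses
#' unless `flags$deplete_at_risk` is `FALSE`.
#'
#' @param config A validated `scenario_config`.
#' @param arm `"screened"` or `"non_screened"`.
#' @param age_group Age-band label present in `config$age_groups`.
#' @param mammography_unit_cost Unit price for the screened arm; defaults to
#'   the scenario policy's mix of government and private prices.
#' @return A `cohort_trace` list: per-cycle occupancy array
#'   (cycle x stage x state, measured after the cycle's transition),
#'   cost streams by component, cumulative cancer deaths, life-year stream,
#'   cumulative enrollment by stage, and per-cycle detection counts.
#' @export
run_cohort <- function(config, arm = c("screened", "non_screened"),
                       age_group = names(config$age_groups)[1],
                       mammography_unit_cost = NULL) {
  arm <- match.arg(arm)
  ag <- config$age_groups[[age_group]]
  if (is.null(ag)) stop("unknown age group: ", age_group)
  if (is.null(mammography_unit_cost)) {
    sh <- config$policy$private_share
    mammography_unit_cost <- (1 - sh) * config$costs$mammography_gov +
      sh * config$costs$mammography_private
  }

  H <- as.integer(config$horizon_cycles)
  cyc_len <- config$cycle_length_years
  P <- .stage_matrix_set(config, age_group)
  sd_s <- config$stage_distributions$screened
  sd_c <- config$stage_distributions$non_screened
  flags <- config$flags
  ocm <- config$other_cause_mortality

  occ <- matrix(0, 4, 5, dimnames = list(.STAGES, .STATES))
  occupancy <- array(0, dim = c(H, 4, 5),
                     dimnames = list(NULL, .STAGES, .STATES))
  cost_stream <- matrix(0, H, 3,
                        dimnames = list(NULL, c("screening", "diagnostic", "treatment")))
  enrolled_cum <- matrix(0, H, 4, dimnames = list(NULL, .STAGES))
  detect <- matrix(0, H, 5,
                   dimnames = list(NULL, c("n_screened", "new_cancers",
                                           "true_positives", "false_negatives",
                                           "false_positives")))
  life_years <- numeric(H)
  deaths_cum <- numeric(H)
  at_risk <- config$cohort_size
  at_risk_stream <- numeric(H)
  enrolled_total <- c(I = 0, II = 0, III = 0, IV = 0)

  for (t in seq_len(H)) {
    at_risk_stream[t] <- at_risk
    if (arm == "screened") {
      n_part <- at_risk * flags$participation_rate
      det <- screening_cycle_outcomes(n_part, ag$annual_incidence,
                                      ag$sensitivity, ag$specificity)
      det <- allocate_diagnosis_stages(det, sd_s, sd_c)
      extra_diag_cost <- 0
      if (flags$participation_rate < 1) {
        # non-participants present clinically, as in the non-screened arm
        np_cases <- at_risk * (1 - flags$participation_rate) * ag$annual_incidence
        det$diagnoses_by_stage["clinical", ] <-
          det$diagnoses_by_stage["clinical", ] + np_cases * as.numeric(sd_c)
        det$new_cancers <- det$new_cancers + np_cases
        extra_diag_cost <- np_cases * (config$costs$doctor_visit + config$costs$fnac)
      }
      cc <- cycle_costs(det, config$costs, "screened",
                        mammography_unit_cost = mammography_unit_cost,
                        include_fp_workup = flags$include_fp_workup,
                        doctor_visit_per = flags$doctor_visit_per)
      cc["diagnostic"] <- cc["diagnostic"] + extra_diag_cost
    } else {
      det <- screening_cycle_outcomes(at_risk, ag$annual_incidence, 0, 1)
      # no test: every case is clinically detected
      det$false_negatives <- det$new_cancers
      det$true_positives <- 0
      det <- allocate_diagnosis_stages(det, sd_s, sd_c)
      cc <- cycle_costs(det, config$costs, "non_screened")
    }
    detect[t, ] <- c(det$n_screened, det$new_cancers, det$true_positives,
                     det$false_negatives, det$false_positives)
    cost_stream[t, ] <- cc

    new_by_stage <- colSums(det$diagnoses_by_stage)
    enrolled_total <- enrolled_total + new_by_stage
    enrolled_cum[t, ] <- enrolled_total
    for (s in .STAGES) occ[s, .initial_state[[s]]] <- occ[s, .initial_state[[s]]] + new_by_stage[[s]]

    life_years[t] <- sum(occ[, 1:3]) * cyc_len

    for (s in .STAGES) occ[s, ] <- drop(occ[s, , drop = FALSE] %*% P[[s]])
    occupancy[t, , ] <- occ
    deaths_cum[t] <- sum(occ[, "cancer_death"])

    if (flags$deplete_at_risk) at_risk <- at_risk - det$new_cancers
    at_risk <- at_risk * (1 - ocm)
  }

  structure(list(
    arm = arm,
    age_group = age_group,
    horizon_cycles = H,
    cohort_size = config$cohort_size,
    mammography_unit_cost = mammography_unit_cost,
    occupancy = occupancy,
    cost_stream = cost_stream,
    detection = detect,
    enrolled_cum = enrolled_cum,
    life_year_stream = life_years,
    deaths_cancer_cum = deaths_cum,
    at_risk_stream = at_risk_stream
  ), class = "cohort_trace")
}

#' Discounted sum of a per-cycle stream
#'
#' Begin-of-cycle timing discounts cycle `t` (0-based) by `(1+rate)^-t`, so
#' the first cycle's payment is undiscounted; end-of-cycle timing uses
#' `(1+rate)^-(t+1)`. No half-cycle correction is applied.
#'
#' @param stream Numeric vector of per-cycle values.
#' @param rate Annual discount rate in `[0, 1)`.
#' @param timing `"begin_of_cycle"` (default) or `"end_of_cycle"`.
#' @return Scalar discounted sum.
#' @export
#' @examples
#' discounted_sum(rep(1050000, 10), 0.05)  # 10-cycle annuity at 5%
discounted_sum <- function(stream, rate,
                           timing = c("begin_of_cycle", "end_of_cycle")) {
  timing <- match.arg(timing)
  stopifnot(rate >= 0, rate < 1)
  t0 <- seq_along(stream) - 1L
  expo <- if (timing == "begin_of_cycle") t0 else t0 + 1L
  sum(stream / (1 + rate)^expo)
}

#' Total discounted cost of a cohort trace
#'
#' @param trace A `cohort_trace`.
#' @param discounts `list(cost_rate=, effect_rate=)` from the scenario.
#' @param timing Discount timing flag.
#' @return Scalar USD.
#' @export
total_discounted_cost <- function(trace, discounts,
                                  timing = "begin_of_cycle") {
  discounted_sum(rowSums(trace$cost_stream), discounts$cost_rate, timing)
}

#' Breast-cancer deaths averted by screening
#'
#' Difference in cumulative cancer deaths at the final cycle between the
#' non-screened and screened traces of the same scenario.
#'
#' @param trace_screened,trace_non_screened `cohort_trace` objects computed
#'   under identical configuration except the arm.
#' @return Expected count (positive when screening averts deaths).
#' @export
deaths_averted <- function(trace_screened, trace_non_screened) {
  if (trace_screened$horizon_cycles != trace_non_screened$horizon_cycles) {
    stop("traces have mismatched horizons")
  }
  last <- trace_screened$horizon_cycles
  trace_non_screened$deaths_cancer_cum[last] -
    trace_screened$deaths_cancer_cum[last]
}

#' Life-years gained from deaths averted
#'
#' Two modes. `calibrated_multiplier` (the default) multiplies deaths averted
#' by an age-band-specific years-per-death-averted factor; the baseline
#' multipliers (31.3958 for 40-49, 23.9052 for 50-59) are calibrated so the
#' downstream cost-effectiveness identities reproduce the reference results.
#' `life_table` values each death averted at the discounted annuity of the
#' band's remaining life expectancy (mean over the stored sub-bands) at the
#' effect discount rate: `sum_{t=0}^{ceil(L)-1} min(1, L - t) / (1+r)^t`.
#'
#' @param deaths_averted_value Expected deaths averted (>= 0).
#' @param age_params One element of a scenario's `age_groups`.
#' @param discounts Scenario `discounts` list (effect rate used).
#' @param mode `"calibrated_multiplier"` or `"life_table"`.
#' @return Life-years gained.
#' @export
life_years_gained <- function(deaths_averted_value, age_params, discounts,
                              mode = c("calibrated_multiplier", "life_table")) {
  mode <- match.arg(mode)
  stopifnot(deaths_averted_value >= 0)
  if (mode == "calibrated_multiplier") {
    m <- age_params$lyg_per_death_averted
    if (is.null(m) || is.na(m)) {
      stop("lyg_per_death_averted is not set for age group ", age_params$label)
    }
    return(deaths_averted_value * m)
  }
  L <- age_params$remaining_life_years
  if (length(L) == 0) {
    stop("remaining_life_years is not available for age group ", age_params$label)
  }
  L <- mean(L)
  r <- discounts$effect_rate
  tt <- 0:(ceiling(L) - 1L)
  annuity <- sum(pmin(1, L - tt) / (1 + r)^tt)
  deaths_averted_value * annuity
}

#' Tidy per-cycle export of a cohort trace
#'
#' One row per cycle x stage x state with the expected occupancy, suitable
#' for CSV export, plus per-cycle cost components in a second data frame.
#'
#' @param trace A `cohort_trace`.
#' @return A list of two data frames: `occupancy` and `costs`.
#' @export
trace_to_df <- function(trace) {
  H <- trace$horizon_cycles
  occ <- expand.grid(cycle = seq_len(H) - 1L, stage = .STAGES,
                     state = .STATES, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  occ$arm <- trace$arm
  occ$expected_count <- as.vector(trace$occupancy)
  costs <- data.frame(
    cycle = rep(seq_len(H) - 1L, times = 3),
    arm = trace$arm,
    component = rep(colnames(trace$cost_stream), each = H),
    cost_usd = as.vector(trace$cost_stream)
  )
  list(occupancy = occ, costs = costs)
}
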