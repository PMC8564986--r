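#' Random-scenario sampler for property testing
#'
#' Emits valid scenarios whose numeric parameters are scaled by independent
#' uniform factors in `1 +/- rel_width` around the packaged baseline
#' (probabilities truncated at 1, stage-distribution weights renormalized,
#' row-sum feasibility enforced by rejection). `rel_width = 0` collapses the
#' sampler onto the baseline exactly.
#'
#' @param seed Integer seed.
#' @param rel_width Relative half-width of the sampling band (default 0.5).
#' @return A `scenario_sampler` list.
#' @export
scenario_sampler <- function(seed = 1, rel_width = 0.5) {
  stopifnot(rel_width >= 0, rel_width < 1)
  structure(list(seed = as.integer(seed), rel_width = rel_width),
            class = "scenario_sampler")
}

#' Draw one random valid scenario
#'
#' Reproducible given `(sampler$seed, draw_index)`; every returned scenario
#' passes [validate_scenario()] with zero violations.
#'
#' @param sampler A [scenario_sampler()].
#' @param draw_index 1-based draw counter.
#' @param max_retries Rejection budget for infeasible transition draws.
#' @return A `scenario_config`.
#' @export
random_scenario <- function(sampler, draw_index = 1, max_retries = 100L) {
  base <- baseline_scenario()
  w <- sampler$rel_width
  set.seed(.draw_seed(sampler$seed, draw_index))
  fac <- function() stats::runif(1, 1 - w, 1 + w)
  prob <- function(p) min(p * fac(), 1)

  for (attempt in seq_len(max_retries)) {
    cfg <- base
    for (ag in names(cfg$age_groups)) {
      g <- cfg$age_groups[[ag]]
      g$annual_incidence <- prob(g$annual_incidence)
      g$sensitivity <- prob(g$sensitivity)
      g$specificity <- prob(g$specificity)
      if (!is.na(g$lyg_per_death_averted)) {
        g$lyg_per_death_averted <- g$lyg_per_death_averted * fac()
      }
      cfg$age_groups[[ag]] <- g
    }
    for (key in names(cfg$transitions)) {
      tr <- cfg$transitions[[key]]
      for (nm in c("p_rem_local", "p_rem_dist", "p_local_dist",
                   "p_local_death", "p_dist_death")) {
        tr[[nm]] <- prob(tr[[nm]])
      }
      cfg$transitions[[key]] <- tr
    }
    for (nm in c("mammography_gov", "mammography_private", "doctor_visit", "fnac")) {
      cfg$costs[[nm]] <- cfg$costs[[nm]] * fac()
    }
    cfg$costs$treatment_by_stage <- vapply(
      cfg$costs$treatment_by_stage, function(x) x * fac(), numeric(1))
    for (arm in c("screened", "non_screened")) {
      wts <- vapply(cfg$stage_distributions[[arm]], function(x) x * fac(),
                    numeric(1))
      cfg$stage_distributions[[arm]] <- wts / sum(wts)
    }
    cfg$discounts$cost_rate <- min(cfg$discounts$cost_rate * fac(), 0.99)
    cfg$discounts$effect_rate <- min(cfg$discounts$effect_rate * fac(), 0.99)
    if (length(validate_scenario(cfg)) == 0) return(cfg)
  }
  stop("no valid scenario after ", max_retries, " retries")
}

#' Individual-level microsimulation (brute-force oracle)
#'
#' Simulates each woman independently through the screening decision tree and
#' the stage-stratified Markov chain with per-individual Bernoulli and
#' categorical draws, using the same stage distributions, costing rules, and
#' transition ordering as the deterministic cohort engine — so any divergence
#' beyond Monte Carlo noise isolates an engine bug, not a modelling
#' difference. It is a test oracle, not a performance-oriented simulator.
#'
#' @param config A validated `scenario_config`.
#' @param arm `"screened"` or `"non_screened"`.
#' @param n_individuals Number of simulated women.
#' @param seed Integer seed.
#' @param age_group Age band to simulate.
#' @return A `microsim_result` list: `n_individuals`, empirical `occupancy`
#'   counts (cycle x stage x state, post-transition, matching the cohort
#'   trace), cumulative cancer `deaths_cancer_cum` with standard error
#'   `deaths_se`, total undiscounted `total_cost` with `cost_se`, per-state
#'   person-cycle totals `state_person_cycles` with
#'   `state_person_cycles_se` (standard errors of the totals, computed from
#'   the per-individual spread).
#' @export
microsim_cohort <- function(config, arm = c("screened", "non_screened"),
                            n_individuals, seed = 1,
                            age_group = names(config$age_groups)[1]) {
  arm <- match.arg(arm)
  stopifnot(n_individuals >= 1)
  n <- as.integer(n_individuals)
  ag <- config$age_groups[[age_group]]
  H <- as.integer(config$horizon_cycles)
  P <- .stage_matrix_set(config, age_group)
  sd_s <- as.numeric(config$stage_distributions$screened)
  sd_c <- as.numeric(config$stage_distributions$non_screened)
  flags <- config$flags
  costs <- config$costs
  ocm <- config$other_cause_mortality
  sh <- config$policy$private_share
  mammo_unit <- (1 - sh) * costs$mammography_gov + sh * costs$mammography_private

  set.seed(.draw_seed(seed, 0L))
  # status: 0 at-risk, 1 remission, 2 local, 3 distant, 4 cancer death,
  #         5 other death (diagnosed), -1 other death while at risk
  status <- integer(n)
  stage <- integer(n)
  cost <- numeric(n)
  person_cycles <- matrix(0, n, 5)  # post-transition state occupancy tallies

  occupancy <- array(0L, dim = c(H, 4, 5),
                     dimnames = list(NULL, .STAGES, .STATES))
  deaths_cum <- numeric(H)

  draw_stage <- function(k, p) {
    if (k == 0) integer(0) else sample.int(4, k, replace = TRUE, prob = p)
  }

  for (t in seq_len(H)) {
    risk <- which(status == 0L)
    if (length(risk) > 0) {
      if (arm == "screened") {
        part <- risk[stats::runif(length(risk)) < flags$participation_rate]
        nonpart <- setdiff(risk, part)
        cost[part] <- cost[part] + mammo_unit +
          if (flags$doctor_visit_per == "screen") costs$doctor_visit else 0
        has_ca <- stats::runif(length(part)) < ag$annual_incidence
        ca <- part[has_ca]
        healthy <- part[!has_ca]
        pos_test <- stats::runif(length(ca)) < ag$sensitivity
        tp <- ca[pos_test]
        fn <- ca[!pos_test]
        fp <- healthy[stats::runif(length(healthy)) < (1 - ag$specificity)]
        if (flags$doctor_visit_per == "positive") {
          pos <- c(tp, fp)
          cost[pos] <- cost[pos] + costs$doctor_visit
        }
        cost[tp] <- cost[tp] + costs$fnac
        if (flags$include_fp_workup) cost[fp] <- cost[fp] + costs$fnac
        stage[tp] <- draw_stage(length(tp), sd_s)
        stage[fn] <- draw_stage(length(fn), sd_c)
        np_ca <- nonpart[stats::runif(length(nonpart)) < ag$annual_incidence]
        stage[np_ca] <- draw_stage(length(np_ca), sd_c)
        cost[np_ca] <- cost[np_ca] + costs$doctor_visit + costs$fnac
        new_diag <- c(tp, fn, np_ca)
      } else {
        new_diag <- risk[stats::runif(length(risk)) < ag$annual_incidence]
        stage[new_diag] <- draw_stage(length(new_diag), sd_c)
        cost[new_diag] <- cost[new_diag] + costs$doctor_visit + costs$fnac
      }
      cost[new_diag] <- cost[new_diag] +
        costs$treatment_by_stage[stage[new_diag]]
      status[new_diag] <- ifelse(stage[new_diag] == 4L, 3L, 1L)
    }

    pre <- status  # snapshot: everyone takes exactly one step per cycle
    for (s in 1:4) {
      Ps <- P[[s]]
      for (from in 1:3) {
        idx <- which(stage == s & pre == from)
        if (length(idx) > 0) {
          status[idx] <- sample.int(5, length(idx), replace = TRUE,
                                    prob = Ps[from, ])
        }
      }
    }
    if (ocm > 0) {
      risk <- which(status == 0L)
      dead <- risk[stats::runif(length(risk)) < ocm]
      status[dead] <- -1L
    }

    diag_alive_or_dead <- which(status > 0L)
    if (length(diag_alive_or_dead) > 0) {
      tab <- table(factor(stage[diag_alive_or_dead], levels = 1:4),
                   factor(status[diag_alive_or_dead], levels = 1:5))
      occupancy[t, , ] <- as.integer(tab)
      pc_idx <- cbind(diag_alive_or_dead, status[diag_alive_or_dead])
      person_cycles[pc_idx] <- person_cycles[pc_idx] + 1
    }
    deaths_cum[t] <- sum(status == 4L)
  }

  pc_tot <- colSums(person_cycles)
  pc_se <- apply(person_cycles, 2, stats::sd) * sqrt(n)
  p_death <- deaths_cum[H] / n
  structure(list(
    n_individuals = n,
    arm = arm,
    age_group = age_group,
    occupancy = occupancy,
    deaths_cancer_cum = deaths_cum,
    deaths_se = sqrt(n * p_death * (1 - p_death)),
    total_cost = sum(cost),
    cost_se = stats::sd(cost) * sqrt(n),
    state_person_cycles = stats::setNames(pc_tot, .STATES),
    state_person_cycles_se = stats::setNames(pc_se, .STATES)
  ), class = "microsim_result")
}

#' Deliberately tiny scenario with closed-form expectations
#'
#' One effective stage (point mass on stage I), two annual cycles, a cohort
#' of 100, incidence 0.1, sensitivity 0.5, perfect specificity, zero costs,
#' zero discounting, and a two-step death path (remission -> distant with
#' probability 0.5, distant -> cancer death with probability 1). Every
#' expectation has a closed form that the cohort engine must hit exactly:
#' e.g. 5 expected screen-detected cancers in the first cycle, and half of
#' each diagnosed cohort dead two transitions after diagnosis.
#'
#' @return A validated `scenario_config`.
#' @export
toy_fixture <- function() {
  cfg <- baseline_scenario()
  cfg$cohort_size <- 100
  cfg$horizon_cycles <- 2L
  cfg$wtp_threshold <- 1000
  cfg$discounts <- list(cost_rate = 0, effect_rate = 0)
  cfg$costs <- list(mammography_gov = 0, mammography_private = 0,
                    doctor_visit = 0, fnac = 0,
                    treatment_by_stage = c(I = 0, II = 0, III = 0, IV = 0))
  cfg$age_groups <- list("40-49" = list(
    label = "40-49", annual_incidence = 0.1, sensitivity = 0.5,
    specificity = 1, remaining_life_years = c("40-44" = 1),
    lyg_per_death_averted = 1))
  zero <- function(sg) list(stage_group = sg, age_group = "40-49",
                            p_rem_local = 0, p_rem_dist = 0, p_local_dist = 0,
                            p_local_death = 0, p_dist_death = 0)
  toy_I <- zero("I")
  toy_I$p_rem_dist <- 0.5
  toy_I$p_dist_death <- 1
  cfg$transitions <- list("I_40-49" = toy_I,
                          "II_III_40-49" = zero("II_III"),
                          "IV_40-49" = zero("IV"))
  pm <- c(I = 1, II = 0, III = 0, IV = 0)
  cfg$stage_distributions <- list(screened = pm, non_screened = pm)
  stopifnot(length(validate_scenario(cfg)) == 0)
  cfg
}
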