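#' Incremental cost-effectiveness ratio
#'
#' Returns the ratio together with a dominance status: `"ratio"` for a
#' positive effect bought at non-negative cost, `"dominant"` when the
#' intervention saves money and gains life-years, `"dominated"` when it costs
#' more and gains nothing, `"undefined"` when both increments are ~0.
#'
#' @param incremental_cost USD.
#' @param incremental_effect Life-years.
#' @param eps Magnitude below which an increment counts as zero.
#' @return `list(value =, status =)`; `value` is `NA` except for `"ratio"`.
#' @export
#' @examples
#' icer(8656833, 2466.14)  # 3510.28 USD per life-year gained
icer <- function(incremental_cost, incremental_effect, eps = 1e-9) {
  if (abs(incremental_cost) < eps && abs(incremental_effect) < eps) {
    return(list(value = NA_real_, status = "undefined"))
  }
  if (incremental_effect > eps && incremental_cost < -eps) {
    return(list(value = NA_real_, status = "dominant"))
  }
  if (incremental_effect <= eps && incremental_cost > eps) {
    return(list(value = NA_real_, status = "dominated"))
  }
  if (incremental_effect > eps) {
    return(list(value = incremental_cost / incremental_effect, status = "ratio"))
  }
  list(value = NA_real_, status = "undefined")
}

#' Incremental net monetary benefit
#'
#' `wtp * incremental_effect - incremental_cost`; positive iff the
#' intervention is cost-effective at willingness-to-pay `wtp`.
#'
#' @param wtp Willingness-to-pay in USD per life-year (>= 0).
#' @param incremental_effect Life-years.
#' @param incremental_cost USD.
#' @return USD.
#' @export
inmb <- function(wtp, incremental_effect, incremental_cost) {
  stopifnot(wtp >= 0)
  wtp * incremental_effect - incremental_cost
}

#' Cost per death averted and number screened per death averted
#'
#' @param cohort_size Women in the cohort (> 0).
#' @param deaths_averted Expected deaths averted.
#' @param incremental_cost USD.
#' @return `list(cost_per_death_averted =, number_screened_per_death_averted =)`,
#'   both `NA` when no deaths are averted.
#' @export
death_aversion_metrics <- function(cohort_size, deaths_averted, incremental_cost) {
  stopifnot(cohort_size > 0)
  if (deaths_averted <= 0) {
    return(list(cost_per_death_averted = NA_real_,
                number_screened_per_death_averted = NA_real_))
  }
  list(cost_per_death_averted = incremental_cost / deaths_averted,
       number_screened_per_death_averted = cohort_size / deaths_averted)
}

#' Cost-effectiveness verdict against a willingness-to-pay threshold
#'
#' Strict inequality: an ICER exactly at the threshold is not cost-effective
#' (the convention is "less than three times GDP per capita").
#'
#' @param icer_result A list from [icer()].
#' @param wtp Willingness-to-pay threshold (> 0).
#' @return `"cost_effective"` or `"not_cost_effective"`.
#' @export
classify <- function(icer_result, wtp) {
  stopifnot(wtp > 0)
  switch(icer_result$status,
    dominant = "cost_effective",
    dominated = "not_cost_effective",
    undefined = "not_cost_effective",
    ratio = if (icer_result$value < wtp) "cost_effective" else "not_cost_effective"
  )
}

.new_cea_result <- function(policy_name, private_share, age_group,
                            incremental_cost, lyg, deaths_averted_value,
                            cohort_size, wtp) {
  ic <- icer(incremental_cost, lyg)
  dm <- death_aversion_metrics(cohort_size, deaths_averted_value, incremental_cost)
  structure(list(
    policy = policy_name,
    private_share = private_share,
    age_group = age_group,
    cohort_size = cohort_size,
    incremental_cost = incremental_cost,
    lyg = lyg,
    deaths_averted = deaths_averted_value,
    icer = ic$value,
    icer_status = ic$status,
    inmb = inmb(wtp, lyg, incremental_cost),
    wtp = wtp,
    cost_per_death_averted = dm$cost_per_death_averted,
    number_screened_per_death_averted = dm$number_screened_per_death_averted,
    verdict = classify(ic, wtp)
  ), class = "cea_result")
}

#' Full cost-effectiveness evaluation of one policy for one age group
#'
#' Runs the screened and non-screened arms, discounts both cost streams,
#' takes the incremental cost (screened minus non-screened), converts deaths
#' averted to life-years gained per the scenario's `lyg_mode`, and assembles
#' every summary metric. The mammography unit price is the policy's blend of
#' government and private prices; since all costs are linear in the unit
#' price this is algebraically identical to blending two pure-policy runs.
#'
#' @param config A validated `scenario_config`.
#' @param age_group Age-band label.
#' @param private_share Proportion of screens at private institutions
#'   (default: the scenario policy's value).
#' @param policy_name Label for the output row.
#' @return A `cea_result` list.
#' @export
run_policy_cea <- function(config, age_group,
                           private_share = config$policy$private_share,
                           policy_name = config$policy$name) {
  unit <- (1 - private_share) * config$costs$mammography_gov +
    private_share * config$costs$mammography_private
  tr_s <- run_cohort(config, "screened", age_group,
                     mammography_unit_cost = unit)
  tr_ns <- run_cohort(config, "non_screened", age_group)
  timing <- config$flags$discount_timing
  inc_cost <- total_discounted_cost(tr_s, config$discounts, timing) -
    total_discounted_cost(tr_ns, config$discounts, timing)
  da <- deaths_averted(tr_s, tr_ns)
  lyg <- life_years_gained(max(da, 0), config$age_groups[[age_group]],
                           config$discounts, config$flags$lyg_mode)
  .new_cea_result(policy_name, private_share, age_group,
                  inc_cost, lyg, da, config$cohort_size, config$wtp_threshold)
}

#' Blend two pure-policy results into a mixed provider policy
#'
#' Mammography price is the only difference between provider tiers, so a mix
#' with private share `s` has incremental cost
#' `s * private + (1 - s) * government`; health outcomes (life-years, deaths
#' averted) are price-invariant and carried over unchanged. All ratios are
#' recomputed from the blended cost.
#'
#' @param result_gov,result_private `cea_result` objects from the same
#'   scenario at government and private prices.
#' @param private_share Proportion in `[0, 1]`.
#' @param policy_name Label for the blended row.
#' @return A `cea_result`.
#' @export
blend_policies <- function(result_gov, result_private, private_share,
                           policy_name = sprintf("mixed_%g%%_private",
                                                 100 * private_share)) {
  stopifnot(private_share >= 0, private_share <= 1)
  if (result_gov$age_group != result_private$age_group) {
    stop("cannot blend results for different age groups")
  }
  if (result_gov$cohort_size != result_private$cohort_size) {
    stop("cannot blend results with different cohort sizes")
  }
  if (abs(result_gov$lyg - result_private$lyg) > 1e-6 ||
      abs(result_gov$deaths_averted - result_private$deaths_averted) > 1e-9) {
    stop("pure-policy results disagree on health outcomes; not the same scenario")
  }
  inc_cost <- private_share * result_private$incremental_cost +
    (1 - private_share) * result_gov$incremental_cost
  .new_cea_result(policy_name, private_share, result_gov$age_group,
                  inc_cost, result_gov$lyg, result_gov$deaths_averted,
                  result_gov$cohort_size, result_gov$wtp)
}

.canonical_policies <- function() {
  data.frame(
    name = c("government", "private", "mixed_50%_private", "mixed_10%_private"),
    private_share = c(0, 1, 0.5, 0.1),
    stringsAsFactors = FALSE
  )
}

#' Policy comparison table across provider mixes and age groups
#'
#' Runs both arms per age group at the two pure prices, blends intermediate
#' provider mixes from the pure runs, and returns one row per
#' policy x age group.
#'
#' @param config A validated `scenario_config`.
#' @param policies Data frame with columns `name` and `private_share`
#'   (default: government-only, private-only, 50/50 and 90/10 mixes).
#' @param age_groups Age-band labels (default: all in the scenario).
#' @return Data frame with columns `policy`, `age_group`,
#'   `incremental_cost_usd`, `lyg`, `icer_usd_per_lyg`, `inmb_usd`,
#'   `cost_per_death_averted_usd`, `number_screened_per_death_averted`,
#'   `deaths_averted`, `verdict`.
#' @export
policy_table <- function(config, policies = .canonical_policies(),
                         age_groups = names(config$age_groups)) {
  rows <- list()
  for (ag in age_groups) {
    gov <- run_policy_cea(config, ag, private_share = 0, policy_name = "government")
    priv <- run_policy_cea(config, ag, private_share = 1, policy_name = "private")
    for (i in seq_len(nrow(policies))) {
      sh <- policies$private_share[i]
      res <- if (sh == 0) gov
        else if (sh == 1) priv
        else blend_policies(gov, priv, sh, policy_name = policies$name[i])
      res$policy <- policies$name[i]
      rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind, lapply(rows, function(r) {
    data.frame(
      policy = r$policy,
      age_group = r$age_group,
      incremental_cost_usd = r$incremental_cost,
      lyg = r$lyg,
      icer_usd_per_lyg = r$icer,
      inmb_usd = r$inmb,
      cost_per_death_averted_usd = r$cost_per_death_averted,
      number_screened_per_death_averted = r$number_screened_per_death_averted,
      deaths_averted = r$deaths_averted,
      verdict = r$verdict,
      stringsAsFactors = FALSE
    )
  }))
}
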