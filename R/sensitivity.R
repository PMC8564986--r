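#' One-way sensitivity range for a parameter
#'
#' Costs and probabilities get +/-20% around the base value, with
#' probabilities capped at 1 (a perturbed sensitivity of 110% is read as a
#' perfect test, not discarded). Discount rates use the conventional 0%-6%
#' policy range instead of a relative band.
#'
#' @param base Base-case value.
#' @param kind `"probability"`, `"cost"` or `"discount_rate"`.
#' @return `c(low, high)`.
#' @export
#' @examples
#' owsa_range(4.5, "cost")          # 3.6 .. 5.4
#' owsa_range(0.921, "probability") # 0.7368 .. 1
#' owsa_range(0.05, "discount_rate")# 0 .. 0.06
owsa_range <- function(base, kind = c("probability", "cost", "discount_rate")) {
  kind <- match.arg(kind)
  if (kind == "discount_rate") return(c(low = 0, high = 0.06))
  low <- 0.8 * base
  high <- 1.2 * base
  if (kind == "probability") high <- min(high, 1)
  c(low = low, high = high)
}

#' Enumerate the scenario parameters varied in sensitivity analyses
#'
#' One row per scalar parameter with its dotted path, its kind (probability /
#' cost / discount_rate), and the distribution family used in probabilistic
#' sensitivity analysis (Beta for probabilities, Gamma for costs and
#' life-year multipliers, fixed for discount rates; stage distributions are
#' handled separately as Dirichlet blocks).
#'
#' @param config A `scenario_config`.
#' @param age_group Age band whose parameters are enumerated.
#' @return Data frame with columns `parameter`, `kind`, `family`, `base`.
#' @export
sensitivity_parameters <- function(config, age_group) {
  rows <- list()
  add <- function(path, kind, family) {
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = path, kind = kind, family = family,
      base = as.numeric(scenario_get(config, path)),
      stringsAsFactors = FALSE)
  }
  agp <- paste0("age_groups.", age_group, ".")
  add(paste0(agp, "annual_incidence"), "probability", "beta")
  add(paste0(agp, "sensitivity"), "probability", "beta")
  add(paste0(agp, "specificity"), "probability", "beta")
  if (!is.na(config$age_groups[[age_group]]$lyg_per_death_averted)) {
    add(paste0(agp, "lyg_per_death_averted"), "cost", "gamma")
  }
  for (sg in .STAGE_GROUPS) {
    key <- paste(sg, age_group, sep = "_")
    tr <- config$transitions[[key]]
    for (nm in c("p_rem_local", "p_rem_dist", "p_local_dist",
                 "p_local_death", "p_dist_death")) {
      if (tr[[nm]] > 0) {
        add(paste0("transitions.", key, ".", nm), "probability", "beta")
      }
    }
  }
  for (nm in c("mammography_gov", "mammography_private", "doctor_visit", "fnac")) {
    add(paste0("costs.", nm), "cost", "gamma")
  }
  for (s in .STAGES) {
    add(paste0("costs.treatment_by_stage.", s), "cost", "gamma")
  }
  add("discounts.cost_rate", "discount_rate", "fixed")
  add("discounts.effect_rate", "discount_rate", "fixed")
  do.call(rbind, rows)
}

#' One-way (tornado) sensitivity analysis on the ICER
#'
#' Re-runs the full pipeline twice per parameter — once at the low and once
#' at the high end of its [owsa_range()] — holding everything else at base,
#' and reports the ICER span. All parameters are reported (zero-span rows
#' included); sorting by descending span gives the tornado ordering.
#'
#' @param config A validated `scenario_config`.
#' @param age_group Age band to analyse.
#' @param private_share Provider mix of the policy under analysis
#'   (default: the scenario policy's).
#' @param params Parameter table from [sensitivity_parameters()].
#' @return Data frame sorted by descending `span` with columns `parameter`,
#'   `kind`, `base_value`, `low_value`, `high_value`, `icer_at_low`,
#'   `icer_at_high`, `span`, plus the base-case ICER as attribute
#'   `base_icer`.
#' @export
run_owsa <- function(config, age_group,
                     private_share = config$policy$private_share,
                     params = sensitivity_parameters(config, age_group)) {
  icer_of <- function(cfg) {
    run_policy_cea(cfg, age_group, private_share = private_share)$icer
  }
  base_icer <- icer_of(config)
  out <- params
  out$base_value <- out$base
  out$base <- NULL
  out$family <- NULL
  out$low_value <- NA_real_
  out$high_value <- NA_real_
  out$icer_at_low <- NA_real_
  out$icer_at_high <- NA_real_
  for (i in seq_len(nrow(out))) {
    rng <- owsa_range(out$base_value[i], out$kind[i])
    out$low_value[i] <- rng[["low"]]
    out$high_value[i] <- rng[["high"]]
    out$icer_at_low[i] <- icer_of(scenario_set(config, out$parameter[i], rng[["low"]]))
    out$icer_at_high[i] <- icer_of(scenario_set(config, out$parameter[i], rng[["high"]]))
  }
  # composite screening-visit price: the mammography unit price and the
  # doctor-visit fee form one out-of-pocket price per screen and move
  # together in a price-policy change, so the tornado also carries a bar
  # varying them jointly
  unit_base <- (1 - private_share) * config$costs$mammography_gov +
    private_share * config$costs$mammography_private
  comp_base <- unit_base + config$costs$doctor_visit
  scale_visit <- function(f) {
    cfg <- config
    cfg$costs$mammography_gov <- cfg$costs$mammography_gov * f
    cfg$costs$mammography_private <- cfg$costs$mammography_private * f
    cfg$costs$doctor_visit <- cfg$costs$doctor_visit * f
    cfg
  }
  out <- rbind(out, data.frame(
    parameter = "costs.screening_visit_price", kind = "cost",
    base_value = comp_base,
    low_value = 0.8 * comp_base, high_value = 1.2 * comp_base,
    icer_at_low = icer_of(scale_visit(0.8)),
    icer_at_high = icer_of(scale_visit(1.2)),
    stringsAsFactors = FALSE))
  out$span <- abs(out$icer_at_high - out$icer_at_low)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  out
}

# -- probabilistic sensitivity analysis ---------------------------------------

#' Configuration for second-order Monte Carlo sensitivity analysis
#'
#' The dispersion of the parameter distributions is an analyst choice; the
#' default coefficient of variation is 0.1 per parameter and the Dirichlet
#' concentration for stage distributions is 100 x the base proportions.
#' Per-parameter overrides can pin a parameter (`family = "fixed"`) or change
#' its CV.
#'
#' @param iterations Monte Carlo iterations (default 10000).
#' @param seed Integer seed; together with the draw index it fully
#'   determines every draw.
#' @param cv Default coefficient of variation for Beta/Gamma parameters.
#' @param dirichlet_concentration Total concentration multiplier for stage
#'   distributions. By default it is slaved to `cv` as `100 * (0.1 / cv)^2`
#'   (100 at the default CV, growing as CV shrinks), so a single dispersion
#'   dial drives every family and the CV -> 0 limit degenerates all of them.
#' @param overrides Named list keyed by parameter path, each a list with
#'   optional `family` and `cv`.
#' @return A `psa_config` list.
#' @export
psa_config <- function(iterations = 10000, seed = 1, cv = 0.1,
                       dirichlet_concentration = NULL, overrides = list()) {
  if (is.null(dirichlet_concentration)) {
    dirichlet_concentration <- 100 * (0.1 / cv)^2
  }
  stopifnot(iterations >= 1, cv > 0, dirichlet_concentration > 0)
  structure(list(iterations = as.integer(iterations), seed = as.integer(seed),
                 cv = cv, dirichlet_concentration = dirichlet_concentration,
                 overrides = overrides),
            class = "psa_config")
}

.draw_seed <- function(seed, draw_index) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(draw_index)) %%
               .Machine$integer.max)
}

# Beta by method of moments from (mean, cv); infeasible cv (variance beyond
# the Bernoulli bound) is clamped down with a warning.
.rbeta_mean_cv <- function(n, mean, cv) {
  if (mean <= 0 || mean >= 1) return(rep(mean, n))
  v_max <- mean * (1 - mean)
  v <- (cv * mean)^2
  if (v >= v_max) {
    warning(sprintf(
      "CV %.3g infeasible for Beta mean %.3g; clamped to the moment bound", cv, mean))
    v <- 0.99 * v_max
  }
  k <- v_max / v - 1
  stats::rbeta(n, mean * k, (1 - mean) * k)
}

.rgamma_mean_cv <- function(n, mean, cv) {
  if (mean <= 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

.rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x <- alpha  # guard against all-zero gamma draws
  x / sum(x)
}

#' Draw one probabilistic-sensitivity parameter set
#'
#' Probabilities are drawn from Beta and costs/life-year multipliers from
#' Gamma distributions, both parameterized by method of moments around the
#' base value with the configured coefficient of variation; stage
#' distributions are drawn from a Dirichlet centred on the base distribution.
#' Draws are reproducible given `(seed, draw_index)` regardless of how many
#' other draws were made in between.
#'
#' @param config Base `scenario_config`.
#' @param psa A `psa_config`.
#' @param draw_index 1-based draw counter.
#' @param age_group Age band whose parameters are perturbed.
#' @param max_retries Rejection-sampling budget for draws violating row-sum
#'   feasibility.
#' @return A list: `config` (the perturbed scenario) and `rejections`
#'   (feasibility redraws used).
#' @export
draw_parameters <- function(config, psa, draw_index,
                            age_group = names(config$age_groups)[1],
                            max_retries = 100L) {
  params <- sensitivity_parameters(config, age_group)
  set.seed(.draw_seed(psa$seed, draw_index))
  for (attempt in seq_len(max_retries)) {
    cfg <- config
    for (i in seq_len(nrow(params))) {
      path <- params$parameter[i]
      ov <- psa$overrides[[path]]
      family <- if (!is.null(ov$family)) ov$family else params$family[i]
      cv <- if (!is.null(ov$cv)) ov$cv else psa$cv
      base <- params$base[i]
      val <- switch(family,
        fixed = base,
        beta = .rbeta_mean_cv(1, base, cv),
        gamma = .rgamma_mean_cv(1, base, cv),
        stop("unknown PSA family: ", family))
      cfg <- scenario_set(cfg, path, val)
    }
    for (arm in c("screened", "non_screened")) {
      base_d <- config$stage_distributions[[arm]]
      d <- .rdirichlet1(psa$dirichlet_concentration * as.numeric(base_d))
      cfg$stage_distributions[[arm]] <- stats::setNames(d, .STAGES)
    }
    if (length(validate_scenario(cfg)) == 0) {
      return(list(config = cfg, rejections = attempt - 1L))
    }
  }
  stop("could not draw a feasible parameter set after ", max_retries, " retries")
}

#' Second-order Monte Carlo probabilistic sensitivity analysis
#'
#' Evaluates the full pipeline once per parameter draw and summarizes the
#' distribution of incremental cost, life-years gained, ICER and INMB.
#' Identical `(seed, iterations)` give an identical summary.
#'
#' @param config Base `scenario_config`.
#' @param psa A `psa_config`.
#' @param age_group Age band to analyse.
#' @param private_share Provider mix of the policy under analysis.
#' @param return_draws Keep the per-draw outputs (for CEAC-style
#'   post-processing).
#' @return A `psa_summary` list: per-output mean / sd / standard error of the
#'   mean / 2.5-50-97.5 percentiles, `probability_cost_effective` at the
#'   scenario WTP, total feasibility `rejections`, and optionally `draws`.
#' @export
run_psa <- function(config, psa, age_group,
                    private_share = config$policy$private_share,
                    return_draws = FALSE) {
  n <- psa$iterations
  draws <- data.frame(incremental_cost = numeric(n), lyg = numeric(n),
                      icer = numeric(n), inmb = numeric(n))
  rejections <- 0L
  for (i in seq_len(n)) {
    dr <- draw_parameters(config, psa, i, age_group)
    rejections <- rejections + dr$rejections
    res <- run_policy_cea(dr$config, age_group, private_share = private_share)
    draws$incremental_cost[i] <- res$incremental_cost
    draws$lyg[i] <- res$lyg
    draws$icer[i] <- res$icer
    draws$inmb[i] <- res$inmb
  }
  # dominance-flagged draws carry NA ICERs; summaries drop them and report
  # how many draws contributed
  summarize <- function(x) {
    q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE, na.rm = TRUE)
    list(mean = mean(x, na.rm = TRUE), sd = stats::sd(x[!is.na(x)]),
         sem = stats::sd(x[!is.na(x)]) / sqrt(sum(!is.na(x))),
         n = sum(!is.na(x)),
         p2.5 = q[1], median = q[2], p97.5 = q[3])
  }
  structure(list(
    iterations = n,
    seed = psa$seed,
    age_group = age_group,
    private_share = private_share,
    wtp = config$wtp_threshold,
    outputs = lapply(draws, summarize),
    probability_cost_effective = mean(draws$inmb > 0),
    rejections = rejections,
    draws = if (return_draws) draws else NULL
  ), class = "psa_summary")
}

#' Probability of cost-effectiveness at an arbitrary willingness-to-pay
#'
#' Recomputes the net-benefit sign per draw at a new threshold, so
#' acceptability can be traced over a grid of thresholds from one draw set.
#'
#' @param draws The `draws` data frame of a [run_psa()] result run with
#'   `return_draws = TRUE`.
#' @param wtp Willingness-to-pay threshold.
#' @return Proportion of draws with positive net monetary benefit.
#' @export
prob_cost_effective <- function(draws, wtp) {
  mean(wtp * draws$lyg - draws$incremental_cost > 0)
}
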