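#' Scenario configuration for the screening cost-effectiveness model
#'
#' A scenario bundles every input of one model run: age-band epidemiology and
#' mammography test characteristics, stage-specific Markov transition
#' probabilities, stage-at-diagnosis distributions for screen-detected and
#' clinically detected cancers, unit costs, discount rates, the provider-mix
#' policy, cohort size and horizon, and behavioural flags. Scenarios are plain
#' lists of class `scenario_config` so they serialize losslessly to YAML/JSON.
#'
#' @name scenario_config
#' @keywords internal
NULL

.STAGES <- c("I", "II", "III", "IV")
.STAGE_GROUPS <- c("I", "II_III", "IV")
.STATES <- c("remission", "local_recurrence", "distant_recurrence",
             "cancer_death", "other_death")
.MODELED_AGE_GROUPS <- c("40-49", "50-59")

.default_flags <- function() {
  list(
    include_fp_workup = TRUE,
    discount_timing = "begin_of_cycle",
    lyg_mode = "calibrated_multiplier",
    participation_rate = 1.0,
    deplete_at_risk = TRUE,
    doctor_visit_per = "screen"
  )
}

#' Baseline scenario: annual mammography screening for an Ethiopian cohort
#'
#' Returns the packaged baseline parameter set: age-specific breast-cancer
#' incidence, mammography sensitivity/specificity, per-cycle stage-progression
#' probabilities (stages II and III share one rate set; stage IV cases enter
#' the chain in the distant-recurrence state), stage-at-diagnosis
#' distributions for the screened and non-screened arms, unit costs in USD
#' (government and private mammography, doctor visit, FNAC, stage-specific
#' treatment), 5%/3% annual discount rates for costs/effects, a 100,000-woman
#' cohort followed for 10 annual cycles, and a willingness-to-pay threshold of
#' 2808.5 USD per life-year (three times GDP per capita). The same values are
#' shipped as a YAML fixture in `inst/extdata/ethiopia_baseline.yaml` with a
#' provenance table mapping each parameter to its upstream literature source.
#'
#' The printed stage distributions sum to 1.001 in both arms; they are
#' renormalized proportionally here (see [normalize_stage_distribution()]).
#' Other-cause mortality defaults to 0 over the 10-year horizon: the
#' other-death state is structural but no rate is published for it.
#'
#' @return A `scenario_config` list.
#' @export
#' @examples
#' cfg <- baseline_scenario()
#' cfg$costs$fnac                       # 22 USD
#' cfg$age_groups[["40-49"]]$sensitivity  # 0.821
baseline_scenario <- function() {
  cfg <- list(
    schema_version = 1L,
    cohort_size = 100000,
    horizon_cycles = 10L,
    cycle_length_years = 1,
    wtp_threshold = 2808.5,
    other_cause_mortality = 0,
    discounts = list(cost_rate = 0.05, effect_rate = 0.03),
    policy = list(name = "government", private_share = 0),
    flags = .default_flags(),
    costs = list(
      mammography_gov = 4.5,
      mammography_private = 42,
      doctor_visit = 6,
      fnac = 22,
      treatment_by_stage = c(I = 160, II = 458.48, III = 850.45, IV = 668.7)
    ),
    age_groups = list(
      "40-49" = list(
        label = "40-49",
        annual_incidence = 0.000878,
        sensitivity = 0.821,
        specificity = 0.859,
        remaining_life_years = c("40-44" = 36.10367697, "45-49" = 31.72113989),
        lyg_per_death_averted = 31.3958
      ),
      "50-59" = list(
        label = "50-59",
        annual_incidence = 0.00079,
        sensitivity = 0.921,
        specificity = 0.859,
        remaining_life_years = numeric(0),
        lyg_per_death_averted = 23.9052
      )
    ),
    # incidence for bands outside the modeled 40-59 range, kept for reference
    reference_incidence = c("30-39" = 0.000853, "60-69" = 0.000656),
    transitions = list(
      "I_40-49" = list(stage_group = "I", age_group = "40-49",
                       p_rem_local = 0.01, p_rem_dist = 0.000016,
                       p_local_dist = 0.062, p_local_death = 0.013,
                       p_dist_death = 0.555),
      "I_50-59" = list(stage_group = "I", age_group = "50-59",
                       p_rem_local = 0.009, p_rem_dist = 0.000025,
                       p_local_dist = 0.052, p_local_death = 0.013,
                       p_dist_death = 0.137),
      "II_III_40-49" = list(stage_group = "II_III", age_group = "40-49",
                            p_rem_local = 0.018, p_rem_dist = 0.024,
                            p_local_dist = 0.165, p_local_death = 0,
                            p_dist_death = 0.386),
      "II_III_50-59" = list(stage_group = "II_III", age_group = "50-59",
                            p_rem_local = 0.016, p_rem_dist = 0.105,
                            p_local_dist = 0.13, p_local_death = 0,
                            p_dist_death = 0.423),
      "IV_40-49" = list(stage_group = "IV", age_group = "40-49",
                        p_rem_local = 0, p_rem_dist = 0,
                        p_local_dist = 0, p_local_death = 0,
                        p_dist_death = 0.386),
      "IV_50-59" = list(stage_group = "IV", age_group = "50-59",
                        p_rem_local = 0, p_rem_dist = 0,
                        p_local_dist = 0, p_local_death = 0,
                        p_dist_death = 0.423)
    ),
    stage_distributions = list(
      screened = normalize_stage_distribution(
        c(I = 0.521, II = 0.382, III = 0.057, IV = 0.041)),
      non_screened = normalize_stage_distribution(
        c(I = 0.1, II = 0.189, III = 0.569, IV = 0.143))
    )
  )
  structure(cfg, class = "scenario_config")
}

#' Normalize a stage-at-diagnosis distribution
#'
#' Divides four non-negative stage weights by their sum. Published stage
#' distributions often carry rounding error (the packaged baseline's print to
#' 1.001 in both arms); proportional rescaling is the minimal correction. A
#' raw sum deviating from 1 by more than `tolerance` is treated as a data
#' error, not rounding, and raises.
#'
#' @param raw Numeric vector of four non-negative weights (stages I-IV).
#' @param tolerance Maximum tolerated deviation of `sum(raw)` from 1
#'   (default 0.05).
#' @return Named numeric vector over stages I-IV summing to 1.
#' @export
#' @examples
#' normalize_stage_distribution(c(0.521, 0.382, 0.057, 0.041))
normalize_stage_distribution <- function(raw, tolerance = 0.05) {
  raw <- as.numeric(raw)
  if (length(raw) != 4L) {
    stop("stage distribution must have exactly 4 entries, got ", length(raw))
  }
  if (any(!is.finite(raw)) || any(raw < 0)) {
    stop("stage distribution weights must be finite and non-negative")
  }
  s <- sum(raw)
  if (s == 0) {
    stop("degenerate stage distribution: all weights are zero")
  }
  if (abs(s - 1) > tolerance) {
    stop(sprintf(
      "stage distribution sum %.6g deviates from 1 by more than tolerance %g",
      s, tolerance))
  }
  stats::setNames(raw / s, .STAGES)
}

#' Validate a scenario configuration
#'
#' Checks every structural invariant of the model inputs and returns all
#' violations found (it does not stop at the first). Violations are data, not
#' exceptions: an empty character vector means the scenario is valid.
#'
#' @param config A `scenario_config` list.
#' @return Character vector of violation messages; `character(0)` when valid.
#' @export
validate_scenario <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

  if (!num1(config$cohort_size) || config$cohort_size < 1) {
    add("cohort_size must be a number >= 1")
  }
  if (!num1(config$horizon_cycles) || config$horizon_cycles < 1) {
    add("horizon_cycles must be a number >= 1")
  }
  if (!num1(config$wtp_threshold) || config$wtp_threshold <= 0) {
    add("wtp_threshold must be a positive number")
  }
  if (!num1(config$other_cause_mortality) ||
      config$other_cause_mortality < 0 || config$other_cause_mortality >= 1) {
    add("other_cause_mortality must be in [0, 1)")
  }
  for (nm in c("cost_rate", "effect_rate")) {
    r <- config$discounts[[nm]]
    if (!num1(r) || r < 0 || r >= 1) {
      add(sprintf("discounts.%s must be in [0, 1)", nm))
    }
  }
  pr <- config$flags$participation_rate
  if (!num1(pr) || pr < 0 || pr > 1) {
    add("flags.participation_rate must be in [0, 1]")
  }
  if (!config$flags$discount_timing %in% c("begin_of_cycle", "end_of_cycle")) {
    add("flags.discount_timing must be begin_of_cycle or end_of_cycle")
  }
  if (!config$flags$lyg_mode %in% c("life_table", "calibrated_multiplier")) {
    add("flags.lyg_mode must be life_table or calibrated_multiplier")
  }
  if (!config$flags$doctor_visit_per %in% c("screen", "positive")) {
    add("flags.doctor_visit_per must be screen or positive")
  }
  ps <- config$policy$private_share
  if (!num1(ps) || ps < 0 || ps > 1) {
    add("policy.private_share must be in [0, 1]")
  }

  for (nm in c("mammography_gov", "mammography_private", "doctor_visit", "fnac")) {
    cst <- config$costs[[nm]]
    if (!num1(cst) || cst < 0) {
      add(sprintf("costs.%s must be a non-negative number", nm))
    }
  }
  tbs <- config$costs$treatment_by_stage
  if (!is.numeric(tbs) || length(tbs) != 4L || any(!is.finite(tbs)) || any(tbs < 0)) {
    add("costs.treatment_by_stage must be 4 non-negative numbers (stages I-IV)")
  }

  for (ag in names(config$age_groups)) {
    g <- config$age_groups[[ag]]
    for (nm in c("annual_incidence", "sensitivity", "specificity")) {
      p <- g[[nm]]
      if (!num1(p) || p < 0 || p > 1) {
        add(sprintf("age_groups.%s.%s must be a probability in [0, 1]", ag, nm))
      }
    }
    rly <- g$remaining_life_years
    if (length(rly) > 0 && (any(!is.finite(rly)) || any(rly <= 0))) {
      add(sprintf("age_groups.%s.remaining_life_years must be strictly positive", ag))
    }
  }

  for (key in names(config$transitions)) {
    tr <- config$transitions[[key]]
    if (!tr$stage_group %in% .STAGE_GROUPS) {
      add(sprintf("transitions.%s.stage_group must be one of %s",
                  key, paste(.STAGE_GROUPS, collapse = ", ")))
    }
    if (!tr$age_group %in% names(config$age_groups)) {
      add(sprintf("transitions.%s references unknown age group '%s'",
                  key, tr$age_group))
    }
    for (nm in c("p_rem_local", "p_rem_dist", "p_local_dist",
                 "p_local_death", "p_dist_death")) {
      p <- tr[[nm]]
      if (!num1(p) || p < 0 || p > 1) {
        add(sprintf("transitions.%s.%s must be a probability in [0, 1]", key, nm))
      }
    }
    ok <- function(x) num1(x) && x >= 0 && x <= 1
    if (ok(tr$p_rem_local) && ok(tr$p_rem_dist) &&
        tr$p_rem_local + tr$p_rem_dist > 1) {
      add(sprintf(
        "transitions.%s: p_rem_local + p_rem_dist = %.6g exceeds 1 (row-sum bound)",
        key, tr$p_rem_local + tr$p_rem_dist))
    }
    if (ok(tr$p_local_dist) && ok(tr$p_local_death) &&
        tr$p_local_dist + tr$p_local_death > 1) {
      add(sprintf(
        "transitions.%s: p_local_dist + p_local_death = %.6g exceeds 1 (row-sum bound)",
        key, tr$p_local_dist + tr$p_local_death))
    }
  }
  for (ag in .modeled_age_groups(config)) {
    for (sg in .STAGE_GROUPS) {
      if (is.null(config$transitions[[paste(sg, ag, sep = "_")]])) {
        add(sprintf("no transition rates for stage group %s, age group %s", sg, ag))
      }
    }
  }

  for (arm in c("screened", "non_screened")) {
    d <- config$stage_distributions[[arm]]
    if (!is.numeric(d) || length(d) != 4L) {
      add(sprintf("stage_distributions.%s must have 4 entries", arm))
    } else if (any(!is.finite(d)) || any(d < 0) || any(d > 1)) {
      add(sprintf("stage_distributions.%s entries must be in [0, 1]", arm))
    } else if (abs(sum(d) - 1) > 1e-9) {
      add(sprintf("stage_distributions.%s must sum to 1 (got %.12g)", arm, sum(d)))
    }
  }
  v
}

.modeled_age_groups <- function(config) names(config$age_groups)

# -- serialization ------------------------------------------------------------

# Schema skeleton used for strict unknown-key checking on load.
.scenario_schema_keys <- function() {
  list(
    top = c("schema_version", "cohort_size", "horizon_cycles",
            "cycle_length_years", "wtp_threshold", "other_cause_mortality",
            "discounts", "policy", "flags", "costs", "age_groups",
            "reference_incidence", "transitions", "stage_distributions"),
    discounts = c("cost_rate", "effect_rate"),
    policy = c("name", "private_share"),
    flags = names(.default_flags()),
    costs = c("mammography_gov", "mammography_private", "doctor_visit",
              "fnac", "treatment_by_stage"),
    age_group = c("label", "annual_incidence", "sensitivity", "specificity",
                  "remaining_life_years", "lyg_per_death_averted"),
    transition = c("stage_group", "age_group", "p_rem_local", "p_rem_dist",
                   "p_local_dist", "p_local_death", "p_dist_death"),
    stage_distributions = c("screened", "non_screened")
  )
}

.check_keys <- function(found, allowed, where, strict) {
  unknown <- setdiff(found, allowed)
  if (length(unknown) > 0) {
    msg <- sprintf("unknown key(s) in %s: %s", where,
                   paste(unknown, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
}

#' Load a scenario from a YAML or JSON document
#'
#' Parses a scenario document, applies defaults for absent optional fields
#' (flags, WTP threshold, other-cause mortality), renormalizes the stage
#' distributions, and validates every invariant. Unknown keys are rejected by
#' default: a silent typo in a probability name is catastrophic in this model.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` scenario document.
#' @param strict Reject unknown keys with an error (default); when `FALSE`
#'   they only produce a warning.
#' @return A validated `scenario_config` list.
#' @export
load_scenario <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  scenario_from_list(raw, strict = strict)
}

#' Build a validated scenario from a plain list
#'
#' Workhorse behind [load_scenario()]; also usable on lists built in code.
#'
#' @inheritParams load_scenario
#' @param raw Plain list as parsed from a scenario document.
#' @return A validated `scenario_config` list.
#' @export
scenario_from_list <- function(raw, strict = TRUE) {
  sch <- .scenario_schema_keys()
  .check_keys(names(raw), sch$top, "scenario", strict)
  if (!is.null(raw$schema_version) && raw$schema_version != 1) {
    stop("unsupported schema_version: ", raw$schema_version)
  }

  cfg <- baseline_scenario()  # defaults come from the baseline skeleton
  cfg$schema_version <- 1L
  for (nm in c("cohort_size", "horizon_cycles", "cycle_length_years",
               "wtp_threshold", "other_cause_mortality")) {
    if (!is.null(raw[[nm]])) cfg[[nm]] <- as.numeric(raw[[nm]])
  }
  if (!is.null(raw$discounts)) {
    .check_keys(names(raw$discounts), sch$discounts, "discounts", strict)
    for (nm in names(raw$discounts)) {
      cfg$discounts[[nm]] <- as.numeric(raw$discounts[[nm]])
    }
  }
  if (!is.null(raw$policy)) {
    .check_keys(names(raw$policy), sch$policy, "policy", strict)
    if (!is.null(raw$policy$name)) cfg$policy$name <- as.character(raw$policy$name)
    if (!is.null(raw$policy$private_share)) {
      cfg$policy$private_share <- as.numeric(raw$policy$private_share)
    }
  }
  if (!is.null(raw$flags)) {
    .check_keys(names(raw$flags), sch$flags, "flags", strict)
    for (nm in names(raw$flags)) {
      val <- raw$flags[[nm]]
      cfg$flags[[nm]] <- if (is.logical(cfg$flags[[nm]])) as.logical(val)
        else if (is.numeric(cfg$flags[[nm]])) as.numeric(val)
        else as.character(val)
    }
  }
  if (!is.null(raw$costs)) {
    .check_keys(names(raw$costs), sch$costs, "costs", strict)
    for (nm in setdiff(names(raw$costs), "treatment_by_stage")) {
      cfg$costs[[nm]] <- as.numeric(raw$costs[[nm]])
    }
    if (!is.null(raw$costs$treatment_by_stage)) {
      tbs <- unlist(raw$costs$treatment_by_stage)
      if (length(tbs) != 4L) stop("costs.treatment_by_stage must have 4 entries")
      cfg$costs$treatment_by_stage <- stats::setNames(as.numeric(tbs), .STAGES)
    }
  }
  if (!is.null(raw$age_groups)) {
    cfg$age_groups <- list()
    for (ag in names(raw$age_groups)) {
      g <- raw$age_groups[[ag]]
      .check_keys(names(g), sch$age_group, paste0("age_groups.", ag), strict)
      entry <- list(
        label = ag,
        annual_incidence = as.numeric(g$annual_incidence),
        sensitivity = as.numeric(g$sensitivity),
        specificity = as.numeric(g$specificity),
        remaining_life_years =
          if (is.null(g$remaining_life_years)) numeric(0)
          else stats::setNames(as.numeric(unlist(g$remaining_life_years)),
                               names(unlist(g$remaining_life_years))),
        lyg_per_death_averted =
          if (is.null(g$lyg_per_death_averted)) NA_real_
          else as.numeric(g$lyg_per_death_averted)
      )
      cfg$age_groups[[ag]] <- entry
    }
  }
  if (!is.null(raw$reference_incidence)) {
    cfg$reference_incidence <- unlist(raw$reference_incidence)
  }
  if (!is.null(raw$transitions)) {
    cfg$transitions <- list()
    for (key in names(raw$transitions)) {
      tr <- raw$transitions[[key]]
      .check_keys(names(tr), sch$transition, paste0("transitions.", key), strict)
      for (nm in c("p_rem_local", "p_rem_dist", "p_local_dist",
                   "p_local_death", "p_dist_death")) {
        if (is.null(tr[[nm]])) tr[[nm]] <- 0
        tr[[nm]] <- as.numeric(tr[[nm]])
      }
      cfg$transitions[[key]] <- tr
    }
  }
  if (!is.null(raw$stage_distributions)) {
    .check_keys(names(raw$stage_distributions), sch$stage_distributions,
                "stage_distributions", strict)
    for (arm in names(raw$stage_distributions)) {
      cfg$stage_distributions[[arm]] <-
        normalize_stage_distribution(unlist(raw$stage_distributions[[arm]]))
    }
  }

  cfg <- structure(cfg, class = "scenario_config")
  viol <- validate_scenario(cfg)
  if (length(viol) > 0) {
    stop("invalid scenario:\n  ", paste(viol, collapse = "\n  "))
  }
  cfg
}

#' Write a scenario to YAML or JSON
#'
#' The written document round-trips: [load_scenario()] on the output
#' reproduces the scenario.
#'
#' @param config A `scenario_config` list.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(config, path) {
  x <- unclass(config)
  # named numeric vectors must survive the round trip as named maps
  x$costs$treatment_by_stage <- as.list(x$costs$treatment_by_stage)
  x$stage_distributions <- lapply(x$stage_distributions, as.list)
  x$reference_incidence <- as.list(x$reference_incidence)
  for (ag in names(x$age_groups)) {
    rly <- x$age_groups[[ag]]$remaining_life_years
    x$age_groups[[ag]]$remaining_life_years <-
      if (length(rly) == 0) NULL else as.list(rly)
    if (is.na(x$age_groups[[ag]]$lyg_per_death_averted)) {
      x$age_groups[[ag]]$lyg_per_death_averted <- NULL
    }
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}

# -- parameter paths ----------------------------------------------------------

#' Get or set a scenario parameter by dotted path
#'
#' Paths address scalars inside the nested scenario list, e.g.
#' `"costs.mammography_gov"`, `"age_groups.40-49.sensitivity"`,
#' `"transitions.I_40-49.p_rem_local"`, `"discounts.cost_rate"`. Used by the
#' one-way and probabilistic sensitivity analyses to perturb one parameter at
#' a time.
#'
#' @param config A `scenario_config` list.
#' @param path Dotted path string.
#' @param value Replacement value (for `scenario_set`).
#' @return `scenario_get`: the value at `path`. `scenario_set`: the modified
#'   scenario.
#' @export
scenario_get <- function(config, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  x <- config
  for (p in parts) {
    if (is.null(x[[p]])) stop("no such scenario parameter: ", path)
    x <- x[[p]]
  }
  x
}

#' @rdname scenario_get
#' @export
scenario_set <- function(config, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  scenario_get(config, path)  # existence check
  rec <- function(x, parts) {
    if (length(parts) == 1L) {
      x[[parts]] <- value
      return(x)
    }
    x[[parts[1]]] <- rec(x[[parts[1]]], parts[-1])
    x
  }
  out <- rec(unclass(config), parts)
  structure(out, class = "scenario_config")
}

#' Path to the packaged baseline scenario fixture
#' @return Path to the YAML fixture inside the installed package.
#' @export
baseline_scenario_path <- function() {
  system.file("extdata", "ethiopia_baseline.yaml", package = "screencea",
              mustWork = TRUE)
}
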