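#' Expected screening/diagnosis outcomes for one annual cycle
#'
#' Deterministic expected-value arithmetic over the screening decision tree:
#' among `at_risk` women, `at_risk * incidence` develop cancer this cycle; the
#' test splits them into true positives (screen-detected) and false negatives
#' (diagnosed clinically in the same cycle, with the less favourable clinical
#' stage distribution); cancer-free women generate false positives at rate
#' `1 - specificity`. Fractional women are allowed throughout: downstream
#' outputs are expectations, not realisations.
#'
#' @param at_risk Expected number of women at risk (>= 0).
#' @param incidence Annual incidence probability.
#' @param sensitivity,specificity Mammography test characteristics.
#' @return A `cycle_detection` list: `n_screened`, `new_cancers`,
#'   `true_positives`, `false_negatives`, `false_positives`,
#'   `true_negatives`, and (after [allocate_diagnosis_stages()]) a
#'   `diagnoses_by_stage` matrix.
#' @export
#' @examples
#' screening_cycle_outcomes(100000, 0.000878, 0.821, 0.859)
screening_cycle_outcomes <- function(at_risk, incidence, sensitivity, specificity) {
  stopifnot(at_risk >= 0,
            incidence >= 0, incidence <= 1,
            sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  new_cancers <- at_risk * incidence
  healthy <- at_risk - new_cancers
  structure(list(
    n_screened = at_risk,
    new_cancers = new_cancers,
    true_positives = new_cancers * sensitivity,
    false_negatives = new_cancers * (1 - sensitivity),
    false_positives = healthy * (1 - specificity),
    true_negatives = healthy * specificity,
    diagnoses_by_stage = NULL
  ), class = "cycle_detection")
}

#' Allocate newly diagnosed cancers to stages at diagnosis
#'
#' Screen-detected cases (true positives) draw from the screened stage
#' distribution; clinically detected cases (false negatives in the screening
#' arm, every case in the no-screening arm) draw from the clinical
#' (non-screened) distribution. This stage shift is the model's entire
#' mechanism of screening benefit.
#'
#' @param detection A `cycle_detection` from [screening_cycle_outcomes()].
#' @param screened_dist,clinical_dist Normalized stage distributions
#'   (see [normalize_stage_distribution()]).
#' @return The `cycle_detection` with a `diagnoses_by_stage` matrix
#'   (rows `screen_detected`/`clinical`, columns stages I-IV).
#' @export
allocate_diagnosis_stages <- function(detection, screened_dist, clinical_dist) {
  for (d in list(screened_dist, clinical_dist)) {
    if (abs(sum(d) - 1) > 1e-9) {
      stop("stage distribution not normalized (sum = ", sum(d), ")")
    }
  }
  m <- rbind(
    screen_detected = detection$true_positives * as.numeric(screened_dist),
    clinical = detection$false_negatives * as.numeric(clinical_dist)
  )
  colnames(m) <- .STAGES
  detection$diagnoses_by_stage <- m
  detection
}

#' Undiscounted cost components for one cycle
#'
#' Screened arm: every screening encounter costs the mammography unit price
#' plus (by default) the doctor-visit fee; suspected cases (true positives,
#' plus false positives when `include_fp_workup`) incur the FNAC diagnostic
#' fee; every diagnosed case incurs a one-time stage-specific treatment cost.
#' Non-screened arm: no screening component; each diagnosed case incurs a
#' doctor visit, FNAC, and stage treatment. Whether the doctor-visit fee
#' attaches per screen or only per positive is not settled by the published
#' inputs; `doctor_visit_per = "positive"` restricts it to suspected cases.
#'
#' @param detection A stage-allocated `cycle_detection`.
#' @param costs The `costs` element of a scenario.
#' @param arm `"screened"` or `"non_screened"`.
#' @param mammography_unit_cost Unit price in USD for this policy's provider
#'   mix (ignored in the non-screened arm).
#' @param include_fp_workup Charge FNAC for false positives (default `TRUE`).
#' @param doctor_visit_per `"screen"` (default) or `"positive"`.
#' @return Named numeric: `screening`, `diagnostic`, `treatment` components in
#'   USD, undiscounted.
#' @export
cycle_costs <- function(detection, costs, arm = c("screened", "non_screened"),
                        mammography_unit_cost = NULL,
                        include_fp_workup = TRUE,
                        doctor_visit_per = c("screen", "positive")) {
  arm <- match.arg(arm)
  doctor_visit_per <- match.arg(doctor_visit_per)
  d <- detection
  counts <- c(d$n_screened, d$new_cancers, d$true_positives,
              d$false_negatives, d$false_positives)
  if (any(counts < 0)) stop("negative expected counts in cycle detection")
  if (is.null(d$diagnoses_by_stage)) {
    stop("detection must be stage-allocated before costing")
  }
  treatment <- sum(colSums(d$diagnoses_by_stage) * costs$treatment_by_stage)
  if (arm == "screened") {
    if (is.null(mammography_unit_cost)) {
      stop("mammography_unit_cost required for the screened arm")
    }
    positives <- d$true_positives + d$false_positives
    doctor_n <- if (doctor_visit_per == "screen") d$n_screened else positives
    screening <- d$n_screened * mammography_unit_cost + doctor_n * costs$doctor_visit
    workup <- d$true_positives + if (include_fp_workup) d$false_positives else 0
    diagnostic <- workup * costs$fnac
  } else {
    screening <- 0
    diagnostic <- d$new_cancers * (costs$doctor_visit + costs$fnac)
  }
  c(screening = screening, diagnostic = diagnostic, treatment = treatment)
}
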