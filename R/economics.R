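# 10-year pathway costs, savings, QALYs and ICERs.
#
# Cost structure: every referred patient gets a risk-assessment visit every
# `assessment_interval_years` over the horizon (£251/visit for the DXA
# pathway, £522 for the strength pathway — both taken as stated per-visit
# totals); treated patients accrue a fixed pharmacological cost over the
# horizon; each expected fracture accrues a direct care cost and an indirect
# (societal) cost.  No discounting is applied by default; a discount-rate
# hook exists but the reference arithmetic is undiscounted.

#' Unit costs and horizon of the screening model
#'
#' Defaults are UK NHS 2016/17 tariffs and published UK fracture-cost
#' estimates: DXA exam £62, CT scan £78, FE simulation service £250,
#' endocrinology specialist visit £189, radiographer handling £8/case,
#' all-in per-assessment totals £251 (DXA pathway) and £522 (strength
#' pathway), preventive treatment £7200 per treated patient over the 10-year
#' horizon (£60/month), hip fracture £16,302 direct and £10,364 indirect.
#'
#' @param dxa_exam,ct_exam,simulation,specialist_visit,radiographer_per_case
#'   Component unit costs, GBP.
#' @param per_assessment_dxa,per_assessment_qct Per-assessment-visit totals,
#'   GBP (used as stated totals, not recomputed from components).
#' @param treatment_per_patient_horizon Treatment cost per treated patient
#'   over the whole horizon, GBP.
#' @param fracture_direct,fracture_indirect Cost per hip fracture, GBP.
#' @param horizon_years,assessment_interval_years Projection horizon and
#'   assessment spacing, years.
#' @param discount_rate Annual discount rate applied to nothing by default
#'   (0); retained as an explicit modelling hook.
#' @return A `cost_parameters` list.
#' @export
cost_parameters <- function(dxa_exam = 62, ct_exam = 78, simulation = 250,
                            specialist_visit = 189, radiographer_per_case = 8,
                            per_assessment_dxa = 251, per_assessment_qct = 522,
                            treatment_per_patient_horizon = 7200,
                            fracture_direct = 16302, fracture_indirect = 10364,
                            horizon_years = 10, assessment_interval_years = 2,
                            discount_rate = 0) {
  for (nm in c("dxa_exam", "ct_exam", "simulation", "specialist_visit",
               "radiographer_per_case", "per_assessment_dxa",
               "per_assessment_qct", "treatment_per_patient_horizon",
               "fracture_direct", "fracture_indirect")) {
    check_nonneg(get(nm), nm)
  }
  check_positive(horizon_years, "horizon_years")
  check_positive(assessment_interval_years, "assessment_interval_years")
  check_number(discount_rate, "discount_rate", 0, 1)
  structure(as.list(environment()), class = "cost_parameters")
}

#' QALY weights and willingness-to-pay threshold
#'
#' @param qaly_no_fracture,qaly_fracture Average quality-adjusted life year
#'   for women over 55 without / with a hip fracture (defaults 0.91, 0.63).
#' @param willingness_to_pay Cost-effectiveness benchmark, GBP per QALY
#'   (default £30,000, the upper UK NICE benchmark).
#' @return A `qaly_parameters` list.
#' @export
qaly_parameters <- function(qaly_no_fracture = 0.91, qaly_fracture = 0.63,
                            willingness_to_pay = 30000) {
  check_number(qaly_no_fracture, "qaly_no_fracture", 0, 1)
  check_number(qaly_fracture, "qaly_fracture", 0, 1)
  check_positive(willingness_to_pay, "willingness_to_pay")
  if (qaly_fracture > qaly_no_fracture) {
    abort_domain("`qaly_fracture` cannot exceed `qaly_no_fracture`.")
  }
  structure(list(qaly_no_fracture = qaly_no_fracture,
                 qaly_fracture = qaly_fracture,
                 qaly_loss_per_fracture = qaly_no_fracture - qaly_fracture,
                 willingness_to_pay = willingness_to_pay),
            class = "qaly_parameters")
}

#' Number of assessment rounds in the horizon
#'
#' Counts the baseline visit and every subsequent visit starting inside the
#' horizon, excluding an end-of-horizon visit: `ceiling(horizon / interval)`
#' (10 years at 2-year spacing gives 5 rounds).
#'
#' @param horizon_years,interval_years Positive durations, years.
#' @return Integer round count, at least 1.
#' @export
#' @examples
#' n_assessments(10, 2) # 5
n_assessments <- function(horizon_years, interval_years) {
  check_positive(horizon_years, "horizon_years")
  check_positive(interval_years, "interval_years")
  max(1L, as.integer(ceiling(horizon_years / interval_years)))
}

#' Total risk-assessment cost over the horizon
#'
#' @param n_patients Referred patients (fractional permitted).
#' @param per_assessment Cost per patient per assessment round, GBP.
#' @param rounds Assessment rounds in the horizon.
#' @param extra_exams Additional triggered exams (e.g. dual-pathway strength
#'   tests), total over the horizon.
#' @param extra_per_exam Cost of each additional exam, GBP.
#' @return GBP: `n_patients * per_assessment * rounds +
#'   extra_exams * extra_per_exam`.
#' @export
#' @examples
#' assessment_cost(1000, 251, 5) # 1,255,000
assessment_cost <- function(n_patients, per_assessment, rounds,
                            extra_exams = 0, extra_per_exam = 0) {
  for (nm in c("n_patients", "per_assessment", "rounds",
               "extra_exams", "extra_per_exam")) {
    check_nonneg(get(nm), nm)
  }
  n_patients * per_assessment * rounds + extra_exams * extra_per_exam
}

#' Construct a pathway cost breakdown
#'
#' Totals are exact sums of the stated components:
#' `total_direct = assessment + treatment + fracture_direct`,
#' `total_full = total_direct + fracture_indirect`.
#'
#' @param assessment_cost,treatment_cost,fracture_direct_cost,fracture_indirect_cost
#'   Component totals, GBP, all non-negative.
#' @param pathway_name Optional label.
#' @return A `cost_breakdown` object.
#' @export
cost_breakdown <- function(assessment_cost, treatment_cost,
                           fracture_direct_cost, fracture_indirect_cost,
                           pathway_name = NA_character_) {
  for (nm in c("assessment_cost", "treatment_cost", "fracture_direct_cost",
               "fracture_indirect_cost")) {
    check_nonneg(get(nm), nm)
  }
  structure(list(
    pathway_name = pathway_name,
    assessment_cost = assessment_cost,
    treatment_cost = treatment_cost,
    fracture_direct_cost = fracture_direct_cost,
    fracture_indirect_cost = fracture_indirect_cost,
    total_direct = assessment_cost + treatment_cost + fracture_direct_cost,
    total_full = assessment_cost + treatment_cost + fracture_direct_cost +
      fracture_indirect_cost
  ), class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("<cost_breakdown>%s\n",
              if (is.na(x$pathway_name)) "" else paste0(" [", x$pathway_name, "]")))
  rows <- c(assessment = x$assessment_cost, treatment = x$treatment_cost,
            `fracture care (direct)` = x$fracture_direct_cost,
            `fracture care (indirect)` = x$fracture_indirect_cost,
            `total (direct)` = x$total_direct, `total (full)` = x$total_full)
  for (nm in names(rows)) cat(sprintf("  %-26s %s\n", nm, format_gbp(rows[[nm]])))
  invisible(x)
}

#' Cost a pathway's tallies
#'
#' Applies the cost model to a set of pathway tallies.  Assessment cost by
#' pathway: the DXA pathway charges `per_assessment_dxa` per patient per
#' round; the strength pathway charges `per_assessment_qct`; the dual
#' pathway charges `per_assessment_dxa` for everyone plus a triggered
#' strength work-up (`ct_exam + simulation`) for each osteopenic-band
#' subject at every round.
#'
#' @param counts A `pathway_counts` (its `pathway_name` selects the exam
#'   structure unless `pathway` is given).
#' @param costs A [cost_parameters()].
#' @param pathway Optional [pathway_definition()] overriding the label in
#'   `counts`.
#' @return A `cost_breakdown`.
#' @export
#' @examples
#' counts <- pathway_counts(1000, 367, 633, 0, 147, 316, "dxa_tscore")
#' pathway_cost(counts, cost_parameters())
pathway_cost <- function(counts, costs = cost_parameters(), pathway = NULL) {
  if (!inherits(counts, "pathway_counts")) {
    abort_domain("`counts` must be a pathway_counts object.")
  }
  if (!inherits(costs, "cost_parameters")) {
    abort_domain("`costs` must be created with cost_parameters().")
  }
  name <- if (!is.null(pathway)) pathway$name else counts$pathway_name
  if (is.na(name) || !name %in% PATHWAY_NAMES) {
    abort_domain("Pathway name must be one of dxa_tscore, qct_ssfe, dual.")
  }
  rounds <- n_assessments(costs$horizon_years, costs$assessment_interval_years)
  assess <- switch(name,
    dxa_tscore = assessment_cost(counts$n_referred, costs$per_assessment_dxa, rounds),
    qct_ssfe = assessment_cost(counts$n_referred, costs$per_assessment_qct, rounds),
    dual = assessment_cost(counts$n_referred, costs$per_assessment_dxa, rounds,
                           extra_exams = counts$n_qct_exams * rounds,
                           extra_per_exam = costs$ct_exam + costs$simulation)
  )
  cost_breakdown(
    assessment_cost = assess,
    treatment_cost = counts$n_treated * costs$treatment_per_patient_horizon,
    fracture_direct_cost = counts$fractures_total * costs$fracture_direct,
    fracture_indirect_cost = counts$fractures_total * costs$fracture_indirect,
    pathway_name = name
  )
}

#' Recover an expected fracture count from an indirect-cost total
#'
#' The indirect fracture-care total of a published scenario divided by the
#' indirect cost per fracture returns the expected fracture count the
#' scenario carried internally (published totals retain sub-integer
#' precision).
#'
#' @param indirect_total Indirect fracture-care total, GBP.
#' @param per_fracture_indirect Indirect cost per fracture, GBP (positive).
#' @return Expected fracture count.
#' @export
#' @examples
#' fractures_from_costs(4801282, 10364) # ~463.27
fractures_from_costs <- function(indirect_total, per_fracture_indirect) {
  check_nonneg(indirect_total, "indirect_total")
  check_positive(per_fracture_indirect, "per_fracture_indirect")
  indirect_total / per_fracture_indirect
}

#' Run and cost a pathway in one step
#'
#' @inheritParams run_pathway
#' @param costs A [cost_parameters()].
#' @return A `pathway_result` holding the tallies (`$counts`) and the cost
#'   breakdown (`$breakdown`).
#' @export
evaluate_pathway <- function(cohort, pathway, model = treatment_model(),
                             costs = cost_parameters(), scale_to = 1000) {
  counts <- run_pathway(cohort, pathway, model, scale_to)
  structure(list(pathway = pathway, counts = counts,
                 breakdown = pathway_cost(counts, costs, pathway)),
            class = "pathway_result")
}

#' @export
print.pathway_result <- function(x, ...) {
  print(x$counts); print(x$breakdown); invisible(x)
}

as_pathway_result <- function(x, arg) {
  if (inherits(x, "pathway_result")) return(x)
  if (is.list(x) && inherits(x$counts, "pathway_counts") &&
      inherits(x$breakdown, "cost_breakdown")) {
    return(x)
  }
  abort_domain(paste0("`", arg, "` must be a pathway_result or a list with ",
                      "$counts (pathway_counts) and $breakdown (cost_breakdown)."))
}

#' Incremental cost-effectiveness of one pathway against another
#'
#' Computes fractures avoided (reference minus candidate expected
#' fractures), QALYs gained (fractures avoided times the per-fracture QALY
#' loss), incremental direct and full costs, and the ICER (incremental full
#' cost per QALY gained).  When no QALYs are gained the ICER is undefined
#' (`NA`, `status = "undefined"`); when the candidate is worse on health
#' the result is flagged (`status = "candidate_worse_health"`) and no ICER
#' is reported.
#'
#' @param reference,candidate `pathway_result` objects (or lists carrying
#'   `$counts` and `$breakdown`) on the same referral base.
#' @param qaly A [qaly_parameters()].
#' @return An `econ_result`; see [tidy()].
#' @export
compare_pathways <- function(reference, candidate, qaly = qaly_parameters()) {
  reference <- as_pathway_result(reference, "reference")
  candidate <- as_pathway_result(candidate, "candidate")
  if (!inherits(qaly, "qaly_parameters")) {
    abort_domain("`qaly` must be created with qaly_parameters().")
  }
  if (abs(reference$counts$n_referred - candidate$counts$n_referred) > 1e-6) {
    abort_domain("Reference and candidate must share the same referral base.")
  }
  fractures_avoided <- reference$counts$fractures_total -
    candidate$counts$fractures_total
  qaly_gained <- fractures_avoided * qaly$qaly_loss_per_fracture
  delta_direct <- candidate$breakdown$total_direct - reference$breakdown$total_direct
  delta_full <- candidate$breakdown$total_full - reference$breakdown$total_full
  status <- if (qaly_gained > 0) "ok" else if (qaly_gained == 0) "undefined" else "candidate_worse_health"
  icer <- if (status == "ok") delta_full / qaly_gained else NA_real_
  structure(list(
    reference_name = reference$counts$pathway_name,
    candidate_name = candidate$counts$pathway_name,
    fractures_avoided = fractures_avoided,
    qaly_gained = qaly_gained,
    delta_cost_direct = delta_direct,
    delta_cost_full = delta_full,
    icer = icer,
    status = status,
    cost_effective = if (status == "ok") icer <= qaly$willingness_to_pay else NA,
    willingness_to_pay = qaly$willingness_to_pay
  ), class = "econ_result")
}

#' @export
print.econ_result <- function(x, ...) {
  cat(sprintf("<econ_result> %s vs %s\n",
              x$candidate_name %||% "candidate", x$reference_name %||% "reference"))
  cat(sprintf("  fractures avoided %.2f (reported as %d) | QALYs gained %.3f\n",
              x$fractures_avoided, as.integer(round_half_up(x$fractures_avoided)),
              x$qaly_gained))
  cat(sprintf("  incremental cost: direct %s, full %s\n",
              format_gbp(x$delta_cost_direct), format_gbp(x$delta_cost_full)))
  if (x$status == "ok") {
    cat(sprintf("  ICER %s per QALY (%scost-effective at %s/QALY)\n",
                format_gbp(x$icer), if (x$cost_effective) "" else "not ",
                format_gbp(x$willingness_to_pay)))
  } else if (x$status == "undefined") {
    cat("  ICER undefined: no QALYs gained\n")
  } else {
    cat("  candidate is worse on health outcomes; ICER not applicable\n")
  }
  invisible(x)
}

#' Published 1000-patient screening scenario
#'
#' The printed cells of a published UK cost-benefit scenario comparing the
#' three pathways over 1000 referred patients and 10 years (efficacy 40%),
#' shipped as a plain-text fixture.  Used as a cross-check for the cost
#' arithmetic and as the input for reproducing the published ICERs.
#'
#' @return Tibble with `quantity` plus one column per pathway.
#' @export
#' @examples
#' reference_scenario()
reference_scenario <- function() {
  path <- system.file("extdata", "reference_scenario.csv",
                      package = "hipscreen", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    quantity = "c", dxa_tscore = "d", qct_ssfe = "d", dual = "d"
  ))
}

scenario_value <- function(scenario, quantity, pathway) {
  row <- scenario[scenario$quantity == quantity, ]
  if (nrow(row) != 1L) abort_data(paste0("Scenario quantity not found: ", quantity))
  row[[pathway]]
}

#' Pathway results reconstructed from published scenario cells
#'
#' Builds a `pathway_result` per pathway directly from the printed totals of
#' [reference_scenario()]; the expected fracture count is recovered from the
#' indirect fracture-care cell via [fractures_from_costs()], preserving the
#' sub-integer precision the published totals carry.
#'
#' @param costs A [cost_parameters()] supplying the indirect cost per
#'   fracture.
#' @return Named list of `pathway_result` objects
#'   (`dxa_tscore`, `qct_ssfe`, `dual`).
#' @export
reference_pathway_results <- function(costs = cost_parameters()) {
  sc <- reference_scenario()
  res <- lapply(PATHWAY_NAMES, function(p) {
    fr_total <- fractures_from_costs(
      scenario_value(sc, "fracture_indirect_cost", p), costs$fracture_indirect)
    treated <- scenario_value(sc, "n_treated", p)
    counts <- pathway_counts(
      n_referred = scenario_value(sc, "n_referred", p),
      n_treated = treated,
      n_untreated = scenario_value(sc, "n_untreated", p),
      n_qct_exams = 0,
      fractures_treated = scenario_value(sc, "fractures_treated", p),
      fractures_untreated = fr_total - scenario_value(sc, "fractures_treated", p),
      pathway_name = p
    )
    breakdown <- cost_breakdown(
      assessment_cost = scenario_value(sc, "assessment_cost", p),
      treatment_cost = scenario_value(sc, "treatment_cost", p),
      fracture_direct_cost = scenario_value(sc, "fracture_direct_cost", p),
      fracture_indirect_cost = scenario_value(sc, "fracture_indirect_cost", p),
      pathway_name = p
    )
    structure(list(pathway = pathway_definition(p), counts = counts,
                   breakdown = breakdown), class = "pathway_result")
  })
  setNames(res, PATHWAY_NAMES)
}
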