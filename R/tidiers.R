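# broom-style tidiers: every fitted/derived object flattens to a tibble so
# results compose with dplyr pipelines.

#' Tidy a strength regression fit
#'
#' @param x A [fit_linear()] result.
#' @param ... Unused.
#' @return One row per coefficient (`term`, `estimate`).
#' @method tidy strength_fit
#' @export
tidy.strength_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.strength_fit
#' @return For `glance()`: one row with `see`, `r_squared`, `n`.
#' @method glance strength_fit
#' @export
glance.strength_fit <- function(x, ...) {
  tibble(see = x$see, r_squared = x$r_squared, n = x$n)
}

#' Tidy an accuracy report
#'
#' @param x A [classify()] result.
#' @param ... Unused.
#' @return One-row tibble with the rule and its operating characteristics.
#' @method tidy accuracy_report
#' @export
tidy.accuracy_report <- function(x, ...) {
  tibble(variable = x$threshold$variable,
         cutoff = x$threshold$cutoff,
         auc = x$auc,
         sensitivity = x$sensitivity,
         specificity = x$specificity,
         accuracy = x$accuracy,
         n_cases = x$n_cases,
         n_controls = x$n_controls)
}

#' Tidy pathway tallies
#'
#' @param x A `pathway_counts` object.
#' @param ... Unused.
#' @return One-row tibble of the tallies at full precision.
#' @method tidy pathway_counts
#' @export
tidy.pathway_counts <- function(x, ...) {
  tibble(pathway = x$pathway_name, n_referred = x$n_referred,
         n_treated = x$n_treated, n_untreated = x$n_untreated,
         n_qct_exams = x$n_qct_exams,
         fractures_treated = x$fractures_treated,
         fractures_untreated = x$fractures_untreated,
         fractures_total = x$fractures_total)
}

#' Tidy a cost breakdown
#'
#' @param x A `cost_breakdown` object.
#' @param ... Unused.
#' @return One-row tibble of component and total costs (GBP, full
#'   precision).
#' @method tidy cost_breakdown
#' @export
tidy.cost_breakdown <- function(x, ...) {
  tibble(pathway = x$pathway_name,
         assessment_cost = x$assessment_cost,
         treatment_cost = x$treatment_cost,
         fracture_direct_cost = x$fracture_direct_cost,
         fracture_indirect_cost = x$fracture_indirect_cost,
         total_direct = x$total_direct,
         total_full = x$total_full)
}

#' Tidy a combined pathway result
#'
#' @param x An [evaluate_pathway()] result.
#' @param ... Unused.
#' @return One-row tibble joining tallies and costs.
#' @method tidy pathway_result
#' @export
tidy.pathway_result <- function(x, ...) {
  bind_cols(tidy(x$counts), tidy(x$breakdown)[-1L])
}

#' Tidy an incremental cost-effectiveness result
#'
#' @param x A [compare_pathways()] result.
#' @param ... Unused.
#' @return One-row tibble with fractures avoided, QALYs gained, incremental
#'   costs, ICER and verdict.
#' @method tidy econ_result
#' @export
tidy.econ_result <- function(x, ...) {
  tibble(reference = x$reference_name, candidate = x$candidate_name,
         fractures_avoided = x$fractures_avoided,
         qaly_gained = x$qaly_gained,
         delta_cost_direct = x$delta_cost_direct,
         delta_cost_full = x$delta_cost_full,
         icer = x$icer, status = x$status,
         cost_effective = x$cost_effective)
}

#' Tidy a radiation risk-benefit chain
#'
#' @param x A [radiation_benefit_chain()] result.
#' @param ... Unused.
#' @return One-row tibble of the chain outputs as fractions plus formatted
#'   percentages.
#' @method tidy radiation_chain
#' @export
tidy.radiation_chain <- function(x, ...) {
  tibble(
    additional_treated_fraction = x$additional_treated_fraction,
    death_risk_reduction = x$death_risk_reduction,
    radiation_death_risk = x$radiation_death_risk,
    additional_treated_pct = format_percent(x$additional_treated_fraction),
    death_risk_reduction_pct = format_percent(x$death_risk_reduction),
    radiation_death_risk_pct = format_percent(x$radiation_death_risk),
    net_benefit = x$net_benefit
  )
}

#' Summarise a trial comparison
#'
#' @param x A [trial_comparison()] tibble.
#' @param ... Unused.
#' @return One-row tibble contrasting the two arms: group sizes, total
#'   costs and the saving from switching predictor.
#' @method glance trial_comparison
#' @export
glance.trial_comparison <- function(x, ...) {
  ab <- x[x$predictor == "abmd", ]
  qc <- x[x$predictor == "qct_ssfe", ]
  tibble(n_per_group_abmd = ab$n_per_group,
         n_per_group_qct = qc$n_per_group,
         total_cost_abmd = ab$total_cost,
         total_cost_qct = qc$total_cost,
         cost_saving = ab$total_cost - qc$total_cost)
}
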