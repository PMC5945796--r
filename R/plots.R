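# ggplot2 views of the main result types.

#' Plot a cohort's predictor distributions
#'
#' Density of the FE-predicted strength and of aBMD by group, the visual
#' counterpart of the discrimination AUCs.
#'
#' @param object Cohort tibble from [generate_cohort()]/[read_cohort()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hips_cohort
#' @export
autoplot.hips_cohort <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = c("predicted_mss_n", "abmd"),
    names_to = "predictor", values_to = "value"
  ) %>%
    mutate(predictor = dplyr::recode(.data$predictor,
                                     predicted_mss_n = "FE-predicted strength (N)",
                                     abmd = "aBMD (g/cm²)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::facet_wrap(~predictor, scales = "free") +
    ggplot2::labs(x = NULL, y = "density", fill = NULL,
                  title = "Risk-predictor distributions by group") +
    ggplot2::theme_minimal()
}

#' Empirical ROC curve behind an accuracy report
#'
#' Plots the empirical ROC of the report's score variable (low score =
#' higher risk) with the operating point of the threshold rule marked.
#'
#' @param report A [classify()] result.
#' @param cohort The cohort it was computed on.
#' @return A ggplot.
#' @export
plot_roc <- function(report, cohort) {
  scores <- rule_scores(cohort, report$threshold)
  is_case <- cohort$group == "fracture"
  cuts <- c(-Inf, sort(unique(scores)), Inf)
  roc <- tibble(
    fpr = vapply(cuts, function(cc) mean(scores[!is_case] <= cc), numeric(1)),
    tpr = vapply(cuts, function(cc) mean(scores[is_case] <= cc), numeric(1))
  )
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::annotate("point", x = 1 - report$specificity,
                      y = report$sensitivity, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("ROC of %s (AUC %.3f), rule cutoff %g marked",
                      report$threshold$variable, report$auc,
                      report$threshold$cutoff)
    ) +
    ggplot2::theme_minimal()
}

#' Stacked cost comparison of the screening pathways
#'
#' @param results Named list of `pathway_result`s (as from
#'   [run_pathways()]`$results`).
#' @return A ggplot of the 10-year cost components per pathway.
#' @export
plot_pathway_costs <- function(results) {
  df <- purrr::map_dfr(results, ~ tidy(.x$breakdown)) %>%
    select("pathway", "assessment_cost", "treatment_cost",
           "fracture_direct_cost", "fracture_indirect_cost") %>%
    tidyr::pivot_longer(-"pathway", names_to = "component",
                        values_to = "cost") %>%
    mutate(component = sub("_cost$", "", .data$component))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pathway, y = .data$cost / 1e6,
                                   fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "10-year cost (£ million)",
                  fill = NULL, title = "Screening pathway cost components") +
    ggplot2::theme_minimal()
}
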