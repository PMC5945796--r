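# Predictor accuracy metrics: regression error (%SEE, %SER), rank AUC, and
# threshold classification.  Both femoral strength and aBMD are "low is bad"
# scores, so throughout this file a CASE is expected to score LOWER than a
# CONTROL and a subject is classified positive (treat / fracture-predicted)
# when the score is at or below the cutoff.

#' Ordinary least-squares fit with its standard error of the estimate
#'
#' Thin wrapper over [stats::lm()] returning the quantities the accuracy
#' metrics need: slope, intercept, residual standard error
#' `sqrt(RSS / (n - 2))` (the standard error of the estimate, SEE, in
#' response units) and n.
#'
#' @param x Predictor values.
#' @param y Response values (same length, `n >= 3`).
#' @return A `strength_fit` object; see [tidy()] and [glance()] methods.
#' @export
#' @examples
#' fit_linear(c(1, 2, 3, 4), c(1, 2, 3, 4)) # perfect fit, SEE 0
fit_linear <- function(x, y) {
  if (length(x) != length(y)) abort_data("`x` and `y` must have equal length.")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) abort_data("Need at least 3 complete (x, y) pairs to fit a line.")
  if (diff(range(x)) == 0) {
    abort_data("`x` is constant: the regression design is degenerate.")
  }
  fit <- lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    see = sqrt(rss / (n - 2L)),
    n = n,
    r_squared = if (tss > 0) 1 - rss / tss else 1
  ), class = "strength_fit")
}

#' @export
print.strength_fit <- function(x, ...) {
  cat(sprintf("<strength_fit> y = %.4g + %.4g x  (n = %d, SEE = %.4g, R^2 = %.3f)\n",
              x$intercept, x$slope, x$n, x$see, x$r_squared))
  invisible(x)
}

#' Normalise a regression error by the mean response
#'
#' Expresses a fit's standard error of the estimate as a percentage of the
#' average response — the %SEE of a strength-prediction validation when the
#' predictor is also a strength, and the %SER when the predictor is aBMD.
#'
#' @param fit A [fit_linear()] result (or anything with a numeric `$see`).
#' @param mean_response Average response (e.g. mean measured strength,
#'   newtons); must be positive.
#' @return Percentage, `100 * see / mean_response`.
#' @export
#' @examples
#' normalised_see(list(see = 506), 3265) # ~15.5
normalised_see <- function(fit, mean_response) {
  check_positive(mean_response, "mean_response")
  see <- fit$see
  check_nonneg(see, "fit$see")
  100 * see / mean_response
}

#' Rank-based AUC with cases expected to score low
#'
#' The probability that a randomly drawn case scores strictly below a
#' randomly drawn control, counting ties as 1/2 — the Mann-Whitney statistic
#' scaled by `n_cases * n_controls`.  Computed from midranks, so it is exact
#' on discrete data and invariant under strictly monotone transforms.
#'
#' @param scores_cases,scores_controls Numeric score vectors, both non-empty.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' rank_auc(c(1, 3), c(2, 4)) # 3 wins out of 4 pairs
rank_auc <- function(scores_cases, scores_controls) {
  scores_cases <- scores_cases[is.finite(scores_cases)]
  scores_controls <- scores_controls[is.finite(scores_controls)]
  n1 <- length(scores_cases)
  n2 <- length(scores_controls)
  if (n1 == 0L || n2 == 0L) {
    abort_data("Both groups must contain at least one finite score.")
  }
  r <- rank(c(scores_cases, scores_controls))
  u_cases_high <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 # #{case > control} + ties/2
  1 - u_cases_high / (n1 * n2)
}

#' Define a treat / fracture-predicted threshold rule
#'
#' A subject is classified positive when the rule variable is at or below
#' the cutoff (inclusive, matching the WHO convention that a T-score equal
#' to the intervention threshold already warrants treatment).
#'
#' @param variable One of `"t_score"` (DXA T-score), `"mss_newtons"`
#'   (FE-predicted minimum side-fall strength, N) or `"mss_bw_multiple"`
#'   (that strength as a multiple of body weight force).
#' @param cutoff Threshold in the variable's units.
#' @param g Gravitational acceleration used for body-weight conversion,
#'   m/s^2.
#' @return A `threshold_rule` object.
#' @export
#' @examples
#' threshold_rule("t_score", -2.5)
#' threshold_rule("mss_newtons", 3000)
threshold_rule <- function(variable = c("t_score", "mss_newtons", "mss_bw_multiple"),
                           cutoff, g = 9.81) {
  variable <- match.arg(variable)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff)) {
    abort_domain("`cutoff` must be a single number (infinite allowed).")
  }
  check_positive(g, "g")
  structure(list(variable = variable, cutoff = cutoff, g = g,
                 direction = "at_or_below_positive"),
            class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf("<threshold_rule> positive iff %s <= %g\n", x$variable, x$cutoff))
  invisible(x)
}

# score vector a rule operates on, in the rule's units
rule_scores <- function(cohort, rule) {
  switch(rule$variable,
    t_score = cohort$t_score,
    mss_newtons = cohort$predicted_mss_n,
    mss_bw_multiple = strength_to_bw_multiple(cohort$predicted_mss_n,
                                              cohort$weight_kg, rule$g)
  )
}

#' Classify a cohort with a threshold rule
#'
#' Applies the rule to every subject, takes the group label as the
#' fracture/no-fracture truth, and reports the confusion-matrix proportions
#' together with the rank AUC of the underlying score.  The same code path
#' serves discrimination accuracy (scoring prevalent fractures) and
#' prediction accuracy (scoring future fractures): the two differ by study
#' design, not by formula.
#'
#' @param cohort Cohort tibble with `group` and the rule's variable
#'   (`weight_kg` as well for body-weight rules).
#' @param rule A [threshold_rule()].
#' @return An `accuracy_report` with `auc`, `sensitivity`, `specificity`,
#'   `accuracy`, counts, and the rule; see [tidy()].
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_pairs = 200, random_seed = 7))
#' classify(cohort, threshold_rule("t_score", -2.5))
classify <- function(cohort, rule) {
  if (!inherits(rule, "threshold_rule")) {
    abort_domain("`rule` must be created with threshold_rule().")
  }
  needed <- c("group",
              switch(rule$variable,
                     t_score = "t_score",
                     mss_newtons = "predicted_mss_n",
                     mss_bw_multiple = c("predicted_mss_n", "weight_kg")))
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    abort_data(paste0("Cohort lacks column(s) needed by the rule: ",
                      paste(missing_cols, collapse = ", ")))
  }
  scores <- rule_scores(cohort, rule)
  bad <- which(!is.finite(scores))
  if (length(bad)) {
    ids <- if ("subject_id" %in% names(cohort)) {
      cohort$subject_id[bad]
    } else {
      paste0("row ", bad)
    }
    abort_data(paste0("Rule variable `", rule$variable,
                      "` is missing for subject(s): ",
                      paste(ids, collapse = ", ")))
  }
  is_case <- cohort$group == "fracture"
  if (!any(is_case) || all(is_case)) {
    abort_data("Classification needs at least one case and one control.")
  }
  positive <- scores <= rule$cutoff
  tp <- sum(positive & is_case)
  tn <- sum(!positive & !is_case)
  n_cases <- sum(is_case)
  n_controls <- sum(!is_case)
  structure(list(
    auc = rank_auc(scores[is_case], scores[!is_case]),
    sensitivity = tp / n_cases,
    specificity = tn / n_controls,
    accuracy = (tp + tn) / (n_cases + n_controls),
    threshold = rule,
    n_cases = n_cases,
    n_controls = n_controls
  ), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "<accuracy_report> %s <= %g on %d cases / %d controls\n",
    x$threshold$variable, x$threshold$cutoff, x$n_cases, x$n_controls))
  cat(sprintf("  AUC %.3f | sensitivity %.3f | specificity %.3f | accuracy %.3f\n",
              x$auc, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Convert strength to a body-weight multiple and back
#'
#' Expresses a femoral strength as a multiple of the subject's body weight
#' force (`weight * g`), the normalisation behind the "four times body
#' weight" strength threshold; `bw_multiple_to_strength()` inverts it.
#'
#' @param strength Strength, newtons.
#' @param multiple Strength as a body-weight multiple.
#' @param weight Body weight, kilograms (positive).
#' @param g Gravitational acceleration, m/s^2 (positive).
#' @return Dimensionless multiple, or newtons for the inverse.
#' @export
#' @examples
#' strength_to_bw_multiple(3000, 80.7) # ~3.8, i.e. about four body weights
#' bw_multiple_to_strength(4, 65) # ~2551 N
strength_to_bw_multiple <- function(strength, weight, g = 9.81) {
  if (any(weight <= 0, na.rm = TRUE)) abort_domain("`weight` must be positive.")
  if (g <= 0) abort_domain("`g` must be positive.")
  strength / (weight * g)
}

#' @rdname strength_to_bw_multiple
#' @export
bw_multiple_to_strength <- function(multiple, weight, g = 9.81) {
  if (any(weight <= 0, na.rm = TRUE)) abort_domain("`weight` must be positive.")
  if (g <= 0) abort_domain("`g` must be positive.")
  multiple * weight * g
}

#' Accuracy summary of both predictors on one cohort
#'
#' Convenience wrapper computing, on a single cohort: the rank AUC of the
#' FE-predicted strength and of aBMD; the %SEE of the FE prediction
#' (predicted strength regressed on measured strength, residual error as a
#' percent of mean measured strength); and the %SER of the density predictor
#' (measured strength regressed on aBMD, same normalisation).  The error
#' metrics need `measured_strength_n`; when it is absent they are returned
#' as `NA` with a warning and the AUCs are still computed.
#'
#' @param cohort Cohort tibble.
#' @return One-row tibble with columns `auc_mss`, `auc_abmd`, `pct_see`,
#'   `pct_ser`, `n_cases`, `n_controls`.
#' @export
cohort_accuracy <- function(cohort) {
  is_case <- cohort$group == "fracture"
  if (!any(is_case) || all(is_case)) {
    abort_data("Cohort must contain both fracture cases and controls.")
  }
  auc_mss <- rank_auc(cohort$predicted_mss_n[is_case],
                      cohort$predicted_mss_n[!is_case])
  auc_abmd <- rank_auc(cohort$abmd[is_case], cohort$abmd[!is_case])
  meas <- cohort$measured_strength_n
  if (all(!is.finite(meas))) {
    warn("No measured strengths in cohort: %SEE/%SER skipped, AUCs still computed.")
    pct_see <- NA_real_
    pct_ser <- NA_real_
  } else {
    mean_meas <- mean(meas, na.rm = TRUE)
    pct_see <- normalised_see(fit_linear(meas, cohort$predicted_mss_n), mean_meas)
    pct_ser <- normalised_see(fit_linear(cohort$abmd, meas), mean_meas)
  }
  tibble(auc_mss = auc_mss, auc_abmd = auc_abmd,
         pct_see = pct_see, pct_ser = pct_ser,
         n_cases = sum(is_case), n_controls = sum(!is_case))
}
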