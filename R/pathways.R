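# Screening/treatment triage pathways.  Three strategies are compared for a
# population referred to secondary care as at risk of osteoporosis:
#   dxa_tscore — treat everyone osteoporotic by the WHO rule (T <= -2.5);
#   qct_ssfe   — treat everyone whose FE-predicted minimum side-fall strength
#                is at or below a fixed cutoff (default 2551 N, i.e. four
#                body-weight forces at a 65 kg reference weight);
#   dual       — treat T <= -2.5, discharge T > -1.0, and resolve the
#                osteopenic band (-2.5 < T <= -1.0) with a strength test.
# Fracture projection is static over the horizon: each subject either is or
# is not fracture-destined, and treatment prevents a fixed fraction
# (efficacy) of fractures among treated fracture-destined subjects.

PATHWAY_NAMES <- c("dxa_tscore", "qct_ssfe", "dual")

#' Define a screening pathway
#'
#' @param name `"dxa_tscore"`, `"qct_ssfe"` or `"dual"`.
#' @param tscore_treat_cutoff Treat at or below this T-score (WHO
#'   osteoporosis definition).
#' @param tscore_safe_cutoff Discharge above this T-score (dual pathway
#'   only); must exceed `tscore_treat_cutoff`.
#' @param mss_cutoff Treat at or below this FE-predicted strength, newtons.
#' @return A `pathway_definition`.
#' @export
#' @examples
#' pathway_definition("dual")
pathway_definition <- function(name = c("dxa_tscore", "qct_ssfe", "dual"),
                               tscore_treat_cutoff = -2.5,
                               tscore_safe_cutoff = -1.0,
                               mss_cutoff = 2551) {
  name <- match.arg(name)
  check_number(tscore_treat_cutoff, "tscore_treat_cutoff")
  check_number(tscore_safe_cutoff, "tscore_safe_cutoff")
  check_positive(mss_cutoff, "mss_cutoff")
  if (tscore_treat_cutoff >= tscore_safe_cutoff) {
    abort_domain("`tscore_treat_cutoff` must lie below `tscore_safe_cutoff`.")
  }
  structure(list(name = name,
                 tscore_treat_cutoff = tscore_treat_cutoff,
                 tscore_safe_cutoff = tscore_safe_cutoff,
                 mss_cutoff = mss_cutoff),
            class = "pathway_definition")
}

#' Treatment efficacy model
#'
#' @param efficacy Fraction of fractures prevented among treated
#'   fracture-destined subjects, in `[0, 1]`.
#' @return A `treatment_model`.
#' @export
treatment_model <- function(efficacy = 0.40) {
  check_number(efficacy, "efficacy", 0, 1)
  structure(list(efficacy = efficacy), class = "treatment_model")
}

#' Triage a cohort through a pathway
#'
#' Adds a `treat` decision and a `qct_performed` flag to every subject.  All
#' cutoffs are inclusive on the treat side.  In the dual pathway
#' `qct_performed` marks exactly the osteopenic band
#' (`tscore_treat_cutoff < T <= tscore_safe_cutoff`), whose decision is then
#' made on predicted strength.
#'
#' @param cohort Cohort tibble with `t_score` (and `predicted_mss_n` where
#'   the pathway can request it).
#' @param pathway A [pathway_definition()].
#' @return The cohort with logical columns `treat` and `qct_performed`
#'   appended.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_pairs = 10, random_seed = 3))
#' triage(cohort, pathway_definition("dual"))[, c("t_score", "treat", "qct_performed")]
triage <- function(cohort, pathway) {
  if (!inherits(pathway, "pathway_definition")) {
    abort_domain("`pathway` must be created with pathway_definition().")
  }
  if (!"t_score" %in% names(cohort)) {
    abort_data("Cohort lacks the `t_score` column required for triage.")
  }
  t <- cohort$t_score
  mss_needed <- switch(pathway$name,
    dxa_tscore = rep(FALSE, nrow(cohort)),
    qct_ssfe = rep(TRUE, nrow(cohort)),
    dual = t > pathway$tscore_treat_cutoff & t <= pathway$tscore_safe_cutoff
  )
  if (any(mss_needed)) {
    mss <- cohort[["predicted_mss_n"]]
    if (is.null(mss) || any(!is.finite(mss[mss_needed]))) {
      bad <- if (is.null(mss)) which(mss_needed) else which(mss_needed & !is.finite(mss))
      ids <- if ("subject_id" %in% names(cohort)) cohort$subject_id[bad] else paste0("row ", bad)
      abort_data(paste0("`predicted_mss_n` required but missing for subject(s): ",
                        paste(ids, collapse = ", ")))
    }
  }
  treat <- switch(pathway$name,
    dxa_tscore = t <= pathway$tscore_treat_cutoff,
    qct_ssfe = cohort$predicted_mss_n <= pathway$mss_cutoff,
    dual = ifelse(t <= pathway$tscore_treat_cutoff, TRUE,
           ifelse(t > pathway$tscore_safe_cutoff, FALSE,
                  cohort$predicted_mss_n <= pathway$mss_cutoff))
  )
  qct_performed <- if (pathway$name == "dual") mss_needed else rep(FALSE, nrow(cohort))
  out <- mutate(as_tibble(cohort), treat = treat, qct_performed = qct_performed)
  new_cohort(out)
}

#' Expected fractures under the efficacy model
#'
#' @param destined Expected number of fracture-destined subjects (`>= 0`).
#' @param model A [treatment_model()].
#' @param treated Logical: are these subjects on treatment?
#' @return Expected fracture count: `destined * (1 - efficacy)` if treated,
#'   `destined` otherwise.
#' @export
#' @examples
#' expected_fractures(24, treatment_model(0.4), treated = TRUE) # 14.4
expected_fractures <- function(destined, model = treatment_model(), treated) {
  check_nonneg(destined, "destined")
  if (!inherits(model, "treatment_model")) {
    abort_domain("`model` must be created with treatment_model().")
  }
  if (isTRUE(treated)) destined * (1 - model$efficacy) else destined
}

#' Run a pathway over a cohort and tally outcomes
#'
#' Triages every subject, takes the case/control label as fracture-destined
#' status, applies the treatment-efficacy model, and optionally rescales all
#' tallies to a reference referral base (e.g. per 1000 referred patients).
#' Tallies are carried at full precision; fractional values after rescaling
#' are intentional.
#'
#' @param cohort Non-empty cohort tibble with `group`, `t_score` and (where
#'   needed) `predicted_mss_n`.
#' @param pathway A [pathway_definition()].
#' @param model A [treatment_model()].
#' @param scale_to Referral base to rescale to, or `NULL` for raw tallies.
#' @return A `pathway_counts` object with `n_referred`, `n_treated`,
#'   `n_untreated`, `n_qct_exams` (strength assessments per round:
#'   triage referrals for the dual pathway, everyone for the qct pathway),
#'   `fractures_treated`, `fractures_untreated`, `fractures_total`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_pairs = 500, random_seed = 11))
#' run_pathway(cohort, pathway_definition("dual"), scale_to = 1000)
run_pathway <- function(cohort, pathway, model = treatment_model(),
                        scale_to = NULL) {
  if (nrow(cohort) == 0L) abort_data("Cannot run a pathway on an empty cohort.")
  decided <- triage(cohort, pathway)
  destined <- decided$group == "fracture"
  n <- nrow(decided)
  n_treated <- sum(decided$treat)
  fr_treated <- expected_fractures(sum(destined & decided$treat), model, TRUE)
  fr_untreated <- expected_fractures(sum(destined & !decided$treat), model, FALSE)
  n_qct <- switch(pathway$name,
    dxa_tscore = 0,
    qct_ssfe = n,
    dual = sum(decided$qct_performed)
  )
  scale <- if (is.null(scale_to)) 1 else {
    check_positive(scale_to, "scale_to")
    scale_to / n
  }
  pathway_counts(
    n_referred = n * scale,
    n_treated = n_treated * scale,
    n_untreated = (n - n_treated) * scale,
    n_qct_exams = n_qct * scale,
    fractures_treated = fr_treated * scale,
    fractures_untreated = fr_untreated * scale,
    pathway_name = pathway$name
  )
}

#' Construct pathway tallies directly
#'
#' Low-level constructor used by [run_pathway()], by the closed-form
#' parametric projection, and to enter published scenario tallies by hand.
#'
#' @param n_referred,n_treated,n_untreated,n_qct_exams Patient tallies
#'   (fractional values permitted for rescaled projections).
#' @param fractures_treated,fractures_untreated Expected fractures in the
#'   treated / untreated arms.
#' @param pathway_name Optional pathway label.
#' @return A `pathway_counts` object; `fractures_total` is always the sum of
#'   the two arms.
#' @export
pathway_counts <- function(n_referred, n_treated, n_untreated,
                           n_qct_exams = 0,
                           fractures_treated, fractures_untreated,
                           pathway_name = NA_character_) {
  for (nm in c("n_referred", "n_treated", "n_untreated", "n_qct_exams",
               "fractures_treated", "fractures_untreated")) {
    check_nonneg(get(nm), nm)
  }
  structure(list(
    pathway_name = pathway_name,
    n_referred = n_referred,
    n_treated = n_treated,
    n_untreated = n_untreated,
    n_qct_exams = n_qct_exams,
    fractures_treated = fractures_treated,
    fractures_untreated = fractures_untreated,
    fractures_total = fractures_treated + fractures_untreated
  ), class = "pathway_counts")
}

#' @export
print.pathway_counts <- function(x, ...) {
  cat(sprintf("<pathway_counts>%s %0.6g referred\n",
              if (is.na(x$pathway_name)) "" else paste0(" [", x$pathway_name, "]"),
              x$n_referred))
  cat(sprintf("  treated %0.6g | untreated %0.6g | strength exams/round %0.6g\n",
              x$n_treated, x$n_untreated, x$n_qct_exams))
  cat(sprintf("  expected fractures: treated %0.6g + untreated %0.6g = %0.6g\n",
              x$fractures_treated, x$fractures_untreated, x$fractures_total))
  invisible(x)
}

#' Closed-form pathway tallies from test characteristics
#'
#' Alternative to the subject-level projection: given the fracture-destined
#' prevalence among referred patients and the sensitivity/specificity of the
#' pathway's decision rule, computes expected tallies analytically.
#'
#' @param n_referred Referral base (e.g. 1000).
#' @param prevalence Fraction of referred patients destined to fracture.
#' @param sensitivity,specificity Decision-rule operating characteristics.
#' @param model A [treatment_model()].
#' @param qct_exams_per_round Expected strength assessments per round (0 for
#'   a pure T-score rule; `n_referred` for a strength-for-all rule; the
#'   osteopenic-band size for a dual triage).
#' @param pathway_name Optional label.
#' @return A `pathway_counts` object.
#' @export
#' @examples
#' parametric_counts(1000, 0.5, 0.73, 0.8)
parametric_counts <- function(n_referred, prevalence, sensitivity, specificity,
                              model = treatment_model(),
                              qct_exams_per_round = 0,
                              pathway_name = NA_character_) {
  check_positive(n_referred, "n_referred")
  check_number(prevalence, "prevalence", 0, 1)
  check_number(sensitivity, "sensitivity", 0, 1)
  check_number(specificity, "specificity", 0, 1)
  destined <- n_referred * prevalence
  safe <- n_referred - destined
  treated_destined <- destined * sensitivity
  treated_safe <- safe * (1 - specificity)
  pathway_counts(
    n_referred = n_referred,
    n_treated = treated_destined + treated_safe,
    n_untreated = n_referred - treated_destined - treated_safe,
    n_qct_exams = qct_exams_per_round,
    fractures_treated = expected_fractures(treated_destined, model, TRUE),
    fractures_untreated = expected_fractures(destined - treated_destined, model, FALSE),
    pathway_name = pathway_name
  )
}
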