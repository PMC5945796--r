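# Radiation risk-benefit chain for switching the risk assessment from DXA
# (effective dose ~0.001 mSv) to a CT-based strength work-up.  The benefit
# side compounds the general-population risk of death after hip fracture,
# the accuracy gain of the strength predictor, and treatment efficacy; the
# risk side compounds the per-CT cancer induction risk with average cancer
# mortality.  All quantities are carried as fractions and formatted as
# percentages only at the reporting boundary.

#' Radiation risk-benefit scenario
#'
#' Defaults: 2.8% population risk of death related to a hip fracture in
#' women over 50; 7 pp accuracy gain from the strength predictor; 40%
#' treatment efficacy; 0.0154% cancer induction risk per pelvic CT at an
#' effective dose of 3.8 mSv; 52% average cancer mortality.  The dose-range
#' fields are documentation only (DXA ~0.001 mSv; standard pelvis CT 6 mSv;
#' a whole-femur low-dose protocol 1.9-4.8 mSv for men, 1.3-3.2 mSv for
#' women).
#'
#' @param baseline_fracture_death_risk Probability of death related to hip
#'   fracture in the target population.
#' @param accuracy_gain Extra fraction of at-risk subjects the strength
#'   predictor identifies (percentage points as a fraction).
#' @param treatment_efficacy Fraction of fractures avoided by treatment.
#' @param cancer_risk_per_ct Cancer induction probability per CT exam.
#' @param cancer_mortality Average probability that an induced cancer is
#'   fatal.
#' @param dose_dxa_msv,dose_ct_standard_msv,dose_ct_protocol_msv Effective
#'   doses, mSv (documentation fields).
#' @return A `radiation_scenario`.
#' @export
radiation_scenario <- function(baseline_fracture_death_risk = 0.028,
                               accuracy_gain = 0.07,
                               treatment_efficacy = 0.40,
                               cancer_risk_per_ct = 0.000154,
                               cancer_mortality = 0.52,
                               dose_dxa_msv = 0.001,
                               dose_ct_standard_msv = 6,
                               dose_ct_protocol_msv = c(1.3, 4.8)) {
  for (nm in c("baseline_fracture_death_risk", "accuracy_gain",
               "treatment_efficacy", "cancer_risk_per_ct",
               "cancer_mortality")) {
    check_number(get(nm), nm, 0, 1)
  }
  structure(as.list(environment()), class = "radiation_scenario")
}

#' Radiation risk-benefit chain
#'
#' Multiplies out the scenario: the additional treated fraction is
#' `baseline_fracture_death_risk * accuracy_gain`; the death-risk reduction
#' applies treatment efficacy on top; the radiation death risk is
#' `cancer_risk_per_ct * cancer_mortality`.  The net-benefit flag is true
#' when the death-risk reduction exceeds the radiation death risk.
#'
#' @param scenario A [radiation_scenario()].
#' @return A `radiation_chain` list with `additional_treated_fraction`,
#'   `death_risk_reduction`, `radiation_death_risk` (all fractions) and
#'   `net_benefit`; the print method formats them as percentages.
#' @export
#' @examples
#' radiation_benefit_chain()
radiation_benefit_chain <- function(scenario = radiation_scenario()) {
  if (!inherits(scenario, "radiation_scenario")) {
    abort_domain("`scenario` must be created with radiation_scenario().")
  }
  additional <- scenario$baseline_fracture_death_risk * scenario$accuracy_gain
  reduction <- additional * scenario$treatment_efficacy
  radiation <- scenario$cancer_risk_per_ct * scenario$cancer_mortality
  structure(list(
    additional_treated_fraction = additional,
    death_risk_reduction = reduction,
    radiation_death_risk = radiation,
    net_benefit = reduction > radiation,
    scenario = scenario
  ), class = "radiation_chain")
}

#' @export
print.radiation_chain <- function(x, ...) {
  cat("<radiation_chain>\n")
  cat("  additional at-risk patients treated:", format_percent(x$additional_treated_fraction), "\n")
  cat("  hip-fracture death-risk reduction:  ", format_percent(x$death_risk_reduction), "\n")
  cat("  added radiation death risk:         ", format_percent(x$radiation_death_risk), "\n")
  cat("  net benefit:", if (x$net_benefit) "yes" else "no",
      "(risk reduction exceeds radiation risk)\n")
  invisible(x)
}
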