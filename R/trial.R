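# Clinical-trial sample-size and cost comparison for studies that use
# femoral strength as the endpoint.  Two sizing paths are provided:
#   n_per_group_normal — the standard two-sample, two-sided
#     normal-approximation formula, from first principles;
#   n_rescaled — variance-ratio rescaling of a reference arm's size, which
#     is how a lower-noise predictor (smaller predictor SD) translates into
#     a proportionally smaller cohort at the same detectable difference.
# The two paths answer different questions and are not interchangeable; see
# the methods vignette for why the reference arm sizes are taken as given.

#' Two-sample normal-approximation group size
#'
#' `ceiling( 2 * (z[1 - alpha/2] + z[power])^2 * sd^2 / delta^2 )` per
#' group, for a two-sided comparison of two means with common SD.
#'
#' @param sd Common outcome SD (predictor SD when the endpoint is the
#'   predicted strength), newtons.
#' @param delta Difference to detect, newtons.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return Integer patients per group.
#' @export
#' @examples
#' n_per_group_normal(718, 653) # 19
n_per_group_normal <- function(sd, delta, alpha = 0.05, power = 0.80) {
  check_positive(sd, "sd")
  check_positive(delta, "delta")
  check_number(alpha, "alpha", 0, 1, allow_lower = FALSE, allow_upper = FALSE)
  check_number(power, "power", 0, 1, allow_lower = FALSE, allow_upper = FALSE)
  z <- qnorm(1 - alpha / 2) + qnorm(power)
  as.integer(ceiling(2 * z^2 * sd^2 / delta^2))
}

#' Rescale a group size by the predictor variance ratio
#'
#' At a fixed detectable difference, required group size scales with outcome
#' variance; swapping a predictor of SD `sd_reference` for one of SD
#' `sd_new` rescales the reference size by `(sd_new / sd_reference)^2`
#' (rounded half up).
#'
#' @param n_reference Reference patients per group.
#' @param sd_reference,sd_new Predictor SDs, newtons.
#' @return Integer patients per group.
#' @export
#' @examples
#' n_rescaled(123, 3054, 2199) # 64
n_rescaled <- function(n_reference, sd_reference, sd_new) {
  check_positive(n_reference, "n_reference")
  check_positive(sd_reference, "sd_reference")
  check_positive(sd_new, "sd_new")
  as.integer(round_half_up(n_reference * (sd_new / sd_reference)^2))
}

#' Total trial cost
#'
#' @param n_total Total enrolled patients (both groups).
#' @param fixed_per_patient Fixed per-patient trial cost, GBP.
#' @param imaging_per_patient Imaging cost per patient, GBP (e.g. £62 DXA,
#'   £78 CT).
#' @param simulation_per_patient FE simulation cost per patient, GBP (0 when
#'   no simulation is used).
#' @return GBP: `n_total * (fixed + imaging + simulation)`.
#' @export
#' @examples
#' trial_cost(246, 5000, 62, 0)   # 1,245,252
#' trial_cost(128, 5000, 78, 250) # 681,984
trial_cost <- function(n_total, fixed_per_patient = 5000,
                       imaging_per_patient = 0, simulation_per_patient = 0) {
  for (nm in c("n_total", "fixed_per_patient", "imaging_per_patient",
               "simulation_per_patient")) {
    v <- get(nm)
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      abort_domain(paste0("`", nm, "` must be finite and non-negative."))
    }
  }
  n_total * (fixed_per_patient + imaging_per_patient + simulation_per_patient)
}

#' Side-by-side trial comparison of the two predictors
#'
#' Builds the two-arm comparison table: the reference (aBMD) arm size is
#' taken as given, the strength-predictor arm is derived by variance-ratio
#' rescaling, and per-arm costs are itemised (fixed + imaging
#' + simulation).
#'
#' @param mean_strength Average femoral strength, newtons.
#' @param sd_abmd,sd_qct Predictor SDs for the aBMD and the FE-strength
#'   arm, newtons.
#' @param n_per_group_abmd Reference patients per group in the aBMD arm.
#' @param detect_fraction Difference to detect as a fraction of mean
#'   strength (documentation column; sizing here is anchored on the
#'   reference arm).
#' @param alpha,power Design parameters (documentation columns).
#' @param fixed_per_patient,dxa_cost,ct_cost,simulation_cost Unit costs,
#'   GBP.
#' @return A `trial_comparison` tibble: one row per arm with group sizes,
#'   totals and itemised costs; see also [glance()].
#' @export
#' @examples
#' trial_comparison()
trial_comparison <- function(mean_strength = 3265,
                             sd_abmd = 3054, sd_qct = 2199,
                             n_per_group_abmd = 123,
                             detect_fraction = 0.20,
                             alpha = 0.05, power = 0.80,
                             fixed_per_patient = 5000,
                             dxa_cost = 62, ct_cost = 78,
                             simulation_cost = 250) {
  n_abmd <- as.integer(n_per_group_abmd)
  n_qct <- n_rescaled(n_abmd, sd_abmd, sd_qct)
  arms <- tibble(
    predictor = c("abmd", "qct_ssfe"),
    mean_strength_n = mean_strength,
    predictor_sd_n = c(sd_abmd, sd_qct),
    detect_fraction = detect_fraction,
    alpha = alpha,
    power = power,
    n_per_group = c(n_abmd, n_qct),
    n_total = 2L * c(n_abmd, n_qct),
    imaging_per_patient = c(dxa_cost, ct_cost),
    simulation_per_patient = c(0, simulation_cost)
  ) %>%
    mutate(
      fixed_cost = .data$n_total * fixed_per_patient,
      imaging_cost = .data$n_total * .data$imaging_per_patient,
      simulation_cost = .data$n_total * .data$simulation_per_patient,
      total_cost = trial_cost(.data$n_total, fixed_per_patient,
                              .data$imaging_per_patient,
                              .data$simulation_per_patient)
    )
  class(arms) <- unique(c("trial_comparison", class(arms)))
  arms
}
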