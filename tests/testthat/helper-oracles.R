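# Independent oracles kept deliberately naive: brute-force pair counting for
# the AUC, normal-equation least squares for the regression, and a
# four-subject cohort small enough to triage by hand.

brute_auc <- function(cases, controls) {
  wins <- 0
  for (a in cases) {
    for (b in controls) {
      wins <- wins + (a < b) + 0.5 * (a == b)
    }
  }
  wins / (length(cases) * length(controls))
}

ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  list(intercept = beta[1], slope = beta[2],
       see = sqrt(sum(resid^2) / (length(x) - 2)))
}

# two fracture cases (T -3 and -1.5, the latter with low strength) and two
# controls (T -2.6 osteoporotic, T -0.5 clearly safe)
toy_cohort <- function() {
  tibble::tibble(
    subject_id = c("c1", "c2", "k1", "k2"),
    group = c("fracture", "fracture", "control", "control"),
    age = 70, weight_kg = 65, height_cm = 160,
    abmd = 0.6,
    t_score = c(-3, -1.5, -2.6, -0.5),
    predicted_mss_n = c(2800, 2400, 2700, 2000),
    measured_strength_n = c(2800, 2400, 2700, 2000)
  )
}

default_costs <- hipscreen::cost_parameters()
default_qaly <- hipscreen::qaly_parameters()
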