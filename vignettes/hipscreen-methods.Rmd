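---
title: "Methods: models, calibration and conventions in hipscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration and conventions in hipscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipscreen)
```

`hipscreen` weighs two hip-fracture risk predictors against each other:
the DXA-measured areal bone mineral density (aBMD, reported as a T-score)
and the femoral strength predicted by CT-based subject-specific finite
element models (the minimum strength over simulated side-fall directions,
MSS, in newtons). The package does not build finite element models; it
takes the statistical behaviour of the two predictors as given —
discrimination (AUC), prediction error (%SEE, %SER) and threshold
accuracy — and carries that behaviour through screening pathways, cost
and QALY accounting, trial sizing and a radiation risk–benefit argument.
This vignette records the models, the calibration mathematics, the open
design choices and their resolutions, and what the results do and do not
establish.

## The cohort generative model

A synthetic cohort emulates a retrospective pair-matched case-control
study of postmenopausal women: `n_pairs` fragility hip-fracture cases,
each matched to one control on age, weight and height. Matching is by
construction — each pair shares a single draw of the covariates — so the
covariate multisets of the two groups are identical, which is the exact
property a matched design is meant to buy.

Per subject the model is

* measured strength $S \sim N(\mu_g, \sigma^2)$, truncated below at
  200 N, with group means $\mu_{control} = \bar S + \delta/2$,
  $\mu_{fracture} = \bar S - \delta/2$ around the population mean
  $\bar S$ (default 3265 N);
* FE-predicted strength $P = S + \varepsilon_P$,
  $\varepsilon_P \sim N(0, (f_{SEE}\,\bar S)^2)$ with $f_{SEE} = 0.155$
  by default, matching a 15–16% normalised standard error of the
  estimate reported by cadaver validation studies of modern FE
  pipelines;
* aBMD $B = a + bS + \varepsilon_B$ with slope $b$ = 1 g/cm² per
  4000 N and intercept 0.2 g/cm² (the error structure, not the affine
  map, is the constrained quantity), and
  $\varepsilon_B \sim N(0, \sigma_B^2)$ scaled as derived below;
* T-score $= (B - 0.942)/0.122$, the z-score against a conventional
  young-adult femoral-neck reference (these reference values are a
  convention, not an empirical estimate, and are config-exposed).

Covariates are age $\sim U(55, 90)$ y, weight $\sim N(65, 10^2)$ kg and
height $\sim N(160, 7^2)$ cm. The 65 kg default weight is deliberate:
four body-weight forces at 65 kg is $4 \times 65 \times 9.81 = 2551$ N,
the operational strength cutoff of the dual pathway, so the weight scale
and the threshold scale are mutually consistent.

### Joint calibration

Four targets must hold simultaneously on a generated cohort: AUC of the
predicted strength (0.82), AUC of aBMD (0.75), %SEE (15.5) and %SER
(22). They interact because both predictors are noisy affine views of
the same latent strength. The closure is a one-dimensional root solve
(`calibrate_strength_sd()`) over the within-group strength SD $\sigma$:

1. The predicted-strength score has per-group SD
   $\sqrt{\sigma^2 + \sigma_P^2}$; the binormal AUC model fixes the
   group separation
   $\delta = \Phi^{-1}(0.82)\sqrt{2(\sigma^2 + \sigma_P^2)}$
   (`calibrate_group_separation()` is the general two-SD form).
2. With the 50/50 mixture variance $u = \sigma^2 + \delta^2/4$, the
   %SER target fixes the aBMD noise:
   $\sigma_B^2 = b^2\,s\,u/(u - s)$ where $s = (0.22\,\bar S)^2$, so the
   pooled regression of strength on aBMD has residual SD exactly
   $0.22\,\bar S$ in expectation.
3. The aBMD AUC then follows from
   $\Phi\!\left(b\delta / \sqrt{2(b^2\sigma^2 + \sigma_B^2)}\right)$,
   and $\sigma$ is solved so this equals 0.75.

At the defaults the solution is $\sigma \approx 810$ N,
$\delta \approx 1237$ N, $\sigma_B \approx 0.253$ g/cm². The solve fails
informatively when the targets are jointly infeasible (e.g. a density
AUC at or above the strength AUC, or an error fraction exceeding the
cohort's dispersion); nothing is silently adjusted.

The 200 N truncation sits more than three within-group SDs below the
fracture-group mean, so its effect on the calibrated moments is
negligible at the default scale; it exists to keep strengths physical
under extreme user configurations.

### Orientation of the regression errors

%SER regresses measured strength on aBMD — the only orientation that
yields an error in newtons, making the two predictors commensurate. For
%SEE both orientations yield newtons, and the choice matters: because
$P = S + \varepsilon_P$, regressing measured on predicted attenuates the
residual by $\sigma_S/\sqrt{\sigma_S^2 + \sigma_P^2}$ (about 0.90 at the
calibrated defaults, biasing a 15.5% error down to ~13.9%), whereas
regressing predicted on measured returns an unbiased estimate of
$\sigma_P$. The package therefore computes %SEE with the predicted value
as the response, which also mirrors how cadaver validation studies
orient the fit (prediction against the experimental ground truth).

### What the generator does and does not emulate

It reproduces the *statistical* structure the downstream analyses
consume: matched covariates, binormal group separation, calibrated
predictor noise. It does not model covariate effects on strength (age
and weight are matched away in the design, so nothing downstream uses
them mechanistically), disease progression, treatment-induced strength
change, or the referral filter that shapes a real secondary-care
population. In particular the case-control mix is 50% fracture-destined
by construction — far above any clinical prevalence — so pathway
projections on synthetic cohorts demonstrate *mechanics* (triage logic,
cost arithmetic, scaling) and invariants, not absolute cost-effectiveness.
Passing the recovery tests shows the estimators and the generator are
mutually consistent; it says nothing about how either predictor performs
on a real population.

## Decision rules

All thresholds classify positive (treat / fracture-predicted) at or
below the cutoff, following the WHO convention that a T-score exactly at
−2.5 already warrants intervention; the same inclusivity is applied to
strength cutoffs for consistency. The rank AUC uses the Mann–Whitney
convention (ties count ½), is computed from midranks, and treats low
scores as high risk for both predictors. Discrimination accuracy
(separating prevalent fractures) and prediction accuracy (classifying
future fractures) share one code path: they differ by who is scored, not
by formula. Body-weight conversion uses $g = 9.81$ m/s² (config-exposed;
the "four times body weight" rounding of 3000 N at a North-American
average of 80.7 kg is insensitive to the third digit of $g$).

## Screening pathways

Three pathways triage a referred population: treat T ≤ −2.5
(`dxa_tscore`); treat MSS ≤ 2551 N (`qct_ssfe`); and the dual triage —
treat T ≤ −2.5, discharge T > −1.0, resolve the osteopenic band with the
strength test (`dual`). The fracture projection is static over the
10-year horizon: each subject is or is not fracture-destined, and
treatment prevents a fixed fraction (efficacy, default 40%) of fractures
among treated destined subjects. There is no time-dependent hazard,
mortality or re-triage.

Fracture-destined status is the case/control label when projecting a
subject-level cohort; because the exact sensitivity/specificity/prevalence
model behind the published scenario's category percentages is not
printed anywhere and cannot be reverse-engineered into a single
consistent set (the implied fracture-destined totals differ between
pathways), the package also exposes a closed-form parametric mode
(`parametric_counts()`) taking prevalence, sensitivity and specificity
directly. The published scenario's *cost arithmetic* is reproduced from
its printed tallies; its category percentages are not asserted.

Tallies are carried at full precision — the pence-level detail of the
published savings rows shows the source arithmetic did the same — and
rounded (half away from zero) only at report time.

## Costs, QALYs and ICERs

Per-assessment visit totals (£251 DXA pathway, £522 strength pathway)
are used as stated totals rather than recomputed from their components,
because the printed components of the strength visit (£78 CT + £250
simulation + £189 specialist = £517) do not sum to £522; the £5 residual
is unexplained and deliberately not papered over. Assessments recur
every 2 years: `ceiling(horizon / interval)` rounds counting baseline
and excluding an end-of-horizon visit — the only reading consistent with
1000 × £251 × 5 = £1,255,000 over 10 years. The dual pathway's
triggered strength work-up (£78 + £250 = £328) is charged for each
osteopenic-band subject at every round, the only structure consistent
with the published dual assessment total (£1,899,184 ≈ £1,255,000 +
~1964 exams × £328).

No discounting is applied (the reference arithmetic is undiscounted; a
`discount_rate` hook exists and defaults to 0). QALY gain is attributed
as a one-shot (0.91 − 0.63) = 0.28 per fracture avoided — the only
reading that reproduces the published ICERs from the published cells;
the time-integration of QALYs over the horizon is otherwise unspecified.
The willingness-to-pay default is £30,000/QALY, the upper UK NICE
benchmark, since the source framing invokes "the NICE thresholds"
without a number; it is config-exposed and only the verdict flag, not
any ICER, depends on it.

`reference_pathway_results()` rebuilds all three pathways from the
shipped reference-scenario cells, recovering the fractional fracture
counts from the indirect-cost cells (indirect total ÷ £10,364). The two
fracture-cost rows imply identical counts per pathway to within 10⁻³
relative — the internal-consistency property the test suite asserts —
and the recomputed ICERs are £40,224/QALY (dual) and £368,102/QALY
(strength-for-all) against the T-score reference. A published
reduced-simulation-cost variant (£75 per simulation, ICER ~£14,656)
cannot be reproduced from any combination of the printed quantities and
is intentionally not asserted anywhere.

## Trial sizing

Two sizing paths are deliberately kept separate. The first-principles
path is the standard two-sample, two-sided normal approximation
$n = \lceil 2 (z_{1-\alpha/2} + z_{power})^2 \sigma^2 / \delta^2 \rceil$
per group (ceiled, as sample sizes conventionally are). The reproduction
path rescales a reference arm by the predictor variance ratio:
$n_{new} = \mathrm{round}(n_{ref} \cdot (\sigma_{new}/\sigma_{ref})^2)$,
rounded half up — the only rounding that maps 123 × (2199/3054)² = 63.77
to the published 64. The published absolute arm size (123 per group for
the aBMD arm at a 20% detectable strength difference) is *not*
reproducible from the standard formula with the stated inputs (which
gives 343 per group; back-solving implies a detectable difference of
about 1091 N); the reference size is therefore taken as a given input
and only the variance-ratio identity between the arms is asserted.
Whether the source calculation was one- or two-sided is unstated; the
package defaults to two-sided and exposes $\alpha$.

Trial costs are exact: $n_{total} \times$ (fixed £5000 + imaging +
simulation) per arm, giving £1,245,252 (246 patients, DXA £62) and
£681,984 (128 patients, CT £78 + simulation £250).

## Radiation risk–benefit

The chain is a product of stated factors, carried as fractions: a 2.8%
population risk of hip-fracture-related death × a 7 pp identification
gain = 0.196% of patients additionally treated; × 40% treatment efficacy
= 0.0784% death-risk reduction; against 0.0154% cancer induction per CT
(at 3.8 mSv) × 52% cancer mortality = 0.008008% added death risk.
Percent formatting (four significant figures) happens only at the
reporting boundary; zeroing any factor zeroes its dependent products.

## Numerical conventions and degenerate inputs

* Rounding half away from zero everywhere a tally or ICER is reported
  (base R's banker's rounding would map 63.5 to 64 but 62.5 to 62).
* Monetary arithmetic is double precision; every asserted equality is an
  exact integer at the magnitudes involved (≤ 10⁷, far inside exact
  double range).
* Zero QALY gain yields an undefined ICER (reported as such, never a
  number); negative gain sets a dominance flag and suppresses the ICER.
* Empty cohorts, constant regressors, single-group classifications,
  partial explicit parameter sets and infeasible calibrations all raise
  typed errors (`hipscreen_domain_error`, `hipscreen_data_error`,
  `hipscreen_config_error`); the CLI maps these to exit codes 2 and 3.
* Cohort generation scopes its RNG through `withr::with_seed()`, so a
  seeded `generate_cohort()` never perturbs the caller's random stream,
  and identical specs serialise to byte-identical files.

## Problem sizes

The stochastic checks use 5000 pairs (10,000 subjects) for target
recovery — at that size the Monte-Carlo SE of a rank AUC is ≈ 0.004, so
a ±0.01 band is a ~2.5-SE test — and 100 randomised pathway
configurations on a 400-subject cohort for the triage invariants
(superset, efficacy monotonicity, exact scaling linearity). These sizes
were chosen to make the bands meaningful rather than generous; the whole
suite runs in well under a minute.

## Known limitations

* The generator's group strength means/SDs are calibrated to the target
  AUCs, not estimated from any raw cohort (no such data are published);
  other (mean, SD) combinations could produce the same AUCs.
* The T-score distribution implied by the calibrated aBMD noise is wider
  than in a typical clinical population; triage fractions on synthetic
  cohorts are therefore illustrative, and the published scenario's
  printed tallies are the anchor for the cost arithmetic.
* The static fracture projection has no incidence dynamics, mortality or
  adherence; the efficacy parameter is a lump.
* ICERs computed on synthetic cohorts inherit the 50% case prevalence
  and are not comparable to referred-population ICERs (see the worked
  example in the README, where both appear side by side).
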