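# Synthetic pair-matched case-control cohorts.
#
# The generator emulates a retrospective postmenopausal cohort of fragility
# hip-fracture cases and non-fractured controls, pair-matched on age, weight
# and height, in which two risk predictors are available for every subject:
# a simulated finite-element minimum side-fall strength (MSS, newtons) and an
# areal bone mineral density (aBMD, g/cm^2) with its T-score.  Group strength
# distributions are normal (truncated at a positivity floor) and the two
# predictors are noisy views of the latent measured strength, so target AUC
# and prediction-error levels can be dialled in analytically.

COHORT_COLUMNS <- c(
  "subject_id", "group", "age", "weight_kg", "height_cm",
  "abmd", "t_score", "predicted_mss_n", "measured_strength_n"
)

GROUP_LEVELS <- c("fracture", "control")

#' Mean offset between groups for a target binormal AUC
#'
#' Inverts the binormal ROC model: for two normal score distributions with
#' standard deviations `sd_fracture` and `sd_control` whose means differ by
#' the returned offset, the probability that a random control scores higher
#' than a random fracture case equals `auc_target`.  Used to place the group
#' strength means so a generated cohort discriminates at a chosen AUC.
#'
#' @param auc_target Target area under the ROC curve, in `[0.5, 1)`.
#' @param sd_fracture,sd_control Score standard deviations per group
#'   (newtons for strength scores); both must be positive.
#' @return The required mean offset (same units as the SDs), `>= 0`:
#'   `qnorm(auc_target) * sqrt(sd_fracture^2 + sd_control^2)`.
#' @export
#' @examples
#' calibrate_group_separation(0.82, 718, 718)
calibrate_group_separation <- function(auc_target, sd_fracture, sd_control) {
  check_number(auc_target, "auc_target", lower = 0.5, upper = 1, allow_upper = FALSE)
  check_positive(sd_fracture, "sd_fracture")
  check_positive(sd_control, "sd_control")
  qnorm(auc_target) * sqrt(sd_fracture^2 + sd_control^2)
}

#' Within-group strength SD satisfying both AUC targets jointly
#'
#' Solves for the common within-group SD of measured strength such that, once
#' the group separation is set for the MSS AUC target and the aBMD noise is
#' set for the %SER target, the aBMD AUC also lands on its target.  The three
#' calibrations interact because both predictors are noisy views of the same
#' latent strength; a one-dimensional root solve closes the system.
#'
#' @inheritParams cohort_spec
#' @return Within-group strength SD in newtons.
#' @export
calibrate_strength_sd <- function(auc_mss = 0.82, auc_abmd = 0.75,
                                  see_fraction = 0.155, ser_fraction = 0.22,
                                  mean_strength = 3265) {
  check_number(auc_mss, "auc_mss", 0.5, 1, allow_upper = FALSE)
  check_number(auc_abmd, "auc_abmd", 0.5, 1, allow_upper = FALSE)
  check_number(see_fraction, "see_fraction", 0, 1, allow_upper = FALSE)
  check_number(ser_fraction, "ser_fraction", 0, 1,
               allow_lower = FALSE, allow_upper = FALSE)
  check_positive(mean_strength, "mean_strength")
  if (auc_abmd >= auc_mss) {
    abort_domain("`auc_abmd` must be below `auc_mss`: the density predictor is the noisier view of strength in this model.")
  }
  sn2 <- (see_fraction * mean_strength)^2
  s <- (ser_fraction * mean_strength)^2
  z1 <- qnorm(auc_mss)
  z2 <- qnorm(auc_abmd)
  gap <- function(sigma) {
    x <- sigma^2
    delta2 <- 2 * z1^2 * (x + sn2) # MSS-calibrated separation, squared
    u <- x + delta2 / 4            # marginal strength variance of the 50/50 mixture
    if (u <= s) return(NA_real_)
    w <- s * u / (u - s)           # aBMD noise variance / slope^2
    delta2 - 2 * z2^2 * (x + w)
  }
  # lower feasibility bound: marginal strength variance must exceed SER^2
  x_min <- max(0, (s - z1^2 * sn2 / 2) / (1 + z1^2 / 2))
  lo <- sqrt(x_min) * 1.001 + 1e-6
  hi <- 100 * mean_strength
  if (!is.finite(gap(lo)) || gap(lo) >= 0 || gap(hi) <= 0) {
    abort_domain("No within-group strength SD satisfies the requested AUC and error-fraction targets jointly.")
  }
  stats::uniroot(gap, c(lo, hi), tol = 1e-9)$root
}

#' Specify a synthetic case-control cohort
#'
#' Builds the fully resolved parameter set the generator consumes.  By
#' default the group strength means/SDs are calibrated so that the simulated
#' MSS predictor discriminates cases from controls at `auc_mss`, aBMD at
#' `auc_abmd`, the FE prediction error is `see_fraction` of mean strength
#' (%SEE) and the strength-on-aBMD regression error is `ser_fraction` of mean
#' strength (%SER).  Passing the four `strength_*` arguments explicitly
#' bypasses the AUC calibration.
#'
#' @param n_pairs Number of fracture/control pairs (cohort size is
#'   `2 * n_pairs`).
#' @param mean_strength Population mean femoral strength, newtons.
#' @param auc_mss,auc_abmd Target discrimination AUC of the strength and the
#'   density predictor (used only when the `strength_*` arguments are `NULL`).
#' @param see_fraction FE prediction error as a fraction of mean strength
#'   (%SEE / 100), in `[0, 1)`.
#' @param ser_fraction Strength-on-aBMD regression error as a fraction of
#'   mean strength (%SER / 100), in `[0, 1)`.
#' @param strength_mean_control,strength_mean_fracture,strength_sd_control,strength_sd_fracture
#'   Explicit per-group normal parameters (newtons); either all four or none.
#' @param tscore_reference_mean,tscore_reference_sd Young-adult femoral-neck
#'   aBMD reference (g/cm^2) used to convert aBMD to T-score.
#' @param abmd_slope,abmd_intercept Affine map from strength (N) to expected
#'   aBMD (g/cm^2); only the residual scale is constrained by `ser_fraction`,
#'   the map itself is a modelling convention.
#' @param age_min,age_max Uniform age range, years.
#' @param weight_mean,weight_sd,height_mean,height_sd Normal covariate
#'   parameters (kg, cm).
#' @param min_strength Positivity floor (newtons) at which the group normal
#'   strength distributions are truncated.
#' @param random_seed Integer seed; identical specs generate identical
#'   cohorts. `NULL` uses the current RNG state.
#' @return A `cohort_spec` list with all parameters resolved to numbers.
#' @export
#' @examples
#' spec <- cohort_spec(n_pairs = 50, random_seed = 1)
#' spec$strength_mean_control - spec$strength_mean_fracture # calibrated offset
cohort_spec <- function(n_pairs = 50,
                        mean_strength = 3265,
                        auc_mss = 0.82,
                        auc_abmd = 0.75,
                        see_fraction = 0.155,
                        ser_fraction = 0.22,
                        strength_mean_control = NULL,
                        strength_mean_fracture = NULL,
                        strength_sd_control = NULL,
                        strength_sd_fracture = NULL,
                        tscore_reference_mean = 0.942,
                        tscore_reference_sd = 0.122,
                        abmd_slope = 1 / 4000,
                        abmd_intercept = 0.2,
                        age_min = 55, age_max = 90,
                        weight_mean = 65, weight_sd = 10,
                        height_mean = 160, height_sd = 7,
                        min_strength = 200,
                        random_seed = NULL) {
  if (!is.numeric(n_pairs) || length(n_pairs) != 1L || n_pairs < 0 ||
      n_pairs != floor(n_pairs)) {
    abort_domain("`n_pairs` must be a non-negative integer.")
  }
  check_number(see_fraction, "see_fraction", 0, 1, allow_upper = FALSE)
  check_number(ser_fraction, "ser_fraction", 0, 1, allow_upper = FALSE)
  check_positive(mean_strength, "mean_strength")
  check_positive(tscore_reference_sd, "tscore_reference_sd")
  check_positive(tscore_reference_mean, "tscore_reference_mean")
  check_positive(abmd_slope, "abmd_slope")
  check_positive(weight_sd, "weight_sd")
  check_positive(height_sd, "height_sd")
  if (age_min <= 0 || age_max <= age_min) {
    abort_domain("Need 0 < age_min < age_max.")
  }

  explicit <- list(strength_mean_control, strength_mean_fracture,
                   strength_sd_control, strength_sd_fracture)
  n_given <- sum(!vapply(explicit, is.null, logical(1)))
  if (n_given == 4L) {
    check_positive(strength_sd_control, "strength_sd_control")
    check_positive(strength_sd_fracture, "strength_sd_fracture")
    check_positive(strength_mean_control, "strength_mean_control")
    check_positive(strength_mean_fracture, "strength_mean_fracture")
  } else if (n_given == 0L) {
    sigma <- calibrate_strength_sd(auc_mss, auc_abmd, see_fraction,
                                   max(ser_fraction, 1e-12), mean_strength)
    noise_sd <- see_fraction * mean_strength
    score_sd <- sqrt(sigma^2 + noise_sd^2)
    delta <- calibrate_group_separation(auc_mss, score_sd, score_sd)
    strength_mean_control <- mean_strength + delta / 2
    strength_mean_fracture <- mean_strength - delta / 2
    strength_sd_control <- sigma
    strength_sd_fracture <- sigma
  } else {
    abort_domain("Give all four `strength_*` parameters or none (AUC calibration).")
  }

  structure(list(
    n_pairs = as.integer(n_pairs),
    mean_strength = mean_strength,
    strength_mean_control = strength_mean_control,
    strength_mean_fracture = strength_mean_fracture,
    strength_sd_control = strength_sd_control,
    strength_sd_fracture = strength_sd_fracture,
    see_fraction = see_fraction,
    ser_fraction = ser_fraction,
    tscore_reference_mean = tscore_reference_mean,
    tscore_reference_sd = tscore_reference_sd,
    abmd_slope = abmd_slope,
    abmd_intercept = abmd_intercept,
    age_min = age_min, age_max = age_max,
    weight_mean = weight_mean, weight_sd = weight_sd,
    height_mean = height_mean, height_sd = height_sd,
    min_strength = min_strength,
    random_seed = if (is.null(random_seed)) NULL else as.integer(random_seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", 2L * x$n_pairs, "subjects in", x$n_pairs, "matched pairs\n")
  cat(sprintf("  strength: control N(%.0f, %.0f), fracture N(%.0f, %.0f), floor %g N\n",
              x$strength_mean_control, x$strength_sd_control,
              x$strength_mean_fracture, x$strength_sd_fracture, x$min_strength))
  cat(sprintf("  error fractions: %%SEE %.1f%%, %%SER %.1f%%\n",
              100 * x$see_fraction, 100 * x$ser_fraction))
  invisible(x)
}

# truncated-normal draw by resampling below the floor; the floor sits several
# SDs below both group means at default scale, so resampling is O(1).
rnorm_floor <- function(n, mean, sd, floor_at) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < floor_at)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < floor_at]
  }
  x
}

# aBMD residual SD implied by the %SER target, given the marginal strength
# variance of the generated mixture.  SER^2 = u * e^2 / (slope^2 u + e^2)
# => e^2 = slope^2 * SER^2 * u / (u - SER^2).
abmd_noise_sd <- function(spec) {
  if (spec$ser_fraction == 0) return(0)
  s <- (spec$ser_fraction * spec$mean_strength)^2
  delta <- spec$strength_mean_control - spec$strength_mean_fracture
  u <- (spec$strength_sd_control^2 + spec$strength_sd_fracture^2) / 2 + delta^2 / 4
  if (u <= s) {
    abort_domain("`ser_fraction` exceeds the cohort's strength dispersion; the strength-on-aBMD regression error cannot reach the target.")
  }
  spec$abmd_slope * sqrt(s * u / (u - s))
}

#' Generate a pair-matched case-control cohort
#'
#' Draws `2 * n_pairs` subjects.  Matching is by construction: each pair
#' shares one draw of (age, weight, height), so the covariate multisets of
#' the two groups are identical.  Measured strength is drawn per group from
#' the (floored) normal distributions in the spec; the FE-predicted MSS adds
#' zero-mean Gaussian noise with SD `see_fraction * mean_strength`; aBMD is
#' an affine function of measured strength plus Gaussian noise scaled so the
#' strength-on-aBMD regression error equals `ser_fraction * mean_strength`
#' in expectation; the T-score is the aBMD z-score against the young-adult
#' reference.  Identical specs (including seed) give identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per subject and columns `subject_id`,
#'   `group`, `age`, `weight_kg`, `height_cm`, `abmd`, `t_score`,
#'   `predicted_mss_n`, `measured_strength_n`, ordered fracture case then
#'   matched control within each pair.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_pairs = 5, random_seed = 42))
#' cohort
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    abort_domain("`spec` must be created with cohort_spec().")
  }
  if (!is.null(spec$random_seed)) {
    return(withr::with_seed(spec$random_seed, generate_cohort_impl(spec)))
  }
  generate_cohort_impl(spec)
}

generate_cohort_impl <- function(spec) {
  n <- spec$n_pairs
  if (n == 0L) {
    return(empty_cohort())
  }
  eps_sd <- abmd_noise_sd(spec)
  see_sd <- spec$see_fraction * spec$mean_strength

  age <- runif(n, spec$age_min, spec$age_max)
  weight <- rnorm_floor(n, spec$weight_mean, spec$weight_sd, 1)
  height <- rnorm_floor(n, spec$height_mean, spec$height_sd, 1)

  s_frac <- rnorm_floor(n, spec$strength_mean_fracture,
                        spec$strength_sd_fracture, spec$min_strength)
  s_ctrl <- rnorm_floor(n, spec$strength_mean_control,
                        spec$strength_sd_control, spec$min_strength)

  subjects <- tibble(
    pair = rep(seq_len(n), each = 2L),
    group = rep(GROUP_LEVELS, times = n),
    age = rep(age, each = 2L),
    weight_kg = rep(weight, each = 2L),
    height_cm = rep(height, each = 2L),
    measured_strength_n = as.vector(rbind(s_frac, s_ctrl))
  )
  m <- nrow(subjects)
  subjects %>%
    mutate(
      subject_id = sprintf("P%04d-%s", .data$pair,
                           ifelse(.data$group == "fracture", "F", "C")),
      predicted_mss_n = pmax(.data$measured_strength_n +
                               rnorm(m, 0, see_sd), spec$min_strength),
      abmd = pmax(spec$abmd_intercept +
                    spec$abmd_slope * .data$measured_strength_n +
                    rnorm(m, 0, eps_sd), 1e-6),
      t_score = (.data$abmd - spec$tscore_reference_mean) /
        spec$tscore_reference_sd
    ) %>%
    select(dplyr::all_of(COHORT_COLUMNS)) %>%
    new_cohort()
}

empty_cohort <- function() {
  new_cohort(tibble(
    subject_id = character(), group = character(), age = numeric(),
    weight_kg = numeric(), height_cm = numeric(), abmd = numeric(),
    t_score = numeric(), predicted_mss_n = numeric(),
    measured_strength_n = numeric()
  ))
}

new_cohort <- function(x) {
  class(x) <- unique(c("hips_cohort", class(x)))
  x
}

# Canonical group labels: matching is case-insensitive and tolerates
# surrounding whitespace; "case" is accepted as a synonym for "fracture".
normalise_group <- function(x) {
  key <- tolower(trimws(x))
  out <- dplyr::case_when(
    key %in% c("fracture", "case", "fractured") ~ "fracture",
    key %in% c("control", "no fracture", "non-fractured") ~ "control",
    TRUE ~ NA_character_
  )
  out
}

#' Write a cohort to delimited text
#'
#' @param cohort Cohort tibble (columns as produced by [generate_cohort()]).
#' @param path Destination file.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols)) {
    abort_data(paste0("Cohort is missing required column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  if (!delim %in% c(",", "\t")) abort_domain('`delim` must be "," or "\\t".')
  out <- as_tibble(cohort)[COHORT_COLUMNS]
  # full-precision numerics so the round trip is lossless
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), "", formatC(v, format = "g", digits = 17))
  })
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Read a cohort from delimited text
#'
#' Accepts comma- or tab-delimited files with a mandatory header row and the
#' exact column set written by [write_cohort()].  Group labels are normalised
#' case-insensitively to `fracture`/`control`; an empty
#' `measured_strength_n` field is read as missing.  Malformed rows raise a
#' data error naming the offending file line.
#'
#' @param path Source file.
#' @return Cohort tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort_data(paste0("Cohort file not found: ", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- suppressWarnings(readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = "c"),
    na = character(), trim_ws = TRUE, progress = FALSE,
    show_col_types = FALSE
  ))
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols)) {
    abort_data(paste0("Cohort file ", path, " is missing required column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(raw), COHORT_COLUMNS)
  if (length(extra)) {
    abort_data(paste0("Cohort file ", path, " has unknown column(s): ",
                      paste(extra, collapse = ", ")))
  }
  raw <- raw[COHORT_COLUMNS]
  if (nrow(raw) == 0L) return(empty_cohort())

  line_no <- seq_len(nrow(raw)) + 1L # header occupies line 1

  group <- normalise_group(raw$group)
  if (anyNA(group)) {
    bad <- line_no[is.na(group)]
    abort_data(paste0("Unknown group label on line(s) ",
                      paste(bad, collapse = ", "), " of ", path,
                      ' (expected "fracture" or "control").'))
  }

  parse_num <- function(col, optional = FALSE) {
    v <- raw[[col]]
    blank <- !nzchar(v) | is.na(v)
    parsed <- suppressWarnings(as.numeric(v))
    bad <- !blank & is.na(parsed)
    if (any(bad)) {
      abort_data(paste0("Non-numeric value in column `", col,
                        "` on line(s) ", paste(line_no[bad], collapse = ", "),
                        " of ", path, "."))
    }
    if (any(blank) && !optional) {
      abort_data(paste0("Missing value in column `", col, "` on line(s) ",
                        paste(line_no[blank], collapse = ", "), " of ", path, "."))
    }
    parsed
  }

  out <- tibble(
    subject_id = raw$subject_id,
    group = group,
    age = parse_num("age"),
    weight_kg = parse_num("weight_kg"),
    height_cm = parse_num("height_cm"),
    abmd = parse_num("abmd"),
    t_score = parse_num("t_score"),
    predicted_mss_n = parse_num("predicted_mss_n"),
    measured_strength_n = parse_num("measured_strength_n", optional = TRUE)
  )
  bad_pos <- with(out, which(weight_kg <= 0 | height_cm <= 0 | age <= 0 |
                               abmd <= 0 | predicted_mss_n <= 0))
  if (length(bad_pos)) {
    abort_data(paste0("Non-positive age/weight/height/aBMD/strength on line(s) ",
                      paste(line_no[bad_pos], collapse = ", "), " of ", path, "."))
  }
  new_cohort(out)
}
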