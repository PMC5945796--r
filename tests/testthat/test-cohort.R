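test_that("group-separation calibration inverts the binormal AUC model", {
  expect_equal(calibrate_group_separation(0.5, 718, 718), 0)
  # frozen against Monte-Carlo integration of the binormal overlap (below)
  expect_equal(calibrate_group_separation(0.82, 718, 718),
               qnorm(0.82) * sqrt(2) * 718, tolerance = 1e-12)
  expect_equal(calibrate_group_separation(0.82, 718, 718), 929.47, tolerance = 1e-4)
  expect_equal(calibrate_group_separation(0.75, 500, 300), 393.27, tolerance = 1e-4)

  # Monte-Carlo oracle: P(control > fracture) at the returned offset
  withr::with_seed(4711, {
    delta <- calibrate_group_separation(0.75, 500, 300)
    xf <- rnorm(4e5, 0, 500)
    xc <- rnorm(4e5, delta, 300)
    expect_equal(mean(xc > xf), 0.75, tolerance = 0.003)
  })

  expect_error(calibrate_group_separation(0.4, 1, 1), class = "hipscreen_domain_error")
  expect_error(calibrate_group_separation(1, 1, 1), class = "hipscreen_domain_error")
  expect_error(calibrate_group_separation(0.8, -1, 1), class = "hipscreen_domain_error")
})

test_that("degenerate cohort specs generate the promised edge cases", {
  empty <- generate_cohort(cohort_spec(n_pairs = 0, random_seed = 1))
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("subject_id", "group", "age", "weight_kg", "height_cm",
                        "abmd", "t_score", "predicted_mss_n",
                        "measured_strength_n"))

  no_noise <- generate_cohort(cohort_spec(
    n_pairs = 40, see_fraction = 0, strength_mean_control = 3800,
    strength_mean_fracture = 2700, strength_sd_control = 800,
    strength_sd_fracture = 800, random_seed = 5
  ))
  expect_identical(no_noise$predicted_mss_n, no_noise$measured_strength_n)
})

test_that("pairs are matched exactly and fields satisfy their invariants", {
  co <- generate_cohort(cohort_spec(n_pairs = 120, random_seed = 7))
  expect_equal(nrow(co), 240L)
  frac <- dplyr::filter(co, group == "fracture")
  ctrl <- dplyr::filter(co, group == "control")
  covs <- function(d) d[order(d$age), c("age", "weight_kg", "height_cm")]
  expect_equal(covs(frac), covs(ctrl)) # identical covariate multisets

  expect_true(all(co$age > 0 & co$weight_kg > 0 & co$height_cm > 0))
  expect_true(all(co$predicted_mss_n > 0 & co$abmd > 0))
  # T-score is exactly the aBMD z-score against the default reference
  expect_equal(co$t_score, (co$abmd - 0.942) / 0.122, tolerance = 1e-12)
})

test_that("identical specs generate bit-identical cohorts", {
  spec <- cohort_spec(n_pairs = 60, random_seed = 123)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(as.data.frame(a), as.data.frame(b))
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a, fa)
  write_cohort(b, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("generated cohorts recover their calibration targets", {
  co <- generate_cohort(cohort_spec(n_pairs = 2500, random_seed = 31))
  acc <- cohort_accuracy(co)
  # 3 Monte-Carlo standard errors of a rank AUC at n=2500/group is ~0.018
  expect_lt(abs(acc$auc_mss - 0.82), 0.018)
  expect_lt(abs(acc$auc_abmd - 0.75), 0.018)
  expect_gt(acc$pct_see, 14)
  expect_lt(acc$pct_see, 17)
})

test_that("cohort files round-trip losslessly and tolerate label variants", {
  co <- generate_cohort(cohort_spec(n_pairs = 50, random_seed = 9))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  expect_equal(as.data.frame(read_cohort(f)), as.data.frame(co), tolerance = 1e-12)

  # tab-delimited round trip
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, ft, delim = "\t")
  expect_equal(as.data.frame(read_cohort(ft)), as.data.frame(co), tolerance = 1e-12)

  # case-variant labels are normalised
  lines <- readLines(f)
  lines <- sub("fracture", "Fracture", lines)
  lines <- sub("control", "CONTROL", lines)
  writeLines(lines, f)
  expect_setequal(unique(read_cohort(f)$group), c("fracture", "control"))
})

test_that("malformed cohort files fail with located parse errors", {
  co <- generate_cohort(cohort_spec(n_pairs = 3, random_seed = 2))
  f <- withr::local_tempfile(fileext = ".csv")

  # missing column
  write_cohort(co, f)
  tab <- readr::read_csv(f, show_col_types = FALSE)
  readr::write_csv(tab[setdiff(names(tab), "t_score")], f)
  expect_error(read_cohort(f), "t_score", class = "hipscreen_data_error")

  # unknown group label, line number named (data row 2 = file line 3)
  write_cohort(co, f)
  lines <- readLines(f)
  lines[3] <- sub("control", "kontrol", lines[3])
  writeLines(lines, f)
  expect_error(read_cohort(f), "line\\(s\\) 3", class = "hipscreen_data_error")

  # non-numeric numeric field
  write_cohort(co, f)
  lines <- readLines(f)
  parts <- strsplit(lines[2], ",")[[1]]
  parts[3] <- "seventy"
  lines[2] <- paste(parts, collapse = ",")
  writeLines(lines, f)
  expect_error(read_cohort(f), "age.*line\\(s\\) 2", class = "hipscreen_data_error")

  # empty measured strength is allowed and read as missing
  write_cohort(co, f)
  tab <- readr::read_csv(f, show_col_types = FALSE)
  tab$measured_strength_n[1] <- NA
  readr::write_csv(tab, f, na = "")
  expect_true(is.na(read_cohort(f)$measured_strength_n[1]))
})

test_that("infeasible calibrations are rejected, not silently fudged", {
  expect_error(calibrate_strength_sd(auc_mss = 0.75, auc_abmd = 0.82),
               class = "hipscreen_domain_error")
  expect_error(cohort_spec(n_pairs = -1), class = "hipscreen_domain_error")
  expect_error(cohort_spec(see_fraction = 1.2), class = "hipscreen_domain_error")
  expect_error(cohort_spec(strength_mean_control = 3800),
               class = "hipscreen_domain_error") # partial explicit set
})
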