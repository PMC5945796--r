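test_that("dual triage resolves the three T-score bands with inclusive cutoffs", {
  dual <- pathway_definition("dual")
  co <- tibble::tibble(
    subject_id = c("s1", "s2", "s3", "s4"),
    group = "control",
    t_score = c(-2.5, -1.5, -0.5, -1.0),
    predicted_mss_n = c(100, 2400, 2000, 2600)
  )
  out <- triage(co, dual)
  # boundary T = -2.5 treats without a strength exam
  expect_equal(out$treat, c(TRUE, TRUE, FALSE, FALSE))
  # exam performed exactly in the osteopenic band (-2.5, -1.0]
  expect_equal(out$qct_performed, c(FALSE, TRUE, FALSE, TRUE))

  # single-test pathways
  expect_equal(triage(co, pathway_definition("dxa_tscore"))$treat,
               c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(triage(co, pathway_definition("qct_ssfe"))$treat,
               c(TRUE, TRUE, TRUE, FALSE))

  # strength needed but absent -> data error naming the subject
  broken <- co
  broken$predicted_mss_n[2] <- NA
  expect_error(triage(broken, dual), "s2", class = "hipscreen_data_error")
  expect_error(triage(broken[2, ], pathway_definition("qct_ssfe")),
               class = "hipscreen_data_error")
})

test_that("expected fractures follow the efficacy model", {
  expect_equal(expected_fractures(24, treatment_model(0.4), treated = TRUE), 14.4)
  expect_equal(expected_fractures(31, treatment_model(0.4), treated = FALSE), 31)
  expect_equal(expected_fractures(57, treatment_model(1), treated = TRUE), 0)
  expect_error(expected_fractures(-1, treatment_model(0.4), TRUE),
               class = "hipscreen_domain_error")
  expect_error(treatment_model(1.2), class = "hipscreen_domain_error")
})

test_that("run_pathway reproduces the hand-enumerated toy cohort", {
  counts <- run_pathway(toy_cohort(), pathway_definition("dual"),
                        treatment_model(0.4))
  # decisions: case1 T-3 treat; case2 band+mss2400 treat (exam);
  # control1 T-2.6 treat; control2 T-0.5 discharge
  expect_equal(counts$n_treated, 3)
  expect_equal(counts$n_qct_exams, 1)
  expect_equal(counts$fractures_treated, 2 * 0.6)
  expect_equal(counts$fractures_untreated, 0)
  expect_equal(counts$fractures_total, 1.2)
  expect_equal(counts$n_treated + counts$n_untreated, counts$n_referred)
})

test_that("projection scaling is the identity at cohort size and exactly linear", {
  co <- generate_cohort(cohort_spec(n_pairs = 150, random_seed = 12))
  raw <- run_pathway(co, pathway_definition("dual"))
  same <- run_pathway(co, pathway_definition("dual"), scale_to = nrow(co))
  expect_equal(tidy(raw), tidy(same))

  per1000 <- tidy(run_pathway(co, pathway_definition("dual"), scale_to = 1000))
  per2000 <- tidy(run_pathway(co, pathway_definition("dual"), scale_to = 2000))
  num <- vapply(per1000, is.numeric, logical(1))
  expect_equal(as.numeric(per2000[num]), 2 * as.numeric(per1000[num]))
})

test_that("pathway invariants hold across randomised configurations", {
  co <- generate_cohort(cohort_spec(n_pairs = 250, random_seed = 19))
  withr::with_seed(101, {
    for (i in 1:25) {
      treat_cut <- runif(1, -3.5, -1.6)
      safe_cut <- runif(1, -1.4, 0.5)
      mss_cut <- runif(1, 1500, 4000)
      eff <- runif(1)
      dxa <- pathway_definition("dxa_tscore", treat_cut, safe_cut, mss_cut)
      dual <- pathway_definition("dual", treat_cut, safe_cut, mss_cut)

      # the dual treated set contains the T-score treated set
      t_dxa <- triage(co, dxa)$treat
      t_dual <- triage(co, dual)$treat
      expect_true(all(t_dual[t_dxa]))

      # fractures are non-increasing in efficacy
      f1 <- run_pathway(co, dual, treatment_model(eff))$fractures_total
      f2 <- run_pathway(co, dual, treatment_model(min(1, eff + 0.2)))$fractures_total
      expect_lte(f2, f1)

      # with zero efficacy every destined subject fractures, any pathway
      f0 <- run_pathway(co, dual, treatment_model(0))$fractures_total
      expect_equal(f0, sum(co$group == "fracture"))
    }
  })
})

test_that("parametric tallies match their closed form", {
  pc <- parametric_counts(1000, prevalence = 0.5, sensitivity = 0.73,
                          specificity = 0.80, model = treatment_model(0.4))
  expect_equal(pc$n_treated, 500 * 0.73 + 500 * 0.2)
  expect_equal(pc$fractures_treated, 500 * 0.73 * 0.6)
  expect_equal(pc$fractures_untreated, 500 * 0.27)
  expect_equal(pc$n_treated + pc$n_untreated, 1000)
  expect_error(parametric_counts(0, 0.5, 0.7, 0.8),
               class = "hipscreen_domain_error")
})

test_that("degenerate pathway inputs are rejected", {
  expect_error(run_pathway(toy_cohort()[0, ], pathway_definition("dual")),
               class = "hipscreen_data_error")
  expect_error(pathway_definition("dual", tscore_treat_cutoff = -1,
                                  tscore_safe_cutoff = -2),
               class = "hipscreen_domain_error")
})
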