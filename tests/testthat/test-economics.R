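test_that("assessment rounds count the baseline and fill the horizon", {
  expect_equal(n_assessments(10, 2), 5) # forced by 1000 * £251 * 5 = £1,255,000
  expect_equal(n_assessments(10, 10), 1)
  expect_equal(n_assessments(1, 2), 1)
  expect_equal(n_assessments(9, 2), 5)
  expect_error(n_assessments(0, 2), class = "hipscreen_domain_error")
  expect_error(n_assessments(10, -1), class = "hipscreen_domain_error")
})

test_that("assessment cost reproduces the published per-pathway totals", {
  expect_equal(assessment_cost(1000, 251, 5), 1255000)
  expect_equal(assessment_cost(1000, 522, 5), 2610000)
  expect_equal(assessment_cost(0, 999, 5), 0)
  expect_equal(assessment_cost(1000, 251, 5, extra_exams = 1964, extra_per_exam = 328),
               1255000 + 1964 * 328)
})

test_that("pathway costing matches published cells from unrounded tallies", {
  costs <- default_costs
  counts <- pathway_counts(
    n_referred = 1000, n_treated = 2644898 / 7200,
    n_untreated = 1000 - 2644898 / 7200,
    fractures_treated = 147, fractures_untreated = 4801282 / 10364 - 147,
    pathway_name = "dxa_tscore"
  )
  bd <- pathway_cost(counts, costs)
  expect_equal(bd$assessment_cost, 1255000)
  expect_equal(round(bd$treatment_cost), 2644898)
  # direct cell carries a +/- GBP 1 rounding residual between the two
  # fracture-cost rows of the published table
  expect_lt(abs(bd$fracture_direct_cost - 7552151), 1.5)
  expect_equal(round(bd$fracture_indirect_cost), 4801282)
  # totals are exact sums of components, no internal re-rounding
  expect_identical(bd$total_direct,
                   bd$assessment_cost + bd$treatment_cost + bd$fracture_direct_cost)
  expect_identical(bd$total_full, bd$total_direct + bd$fracture_indirect_cost)

  none <- pathway_counts(1000, 100, 900, 0, 0, 0, "dxa_tscore")
  bd0 <- pathway_cost(none, costs)
  expect_equal(bd0$fracture_direct_cost, 0)
  expect_equal(bd0$fracture_indirect_cost, 0)
})

test_that("the dual pathway charges the triggered strength work-up per round", {
  counts <- pathway_counts(1000, 633, 286, n_qct_exams = 1963.976,
                           fractures_treated = 253,
                           fractures_untreated = 143, pathway_name = "dual")
  bd <- pathway_cost(counts, default_costs)
  # per-round exam tally is multiplied by the 5 rounds at £78 + £250 each
  expect_equal(bd$assessment_cost,
               1000 * 251 * 5 + 1963.976 * 5 * 328)
})

test_that("fracture counts are recoverable from indirect-cost totals", {
  expect_equal(fractures_from_costs(4801282, 10364), 463.26, tolerance = 1e-4)
  expect_equal(fractures_from_costs(4558045, 10364), 439.80, tolerance = 1e-4)
  expect_equal(fractures_from_costs(0, 10364), 0)
  expect_error(fractures_from_costs(100, 0), class = "hipscreen_domain_error")
})

test_that("self-comparison yields zero effect and an undefined ICER", {
  rr <- reference_pathway_results(default_costs)
  self <- compare_pathways(rr$dxa_tscore, rr$dxa_tscore, default_qaly)
  expect_equal(self$fractures_avoided, 0)
  expect_equal(self$delta_cost_full, 0)
  expect_identical(self$status, "undefined")
  expect_true(is.na(self$icer))

  # candidate worse on health -> dominance flag, no ICER
  worse <- compare_pathways(rr$dual, rr$dxa_tscore, default_qaly)
  expect_identical(worse$status, "candidate_worse_health")
  expect_true(is.na(worse$icer))
})

test_that("QALY identities hold in every comparison", {
  rr <- reference_pathway_results(default_costs)
  for (cand in c("qct_ssfe", "dual")) {
    cmp <- compare_pathways(rr$dxa_tscore, rr[[cand]], default_qaly)
    expect_equal(cmp$qaly_gained, cmp$fractures_avoided * (0.91 - 0.63))
    expect_equal(cmp$icer * cmp$qaly_gained, cmp$delta_cost_full)
  }
})

test_that("ICER is invariant under rescaling the referral base", {
  co <- generate_cohort(cohort_spec(n_pairs = 200, random_seed = 55))
  icer_at <- function(base) {
    ref <- evaluate_pathway(co, pathway_definition("dxa_tscore"), scale_to = base)
    cand <- evaluate_pathway(co, pathway_definition("dual"), scale_to = base)
    compare_pathways(ref, cand, default_qaly)$icer
  }
  expect_equal(icer_at(1000), icer_at(5000))
})

test_that("mismatched referral bases are rejected", {
  co <- generate_cohort(cohort_spec(n_pairs = 100, random_seed = 8))
  a <- evaluate_pathway(co, pathway_definition("dxa_tscore"), scale_to = 1000)
  b <- evaluate_pathway(co, pathway_definition("dual"), scale_to = 2000)
  expect_error(compare_pathways(a, b, default_qaly),
               class = "hipscreen_domain_error")
})
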