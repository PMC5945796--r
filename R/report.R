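# Pipeline stages tying the modules together: simulate a cohort, evaluate
# predictor accuracy, run the three pathways with costs and ICERs, size the
# trial comparison, run the radiation chain, and render everything into one
# report.  Each stage is an exported function over a run_config; the
# shipped command-line wrapper (inst/cli/hipscreen) is a thin layer over
# these.

#' Simulate a cohort from a configuration
#'
#' @param config A [load_config()] result.
#' @param out_file Optional path; when given the cohort is also written as
#'   delimited text with [write_cohort()].
#' @param seed Optional seed overriding `config$random_seed`.
#' @return The cohort tibble.
#' @export
run_simulate <- function(config = load_config(), out_file = NULL, seed = NULL) {
  cohort <- generate_cohort(config_cohort_spec(config, random_seed = seed))
  if (!is.null(out_file)) write_cohort(cohort, out_file)
  cohort
}

#' Accuracy fragment: both predictors, all threshold rules
#'
#' Computes [cohort_accuracy()] plus one [classify()] report per configured
#' threshold rule (T-score, absolute strength, strength cutoff used by the
#' pathways, and body-weight multiple).
#'
#' @param cohort Cohort tibble.
#' @param config A [load_config()] result.
#' @return List with `$summary` (one-row tibble) and `$rules` (one row per
#'   threshold rule).
#' @export
run_evaluate <- function(cohort, config = load_config()) {
  th <- config$thresholds
  rules <- list(
    threshold_rule("t_score", th$tscore_treat_cutoff, g = th$g),
    threshold_rule("mss_newtons", th$mss_absolute, g = th$g),
    threshold_rule("mss_newtons", th$mss_cutoff, g = th$g),
    threshold_rule("mss_bw_multiple", th$bw_multiple, g = th$g)
  )
  reports <- purrr::map(rules, ~ classify(cohort, .x))
  list(
    summary = cohort_accuracy(cohort),
    rules = purrr::map_dfr(reports, tidy)
  )
}

#' Pathway fragment: tallies, costs and ICERs for all three pathways
#'
#' Evaluates the T-score, strength and dual pathways on one cohort
#' (projected to `config$pathways$scale_to` referred patients), and
#' compares the strength and dual pathways against the T-score reference.
#'
#' @param cohort Cohort tibble.
#' @param config A [load_config()] result.
#' @return List with `$results` (named `pathway_result`s), `$table`
#'   (quantity-by-pathway tibble mirroring the published scenario layout)
#'   and `$comparisons` (named `econ_result`s vs the T-score pathway).
#' @export
run_pathways <- function(cohort, config = load_config()) {
  costs <- config_costs(config)
  model <- config_treatment(config)
  qaly <- config_qaly(config)
  scale_to <- config$pathways$scale_to
  results <- setNames(lapply(PATHWAY_NAMES, function(p) {
    evaluate_pathway(cohort, config_pathway(config, p), model, costs, scale_to)
  }), PATHWAY_NAMES)
  comparisons <- list(
    qct_ssfe = compare_pathways(results$dxa_tscore, results$qct_ssfe, qaly),
    dual = compare_pathways(results$dxa_tscore, results$dual, qaly)
  )
  list(results = results,
       table = pathway_table(results),
       comparisons = comparisons)
}

#' Quantity-by-pathway projection table
#'
#' Arranges a set of pathway results into the standard scenario layout (one
#' row per quantity, one column per pathway), with savings rows relative to
#' the first pathway in the list.  Tallies are reported rounded to the
#' nearest patient/fracture; monetary rows to the nearest pound except the
#' savings rows, which keep pence.
#'
#' @param results Named list of `pathway_result` objects; the first is the
#'   reference for the savings rows.
#' @return Tibble with a `quantity` column and one numeric column per
#'   pathway.
#' @export
pathway_table <- function(results) {
  ref <- results[[1L]]
  cols <- purrr::map(results, function(r) {
    cn <- r$counts; bd <- r$breakdown
    c(
      n_referred = round_half_up(cn$n_referred),
      n_treated = round_half_up(cn$n_treated),
      n_untreated = round_half_up(cn$n_untreated),
      fractures_treated = round_half_up(cn$fractures_treated),
      fractures_untreated = round_half_up(cn$fractures_untreated),
      fractures_total = round_half_up(cn$fractures_total),
      assessment_cost = round_half_up(bd$assessment_cost),
      treatment_cost = round_half_up(bd$treatment_cost),
      fracture_direct_cost = round_half_up(bd$fracture_direct_cost),
      total_direct = round_half_up(bd$total_direct),
      fracture_indirect_cost = round_half_up(bd$fracture_indirect_cost),
      total_full = round_half_up(bd$total_full),
      direct_saved = round_half_up(ref$breakdown$total_direct - bd$total_direct, 2),
      full_saved = round_half_up(ref$breakdown$total_full - bd$total_full, 2),
      fractures_avoided = round_half_up(ref$counts$fractures_total - cn$fractures_total)
    )
  })
  out <- tibble(quantity = names(cols[[1L]]))
  for (nm in names(cols)) out[[nm]] <- unname(cols[[nm]])
  # the reference pathway has no savings relative to itself
  out[out$quantity %in% c("direct_saved", "full_saved", "fractures_avoided"),
      names(results)[1L]] <- NA_real_
  out
}

#' Trial fragment from a configuration
#'
#' @param config A [load_config()] result.
#' @return A [trial_comparison()] tibble.
#' @export
run_trial <- function(config = load_config()) {
  do.call(trial_comparison, config$trial)
}

#' Radiation fragment from a configuration
#'
#' @param config A [load_config()] result.
#' @return A [radiation_benefit_chain()] result.
#' @export
run_radiation <- function(config = load_config()) {
  radiation_benefit_chain(config_radiation(config))
}

#' Full run: all fragments plus provenance
#'
#' @param config A [load_config()] result.
#' @param cohort Optional pre-generated cohort; by default one is simulated
#'   from the configuration.
#' @param seed Optional seed overriding `config$random_seed`.
#' @return A `run_report` list with `provenance`, `accuracy`, `pathways`,
#'   `trial` and `radiation` elements.
#' @export
#' @examples
#' \donttest{
#' report <- run_report(load_config())
#' report$pathways$table
#' }
run_report <- function(config = load_config(), cohort = NULL, seed = NULL) {
  if (is.null(cohort)) cohort <- run_simulate(config, seed = seed)
  structure(list(
    provenance = list(
      package_version = as.character(utils::packageVersion("hipscreen")),
      config_hash = rlang::hash(unclass(config)),
      random_seed = seed %||% config$random_seed,
      timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")
    ),
    config = config,
    cohort = cohort,
    accuracy = run_evaluate(cohort, config),
    pathways = run_pathways(cohort, config),
    trial = run_trial(config),
    radiation = run_radiation(config)
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> hipscreen", x$provenance$package_version,
      "| seed", x$provenance$random_seed,
      "| config", substr(x$provenance$config_hash, 1, 8), "\n")
  cat("cohort:", nrow(x$cohort), "subjects\n\n")
  print(x$accuracy$summary)
  cat("\n")
  print(x$pathways$table, n = Inf)
  cat("\n")
  for (cmp in x$pathways$comparisons) print(cmp)
  cat("\n")
  print(glance(x$trial))
  cat("\n")
  print(x$radiation)
  invisible(x)
}

md_table <- function(df) {
  fmt <- function(v) {
    if (is.numeric(v)) {
      ifelse(is.na(v), "", formatC(v, format = "fg", digits = 10, big.mark = ","))
    } else {
      as.character(v)
    }
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Render a run report as markdown (and per-table CSV)
#'
#' @param report A [run_report()] result.
#' @param out_dir Output directory (created if absent).
#' @param formats Any of `"markdown"`, `"csv"`.
#' @return Paths of the files written, invisibly.
#' @export
write_report <- function(report, out_dir, formats = c("markdown", "csv")) {
  formats <- match.arg(formats, c("markdown", "csv"), several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  if ("csv" %in% formats) {
    tables <- list(
      accuracy_summary = report$accuracy$summary,
      accuracy_rules = report$accuracy$rules,
      pathway_projection = report$pathways$table,
      econ_comparisons = purrr::map_dfr(report$pathways$comparisons, tidy),
      trial_comparison = as_tibble(report$trial)
    )
    for (nm in names(tables)) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      readr::write_csv(tables[[nm]], p, na = "")
      written <- c(written, p)
    }
  }
  if ("markdown" %in% formats) {
    rad <- report$radiation
    lines <- c(
      "# hipscreen run report",
      "",
      paste0("- package version: ", report$provenance$package_version),
      paste0("- config hash: ", report$provenance$config_hash),
      paste0("- random seed: ", report$provenance$random_seed),
      paste0("- timestamp: ", report$provenance$timestamp),
      "",
      "## Predictor accuracy",
      "", md_table(report$accuracy$summary), "",
      md_table(report$accuracy$rules), "",
      "## Screening pathway projection",
      "", md_table(report$pathways$table), "",
      "## Incremental cost-effectiveness vs the T-score pathway",
      "", md_table(purrr::map_dfr(report$pathways$comparisons, tidy)), "",
      "## Trial comparison",
      "", md_table(as_tibble(report$trial)), "",
      "## Radiation risk-benefit",
      "",
      paste0("- additional at-risk patients treated: ",
             format_percent(rad$additional_treated_fraction)),
      paste0("- hip-fracture death-risk reduction: ",
             format_percent(rad$death_risk_reduction)),
      paste0("- added radiation death risk: ",
             format_percent(rad$radiation_death_risk)),
      paste0("- net benefit: ", if (rad$net_benefit) "yes" else "no"),
      ""
    )
    p <- file.path(out_dir, "report.md")
    writeLines(lines, p)
    written <- c(written, p)
  }
  invisible(written)
}
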