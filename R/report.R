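# End-to-end pipeline commands: simulate cohorts, evaluate screening
# performance, export plot data, plan trial enrollment. Each command writes
# plain-text outputs (CSV/TSV/JSON) plus a provenance record, is
# deterministic given its arguments, and never overwrites its inputs.
# Percentages are rounded (half-up, 2 decimals) only at the report boundary.

check_out_dir <- function(out_dir, inputs = character(0)) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory `%s`.", out_dir))
  }
  inputs <- normalizePath(inputs[file.exists(inputs)], mustWork = FALSE)
  if (length(inputs) > 0 && any(dirname(inputs) == normalizePath(out_dir))) {
    abort("`out_dir` must not contain the input files (outputs never overwrite inputs).")
  }
  invisible(normalizePath(out_dir))
}

write_provenance <- function(out_dir, command, params) {
  prov <- list(
    command = command,
    package = "ptauscreen",
    version = as.character(utils::packageVersion("ptauscreen")),
    parameters = params
  )
  path <- file.path(out_dir, paste0(command, "_provenance.json"))
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Simulate synthetic CI and CU cohorts to CSV
#'
#' Generates the default-calibrated cognitively impaired (538 records) and
#' cognitively unimpaired (1610 records) synthetic cohorts -- or any supplied
#' stratum calibration -- and writes one CSV per cognitive status plus a
#' provenance JSON (seed, parameters, package version).
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param strata Stratum calibration tibble (default [default_strata()]).
#' @param lloq Lower limit of quantification (pg/mL).
#' @return Invisibly, a named character vector of written file paths.
#' @export
run_simulate <- function(out_dir, seed = 1L, strata = default_strata(),
                         lloq = 0.0693) {
  check_strata(strata)
  out_dir <- check_out_dir(out_dir)
  statuses <- unique(strata$cognitive_status)
  paths <- character(0)
  full <- generate_cohort(strata, seed = seed, lloq = lloq,
                          cohort_label = "SYNTH")
  for (st in statuses) {
    tab <- full[full$cognitive_status == st, , drop = FALSE]
    path <- file.path(out_dir, sprintf("cohort_%s.csv", tolower(st)))
    write_cohort(tab, path)
    paths[paste0("cohort_", tolower(st))] <- path
    message(sprintf("wrote %s (%d records)", path, nrow(tab)))
  }
  paths["provenance"] <- write_provenance(out_dir, "simulate", list(
    seed = seed, lloq = lloq,
    strata = as.data.frame(strata)
  ))
  invisible(paths)
}

#' Evaluate screening performance of a cohort file
#'
#' Runs the evaluation layer on a cohort CSV: per-cohort and pooled AUC
#' forest table, a Table-style screening summary at the rule-out cutoff for
#' the amyloid PET visual read reference and (when Centiloid values are
#' present) for each `CL >= threshold` reference, visual-read/Centiloid
#' concordance, and the full cutoff grid. Writes TSV tables and a JSON
#' metrics report with percentages rounded half-up to 2 decimals.
#'
#' @param input Path to a cohort CSV ([read_cohort()] schema).
#' @param out_dir Output directory.
#' @param cutoff Rule-out cutoff in pg/mL (default 0.189).
#' @param prevalence Adjustment prevalence for the visual-read reference, or
#'   `NULL` for the sample case fraction.
#' @param cl_thresholds Centiloid thresholds to evaluate (default
#'   `c(24, 40)`); ignored with a message when no Centiloid values exist.
#'   Requesting them explicitly on a cohort without Centiloid values is an
#'   error.
#' @param cl_prevalences Optional numeric vector of adjustment prevalences,
#'   one per Centiloid threshold (`NULL` = per-threshold sample fraction).
#' @param lloq Lower limit of quantification passed to [read_cohort()].
#' @return Invisibly, a named character vector of written file paths.
#' @export
run_evaluate <- function(input, out_dir, cutoff = 0.189, prevalence = NULL,
                         cl_thresholds = NULL, cl_prevalences = NULL,
                         lloq = 0.0693) {
  tab <- read_cohort(input, lloq = lloq)
  out_dir <- check_out_dir(out_dir, inputs = input)
  have_cl <- any(!is.na(tab$centiloid))
  if (!is.null(cl_thresholds) && !have_cl) {
    abort("Centiloid reference requested but the cohort has no `centiloid` values.")
  }

  forest <- auc_forest(tab)
  readr::write_tsv(tibble::as_tibble(forest), file.path(out_dir, "auc_forest.tsv"))

  summaries <- list(
    visual_read = screening_summary(tab, cutoff, prevalence = prevalence)
  )
  concord <- NULL
  if (have_cl && !is.null(cl_thresholds)) {
    for (i in seq_along(cl_thresholds)) {
      th <- cl_thresholds[i]
      sub <- tab[!is.na(tab$centiloid), , drop = FALSE]
      sub$cl_status <- as.character(classify_centiloid(sub$centiloid, th))
      pi_th <- if (!is.null(cl_prevalences)) cl_prevalences[i] else NULL
      summaries[[sprintf("cl_ge_%g", th)]] <-
        screening_summary(sub, cutoff, prevalence = pi_th, truth = cl_status)
    }
    concord <- cl_concordance(tab, cl_thresholds)
    readr::write_tsv(concord, file.path(out_dir, "cl_concordance.tsv"))
  }
  summary_tbl <- dplyr::bind_rows(summaries, .id = "reference")
  readr::write_tsv(summary_tbl, file.path(out_dir, "screening_summary.tsv"))

  grid <- cutoff_grid(tab, prevalence = prevalence)
  readr::write_tsv(grid, file.path(out_dir, "cutoff_grid.tsv"))

  pct <- function(x) round_half_up(100 * x, 2)
  report <- list(
    input = basename(input),
    n = nrow(tab),
    cutoff = cutoff,
    auc = lapply(seq_len(nrow(forest)), function(i) {
      list(label = forest$label[i], n_pos = forest$n_pos[i],
           n_neg = forest$n_neg[i], auc = round(forest$auc[i], 4),
           ci_low = round(forest$ci_low[i], 4),
           ci_high = round(forest$ci_high[i], 4))
    }),
    screening = lapply(summaries, function(sm) list(
      n = sm$n, tp = sm$tp, fn = sm$fn, fp = sm$fp, tn = sm$tn,
      prevalence_pct = pct(sm$prevalence),
      sensitivity_pct = pct(sm$sensitivity),
      specificity_pct = pct(sm$specificity),
      ppv_pct = pct(sm$ppv), npv_pct = pct(sm$npv), opa_pct = pct(sm$opa),
      screen_out_pct = pct(sm$screen_out),
      additional_screening_pct = pct(sm$additional_screening),
      scans_saved_pct = pct(sm$scans_saved)
    )),
    cl_concordance = if (!is.null(concord)) {
      lapply(seq_len(nrow(concord)), function(i) {
        list(threshold = concord$threshold[i], n = concord$n[i],
             concordance_pct = pct(concord$concordance[i]))
      })
    }
  )
  json_path <- file.path(out_dir, "metrics_report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths <- c(auc_forest = file.path(out_dir, "auc_forest.tsv"),
             screening_summary = file.path(out_dir, "screening_summary.tsv"),
             cutoff_grid = file.path(out_dir, "cutoff_grid.tsv"),
             metrics_report = json_path,
             provenance = write_provenance(out_dir, "evaluate", list(
               input = input, cutoff = cutoff, prevalence = prevalence,
               cl_thresholds = cl_thresholds, lloq = lloq
             )))
  invisible(paths)
}

#' Export integrated-risk and sensitivity/specificity plot data
#'
#' Computes the predictiveness curves (empirical and monotone estimators)
#' and the sensitivity/specificity curves for a cohort file and writes the
#' long-format plot-data TSVs, including the reference layers and the
#' rule-out cutoff marker.
#'
#' @inheritParams run_evaluate
#' @return Invisibly, a named character vector of written file paths.
#' @export
run_profile <- function(input, out_dir, cutoff = 0.189, prevalence = NULL,
                        lloq = 0.0693) {
  tab <- read_cohort(input, lloq = lloq)
  out_dir <- check_out_dir(out_dir, inputs = input)
  emp <- risk_curve(tab, prevalence = prevalence, estimator = "empirical")
  mon <- risk_curve(tab, prevalence = prevalence, estimator = "monotone")
  risk_tbl <- integrated_risk_data(emp, mon, cutoff = cutoff)
  ss <- sens_spec_curves(tab, prevalence = prevalence)
  paths <- c(
    integrated_risk = file.path(out_dir, "integrated_risk.tsv"),
    sens_spec = file.path(out_dir, "sens_spec.tsv")
  )
  readr::write_tsv(risk_tbl, paths["integrated_risk"])
  readr::write_tsv(tibble::as_tibble(ss), paths["sens_spec"])
  paths["provenance"] <- write_provenance(out_dir, "profile", list(
    input = input, cutoff = cutoff, prevalence = prevalence, lloq = lloq
  ))
  invisible(paths)
}

#' Trial-enrollment plan report
#'
#' Evaluates the pre-screening trial plan across a sweep of cognitive-status
#' mixture fractions ([trial_plan_sweep()]) and writes the sweep TSV plus a
#' JSON report with the pure-population endpoints.
#'
#' @param out_dir Output directory.
#' @param n_enroll Enrollment target (default 750).
#' @param ci,cu Per-stratum parameter lists with `sensitivity`,
#'   `specificity`, `prevalence` (e.g. taken from [screening_summary()]).
#' @param ci_fraction Mixture fractions to sweep.
#' @return Invisibly, a named character vector of written file paths.
#' @export
run_plan_trial <- function(out_dir, n_enroll = 750, ci, cu,
                           ci_fraction = seq(0, 1, by = 0.05)) {
  out_dir <- check_out_dir(out_dir)
  sweep <- trial_plan_sweep(n_enroll, ci, cu, ci_fraction = ci_fraction)
  path <- file.path(out_dir, "trial_plan_sweep.tsv")
  readr::write_tsv(sweep, path)
  pct <- function(x) round_half_up(100 * x, 2)
  ends <- list(
    n_enroll = n_enroll,
    all_cu_scans_saved_pct = pct(sweep$saved_fraction[sweep$ci_fraction == 0][1]),
    all_ci_scans_saved_pct = pct(sweep$saved_fraction[sweep$ci_fraction == 1][1])
  )
  json_path <- file.path(out_dir, "trial_plan.json")
  jsonlite::write_json(ends, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths <- c(trial_plan_sweep = path, trial_plan = json_path,
             provenance = write_provenance(out_dir, "plan_trial", list(
               n_enroll = n_enroll, ci = ci, cu = cu
             )))
  invisible(paths)
}

#' Read a YAML run configuration
#'
#' Loads a YAML file of command parameters (as used by the `inst/cli`
#' entry point) and merges it over a list of defaults; keys present in the
#' file override the defaults.
#'
#' @param path YAML file path.
#' @param defaults Named list of default parameter values.
#' @return Named list of parameters.
#' @export
read_run_config <- function(path, defaults = list()) {
  if (!file.exists(path)) abort(sprintf("config file `%s` does not exist.", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort("config file must contain a YAML mapping.")
  utils::modifyList(defaults, cfg)
}
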