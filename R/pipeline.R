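#' Pipeline configuration
#'
#' Exactly one input source must be given: a cohort CSV (with its parameter
#' file) or a synthetic-generator configuration.
#'
#' @param cohort_path,parameters_path paths to the interchange CSV files.
#' @param synthetic a [synthetic_config()].
#' @param cutoff_policy cutoff retention policy, see [validate_thresholds()].
#' @param correlation GEE working correlation, see [fit_gee()].
#' @param alpha_level significance level for term selection.
#' @param tol,max_iter GEE iteration controls.
#' @param seed integer seed (forwarded to the generator when synthetic).
#' @param outdir output directory for artifacts; created if absent.
#' @return A list of class `iui_pipeline_config`.
#' @export
pipeline_config <- function(cohort_path = NULL, parameters_path = NULL,
                            synthetic = NULL,
                            cutoff_policy = "discovery",
                            correlation = "exchangeable",
                            alpha_level = 0.05, tol = 1e-6, max_iter = 100,
                            seed = 1L, outdir = NULL) {
  if (is.null(cohort_path) == is.null(synthetic)) {
    stop_iui("provide exactly one of cohort_path or synthetic",
             class = "iui_config_error")
  }
  if (!is.null(cohort_path)) {
    if (is.null(parameters_path)) {
      stop_iui("cohort_path requires parameters_path", class = "iui_config_error")
    }
    for (f in c(cohort_path, parameters_path)) {
      if (!file.exists(f)) stop_iui("input file not found: ", f, class = "iui_io_error")
    }
  }
  assert_choice(cutoff_policy, c("discovery", "validation", "tighter"), "cutoff_policy")
  assert_choice(correlation, c("exchangeable", "independence"), "correlation")
  structure(list(cohort_path = cohort_path, parameters_path = parameters_path,
                 synthetic = synthetic, cutoff_policy = cutoff_policy,
                 correlation = correlation, alpha_level = alpha_level,
                 tol = tol, max_iter = max_iter, seed = as.integer(seed),
                 outdir = outdir),
            class = "iui_pipeline_config")
}

stage <- function(name, expr, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e) {
    stop_iui("stage '", name, "' failed: ", conditionMessage(e),
             class = "iui_stage_error")
  })
  if (verbose) {
    message(sprintf("[%s] done in %.2fs", name, proc.time()[["elapsed"]] - t0))
  }
  out
}

#' Run the full discovery-validation-GEE-policy pipeline
#'
#' Stages: read or generate the cohort, split recruitment periods, discover
#' candidate thresholds, consistency-validate them, binarize all cycles,
#' fit the exchangeable GEE, select significant terms, evaluate the
#' decline/retain policy retrospectively, and compute descriptives. When
#' `config$outdir` is set, writes `rules.json`, `gee_report.csv`,
#' `policy_report.json`, `descriptives.json`, the generated `cohort.csv`
#' (synthetic runs) and a `manifest.json` (config, seed, versions); all
#' files are deterministic under a fixed seed. Nothing is written until
#' every stage has succeeded.
#'
#' @param config an [pipeline_config()].
#' @param verbose log stage timers to standard error.
#' @return A list of class `iui_pipeline_result` with the cohort, rules,
#'   fit, Wald report, selected terms, policy and descriptives.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "iui_pipeline_config"))
  cohort <- stage("input", {
    if (!is.null(config$cohort_path)) {
      schema <- read_parameters(config$parameters_path)
      read_cohort(config$cohort_path, schema)
    } else {
      synth <- config$synthetic
      synth$seed <- config$seed
      generate_cohort(synth)
    }
  }, verbose)
  periods <- stage("split", split_periods(cohort), verbose)
  candidates <- stage("discover",
                      discover_thresholds(periods$discovery, cohort$parameters),
                      verbose)
  rules <- stage("validate",
                 validate_thresholds(candidates, periods$validation,
                                     cutoff_policy = config$cutoff_policy),
                 verbose)
  validated <- rules[rules$status == "validated", , drop = FALSE]
  aliases <- list()
  design <- stage("binarize", {
    d <- binarize(cohort, validated)
    # a validated rule that flags no cycle (or every cycle) is untestable in
    # the GEE: its column is constant and the fit would be singular
    informative <- vapply(d$flags, function(v) {
      length(unique(v[!is.na(v)])) > 1
    }, logical(1))
    if (any(!informative)) {
      message("dropping uninformative flag column(s): ",
              paste(names(d$flags)[!informative], collapse = ", "))
      validated <- validated[informative, , drop = FALSE]
      d <- binarize(cohort, validated)
    }
    # identical flag columns are one variable to the GEE; keep one
    # representative, the aliases inherit its selection outcome
    keys <- vapply(d$flags, function(v) paste(v, collapse = ","), character(1))
    if (anyDuplicated(keys)) {
      for (k in unique(keys[duplicated(keys)])) {
        grp <- names(d$flags)[keys == k]
        aliases[[grp[1]]] <- grp[-1]
      }
      message("merging duplicate flag column(s): ",
              paste(vapply(names(aliases), function(r) {
                paste0(r, " <- {", paste(aliases[[r]], collapse = ", "), "}")
              }, character(1)), collapse = "; "))
      d$flags <- d$flags[, !duplicated(keys), drop = FALSE]
    }
    d
  }, verbose)
  fit <- stage("fit", fit_gee(design, correlation = config$correlation,
                              max_iter = config$max_iter, tol = config$tol,
                              on_separation = "drop"),
               verbose)
  report <- stage("wald", wald_report(fit), verbose)
  # flags separated out of the fit predict failure deterministically on this
  # cohort (no flagged cycle is ever pregnant); they are selected by
  # construction alongside the Wald-significant terms
  selected <- stage("select", {
    sel <- union(select_significant(report, config$alpha_level),
                 fit$separated)
    for (r in intersect(sel, names(aliases))) sel <- union(sel, aliases[[r]])
    sel
  }, verbose)
  sig_rules <- validated[rule_labels(validated) %in% selected, , drop = FALSE]
  policy <- stage("evaluate", evaluate_policy(cohort, sig_rules), verbose)
  descriptives <- stage("describe", describe_cohort(cohort), verbose)
  result <- structure(list(cohort = cohort, candidates = candidates,
                           rules = rules, fit = fit, report = report,
                           selected = selected, significant_rules = sig_rules,
                           policy = policy, descriptives = descriptives,
                           config = config),
                      class = "iui_pipeline_result")
  if (!is.null(config$outdir)) write_pipeline_artifacts(result, config$outdir)
  result
}

write_pipeline_artifacts <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  config <- result$config
  write_rules(result$rules, file.path(outdir, "rules.json"))
  utils::write.csv(result$report, file.path(outdir, "gee_report.csv"),
                   row.names = FALSE, quote = FALSE)
  pol <- result$policy
  jsonlite::write_json(
    list(counts = as.list(pol$counts),
         pct_preg_retained = pol$pct_preg_retained,
         pct_nonpreg_retained = pol$pct_nonpreg_retained,
         pct_preg_declined = pol$pct_preg_declined,
         pct_nonpreg_declined = pol$pct_nonpreg_declined,
         predicted_rate = pol$predicted_rate,
         observed_rate = pol$observed_rate,
         relative_increase = pol$relative_increase,
         recommended = pol$per_cycle),
    file.path(outdir, "policy_report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  jsonlite::write_json(
    list(summary = result$descriptives$summary,
         by_cycle_index = result$descriptives$by_cycle_index),
    file.path(outdir, "descriptives.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  if (is.null(config$cohort_path)) {
    write_cohort(result$cohort, file.path(outdir, "cohort.csv"))
  }
  manifest <- list(
    package = "iuiselect",
    version = as.character(utils::packageVersion("iuiselect")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    cutoff_policy = config$cutoff_policy,
    correlation = config$correlation,
    alpha_level = config$alpha_level,
    tol = config$tol, max_iter = config$max_iter,
    input = if (is.null(config$cohort_path)) "synthetic" else config$cohort_path,
    selected_terms = result$selected)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
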