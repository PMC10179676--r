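#' Group extremes from the published threshold tables
#'
#' Long-format table of per-parameter, per-period, per-outcome-group
#' minima and maxima as printed for the two recruitment periods. The male
#' validation-period no-pregnancy block is not published (the validation
#' tables list pregnancy-group extremes only); those rows are synthetic
#' stand-ins taken from the all-patient ranges and flagged
#' `synthetic = TRUE`. They cannot affect male thresholds, which use the
#' pregnancy group in both periods.
#'
#' @return A data frame with columns
#'   `period, group, parameter, min, max, synthetic`.
#' @export
published_extremes <- function() {
  utils::read.csv(system.file("extdata", "published_extremes.csv",
                              package = "iuiselect", mustWork = TRUE))
}

#' Build a cohort realizing prescribed group extremes exactly
#'
#' For each recruitment period and outcome group, `n_per_group` singleton
#' couples are created. The first record carries every parameter's group
#' minimum and the second its maximum, so the observed group extremes equal
#' the supplied table exactly; the remaining records draw uniformly between
#' the bounds. Used as the worked-example input for threshold discovery and
#' validation when only extreme values (not patient-level data) are
#' published.
#'
#' @param extremes data frame with columns
#'   `period, group, parameter, min, max` (e.g. [published_extremes()]).
#' @param parameters a [parameter_set()] declaring every parameter named in
#'   `extremes`.
#' @param n_per_group records per (period, group) block; at least 2 so both
#'   extremes can be realized.
#' @param seed integer seed for the interior uniform draws.
#' @return An `iui_cohort` of singleton couples (one cycle each).
#' @export
fixture_from_extremes <- function(extremes, parameters = published_parameters(),
                                  n_per_group = 30, seed = 1L) {
  if (n_per_group < 2) {
    stop_iui("n_per_group must be >= 2 to realize both extremes",
             class = "iui_config_error")
  }
  need <- c("period", "group", "parameter", "min", "max")
  missing <- setdiff(need, names(extremes))
  if (length(missing)) {
    stop_iui("extremes table lacks columns: ", paste(missing, collapse = ", "),
             class = "iui_schema_error")
  }
  if (any(extremes$min > extremes$max)) {
    stop_iui("extremes with min > max", class = "iui_config_error")
  }
  unknown <- setdiff(extremes$parameter, parameters$name)
  if (length(unknown)) {
    stop_iui("extremes name parameters absent from the parameter set: ",
             paste(unique(unknown), collapse = ", "), class = "iui_schema_error")
  }
  set.seed(seed)
  blocks <- unique(extremes[c("period", "group")])
  rows <- list()
  for (b in seq_len(nrow(blocks))) {
    period <- blocks$period[b]
    group <- blocks$group[b]
    ex <- extremes[extremes$period == period & extremes$group == group, ]
    vals <- matrix(NA_real_, nrow = n_per_group, ncol = nrow(ex),
                   dimnames = list(NULL, ex$parameter))
    for (j in seq_len(nrow(ex))) {
      vals[1, j] <- ex$min[j]
      vals[2, j] <- ex$max[j]
      if (n_per_group > 2) {
        vals[3:n_per_group, j] <- stats::runif(n_per_group - 2, ex$min[j], ex$max[j])
      }
    }
    df <- data.frame(
      couple_id = sprintf("%s_%s_%03d", substr(period, 1, 1),
                          substr(group, 1, 4), seq_len(n_per_group)),
      cycle_index = 1L, period = period,
      pregnancy = group == "pregnancy", multiple_pregnancy = NA)
    rows[[b]] <- cbind(df, as.data.frame(vals))
  }
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(df) {
    for (nm in setdiff(all_cols, names(df))) df[[nm]] <- NA_real_
    df[all_cols]
  })
  cycles <- do.call(rbind, rows)
  rownames(cycles) <- NULL
  iui_cohort(cycles, parameters)
}
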