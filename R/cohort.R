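RESERVED_COLS <- c("couple_id", "cycle_index", "period", "pregnancy",
                   "multiple_pregnancy")

#' Per-cycle cohort container
#'
#' A cohort is the unit of analysis: one row per IUI cycle with the couple
#' identifier (the cluster), the 1-based cycle index (at most 4 cycles per
#' couple), the recruitment period (`"discovery"` or `"validation"`), the
#' binary clinical-pregnancy outcome, an optional multiple-pregnancy flag,
#' and one numeric column per measured parameter (missing = `NA`).
#'
#' Structural invariants enforced here: cycle indices lie in 1..4 and are
#' unique within a couple; no cycle follows a pregnancy for the same couple
#' (pregnant couples exit follow-up); a couple belongs to exactly one
#' recruitment period; `multiple_pregnancy` implies `pregnancy`; every
#' parameter column is declared in the parameter set.
#'
#' @param cycles data frame of cycles (see Details).
#' @param parameters an [parameter_set()] describing the parameter columns.
#' @return An object of class `iui_cohort`: a list with elements `cycles`
#'   and `parameters`.
#' @export
iui_cohort <- function(cycles, parameters) {
  obj <- structure(list(cycles = as.data.frame(cycles), parameters = parameters),
                   class = "iui_cohort")
  validate_cohort(obj)
}

#' @export
print.iui_cohort <- function(x, ...) {
  cy <- x$cycles
  cat(sprintf("<iui_cohort> %d cycles, %d couples, %d parameters\n",
              nrow(cy), length(unique(cy$couple_id)), nrow(x$parameters)))
  if (nrow(cy)) {
    tab <- table(cy$period)
    cat("  periods:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    cat(sprintf("  pregnancies: %d (%.2f%% per cycle)\n",
                sum(cy$pregnancy), 100 * mean(cy$pregnancy)))
  }
  invisible(x)
}

parameter_columns <- function(cohort) {
  setdiff(names(cohort$cycles), RESERVED_COLS)
}

#' Validate a cohort's structural invariants
#'
#' @param cohort an `iui_cohort`.
#' @return The cohort, invisibly unchanged, if valid; otherwise an error of
#'   class `iui_structural_error` listing every offending row.
#' @export
validate_cohort <- function(cohort) {
  cy <- cohort$cycles
  validate_parameters(cohort$parameters)
  need <- c("couple_id", "cycle_index", "period", "pregnancy")
  missing <- setdiff(need, names(cy))
  if (length(missing)) {
    stop_iui("cohort lacks columns: ", paste(missing, collapse = ", "),
             class = "iui_structural_error")
  }
  if (!"multiple_pregnancy" %in% names(cy)) cy$multiple_pregnancy <- NA
  problems <- character(0)
  row_id <- function(i) paste0("row ", i, " (couple ", cy$couple_id[i],
                               ", cycle ", cy$cycle_index[i], ")")
  bad <- which(!cy$cycle_index %in% 1:4)
  for (i in bad) problems <- c(problems, paste0(row_id(i), ": cycle_index outside 1..4"))
  bad <- which(!cy$period %in% c("discovery", "validation"))
  for (i in bad) problems <- c(problems, paste0(row_id(i), ": unknown period '",
                                                cy$period[i], "'"))
  if (!is.logical(cy$pregnancy) || anyNA(cy$pregnancy)) {
    problems <- c(problems, "pregnancy must be logical and non-missing")
  } else {
    bad <- which(!is.na(cy$multiple_pregnancy) & cy$multiple_pregnancy & !cy$pregnancy)
    for (i in bad) problems <- c(problems,
      paste0(row_id(i), ": multiple_pregnancy without pregnancy"))
  }
  dup <- duplicated(cy[c("couple_id", "cycle_index")])
  for (i in which(dup)) problems <- c(problems, paste0(row_id(i), ": duplicate (couple_id, cycle_index)"))
  extra <- setdiff(parameter_columns(cohort), cohort$parameters$name)
  if (length(extra)) {
    problems <- c(problems, paste0("undeclared parameter columns: ",
                                   paste(extra, collapse = ", ")))
  }
  if (!length(problems) && nrow(cy)) {
    for (id in unique(cy$couple_id)) {
      rows <- which(cy$couple_id == id)
      if (length(unique(cy$period[rows])) > 1L) {
        problems <- c(problems, paste0("couple ", id, " appears in both periods"))
      }
      preg_idx <- cy$cycle_index[rows][cy$pregnancy[rows]]
      if (length(preg_idx) && any(cy$cycle_index[rows] > min(preg_idx))) {
        problems <- c(problems, paste0("couple ", id, ": cycle recorded after pregnancy at cycle ",
                                       min(preg_idx)))
      }
    }
  }
  if (length(problems)) {
    stop_iui("invalid cohort:\n  ", paste(problems, collapse = "\n  "),
             class = "iui_structural_error")
  }
  invisible(cohort)
}

#' Read a per-cycle cohort from CSV
#'
#' Expects the interchange layout written by [write_cohort()]: columns
#' `couple_id, cycle_index, period, pregnancy, multiple_pregnancy`, then one
#' numeric column per parameter in `schema`. Empty cells are missing values.
#' `period` may be coded `1`/`2` or `discovery`/`validation`; `pregnancy`
#' may be coded `0`/`1` or `TRUE`/`FALSE`.
#'
#' @param path CSV file path.
#' @param schema an [parameter_set()] naming the expected parameter columns.
#' @return A validated `iui_cohort`.
#' @export
read_cohort <- function(path, schema) {
  if (!file.exists(path)) {
    stop_iui("cohort file not found: ", path, class = "iui_io_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         na.strings = "")
  need <- c("couple_id", "cycle_index", "period", "pregnancy")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop_iui("cohort CSV lacks columns: ", paste(missing, collapse = ", "),
             class = "iui_schema_error")
  }
  unknown <- setdiff(setdiff(names(raw), RESERVED_COLS), schema$name)
  if (length(unknown)) {
    stop_iui("cohort CSV has columns absent from the schema: ",
             paste(unknown, collapse = ", "), class = "iui_schema_error")
  }
  parse_num <- function(col) {
    x <- raw[[col]]
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      stop_iui("malformed numeric cell(s) in column '", col, "' at row(s) ",
               paste(bad, collapse = ", "), class = "iui_parse_error")
    }
    out
  }
  ci <- parse_num("cycle_index")
  if (any(!is.na(ci) & ci != round(ci))) {
    stop_iui("non-integer cycle_index at row(s) ",
             paste(which(!is.na(ci) & ci != round(ci)), collapse = ", "),
             class = "iui_parse_error")
  }
  cycles <- data.frame(
    couple_id = raw$couple_id,
    cycle_index = as.integer(ci),
    period = raw$period,
    pregnancy = NA,
    multiple_pregnancy = NA,
    stringsAsFactors = FALSE
  )
  mapped <- c(`1` = "discovery", `2` = "validation")[raw$period]
  cycles$period <- ifelse(is.na(mapped), raw$period, mapped)
  parse_flag <- function(col) {
    if (!col %in% names(raw)) return(rep(NA, nrow(raw)))
    x <- toupper(raw[[col]])
    out <- rep(NA, length(x))
    out[x %in% c("TRUE", "T", "1")] <- TRUE
    out[x %in% c("FALSE", "F", "0")] <- FALSE
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      stop_iui("malformed logical cell(s) in column '", col, "' at row(s) ",
               paste(bad, collapse = ", "), class = "iui_parse_error")
    }
    out
  }
  cycles$pregnancy <- parse_flag("pregnancy")
  cycles$multiple_pregnancy <- parse_flag("multiple_pregnancy")
  for (p in intersect(schema$name, names(raw))) cycles[[p]] <- parse_num(p)
  iui_cohort(cycles, schema)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: numeric cells are rendered with 17 significant
#' digits so that `read_cohort(write_cohort(c))` reproduces `c` exactly;
#' missing values become empty cells.
#'
#' @param cohort an `iui_cohort`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  cy <- cohort$cycles
  if (!"multiple_pregnancy" %in% names(cy)) cy$multiple_pregnancy <- NA
  cols <- c(RESERVED_COLS, intersect(cohort$parameters$name, names(cy)))
  cy <- cy[, cols, drop = FALSE]
  for (nm in names(cy)) {
    if (is.numeric(cy[[nm]])) {
      out <- sprintf("%.17g", cy[[nm]])
      out[is.na(cy[[nm]])] <- NA
      cy[[nm]] <- out
    }
  }
  utils::write.csv(cy, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Split a cohort into its recruitment periods
#'
#' @param cohort an `iui_cohort` containing discovery and/or validation
#'   cycles. An empty period is allowed but raises a warning.
#' @return Named list with `iui_cohort` elements `discovery` and
#'   `validation`; cycle counts always sum to the input count.
#' @export
split_periods <- function(cohort) {
  validate_cohort(cohort)
  pick <- function(p) {
    sub <- cohort$cycles[cohort$cycles$period == p, , drop = FALSE]
    rownames(sub) <- NULL
    structure(list(cycles = sub, parameters = cohort$parameters),
              class = "iui_cohort")
  }
  out <- list(discovery = pick("discovery"), validation = pick("validation"))
  for (p in names(out)) {
    if (!nrow(out[[p]]$cycles)) warning("period '", p, "' is empty", call. = FALSE)
  }
  out
}
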