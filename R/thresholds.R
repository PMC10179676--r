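#' Directional threshold rules
#'
#' A rule flags a cycle as "altered" when a parameter lies strictly beyond
#' its cutoff: above it for `direction = "upper"`, below it for
#' `direction = "lower"`. Rules are `candidate` when discovered,
#' then `validated` or `dropped` by the consistency check in the second
#' recruitment period.
#'
#' @param parameter,direction,cutoff,source_period,status,source_group
#'   vectors (recycled) defining one rule per row.
#' @return A data frame of class `iui_rules`.
#' @export
threshold_rules <- function(parameter, direction, cutoff,
                            source_period = "discovery", status = "candidate",
                            source_group = "pregnancy") {
  n <- length(parameter)
  rules <- data.frame(parameter = as.character(parameter),
                      direction = rep_len(as.character(direction), n),
                      cutoff = rep_len(as.numeric(cutoff), n),
                      source_period = rep_len(as.character(source_period), n),
                      status = rep_len(as.character(status), n),
                      source_group = rep_len(as.character(source_group), n))
  validate_rules(rules)
}

validate_rules <- function(rules) {
  stopifnot(is.data.frame(rules))
  if (any(!rules$direction %in% c("upper", "lower"))) {
    stop_iui("rule direction must be 'upper' or 'lower'", class = "iui_value_error")
  }
  if (any(!is.finite(rules$cutoff))) {
    stop_iui("rule cutoffs must be finite", class = "iui_value_error")
  }
  if (any(!rules$status %in% c("candidate", "validated", "dropped"))) {
    stop_iui("rule status must be candidate/validated/dropped",
             class = "iui_value_error")
  }
  if (anyDuplicated(rules[c("parameter", "direction")])) {
    stop_iui("duplicate (parameter, direction) rule",
             class = "iui_value_error")
  }
  class(rules) <- unique(c("iui_rules", class(rules)))
  rules
}

group_extreme <- function(cohort, parameter, pregnant) {
  cy <- cohort$cycles
  v <- cy[[parameter]][cy$pregnancy == pregnant]
  v[!is.na(v)]
}

#' Discover extreme-value threshold candidates
#'
#' For every modelled parameter and permitted direction, compares the
#' outcome groups of the discovery period. A candidate upper rule is
#' emitted when the pregnancy group's maximum lies strictly below the
#' no-pregnancy group's maximum (no pregnancy was observed above it), a
#' lower rule when the pregnancy minimum lies strictly above the
#' no-pregnancy minimum. The cutoff is the extreme of the parameter's
#' `source_group` (the pregnancy group by default; the no-pregnancy group
#' reproduces the published female-parameter convention). Missing values
#' are ignored per parameter.
#'
#' @param discovery an `iui_cohort` restricted to the discovery period,
#'   containing at least one pregnancy and one non-pregnancy cycle.
#' @param specs a [parameter_set()]; only rows with
#'   `include_in_model = TRUE` are scanned.
#' @return An `iui_rules` data frame of candidates.
#' @export
discover_thresholds <- function(discovery, specs = discovery$parameters) {
  cy <- discovery$cycles
  if (!any(cy$pregnancy)) {
    stop_iui("no pregnancies in the discovery period; no thresholds derivable",
             class = "iui_value_error")
  }
  if (all(cy$pregnancy)) {
    stop_iui("no non-pregnancy cycles in the discovery period",
             class = "iui_value_error")
  }
  out <- list()
  for (i in seq_len(nrow(specs))) {
    if (!specs$include_in_model[i]) next
    pol <- specs$direction_policy[i]
    if (pol == "none") next
    p <- specs$name[i]
    if (!p %in% names(cy)) {
      warning("parameter '", p, "' absent from the discovery data; skipped",
              call. = FALSE)
      next
    }
    preg <- group_extreme(discovery, p, TRUE)
    nopreg <- group_extreme(discovery, p, FALSE)
    if (!length(preg) || !length(nopreg)) {
      warning("parameter '", p, "' entirely missing in one group; skipped",
              call. = FALSE)
      next
    }
    src <- if (specs$source_group[i] == "pregnancy") preg else nopreg
    if (pol %in% c("upper", "both") && max(preg) < max(nopreg)) {
      out[[length(out) + 1L]] <- threshold_rules(
        p, "upper", max(src), "discovery", "candidate", specs$source_group[i])
    }
    if (pol %in% c("lower", "both") && min(preg) > min(nopreg)) {
      out[[length(out) + 1L]] <- threshold_rules(
        p, "lower", min(src), "discovery", "candidate", specs$source_group[i])
    }
  }
  if (!length(out)) {
    return(threshold_rules(character(0), character(0), numeric(0)))
  }
  validate_rules(do.call(rbind, out))
}

#' Consistency-validate candidate thresholds in the second period
#'
#' An upper candidate survives when the validation-period extreme of its
#' source group does not exceed the cutoff (boundary inclusive); a lower
#' candidate when the source-group minimum does not fall below it.
#' Surviving rules keep the discovery cutoff by default;
#' `cutoff_policy = "validation"` re-reads the cutoff from the validation
#' period's source-group extreme, and `"tighter"` keeps whichever of the
#' two flags more cycles as altered.
#'
#' @param candidates an `iui_rules` set of candidates.
#' @param validation an `iui_cohort` restricted to the validation period,
#'   containing at least one pregnancy.
#' @param cutoff_policy `"discovery"` (default), `"validation"` or
#'   `"tighter"`.
#' @return An `iui_rules` data frame with `status` set to `validated` or
#'   `dropped` and extra columns `cutoff_discovery` / `cutoff_validation`.
#' @export
validate_thresholds <- function(candidates, validation,
                                cutoff_policy = c("discovery", "validation", "tighter")) {
  cutoff_policy <- match.arg(cutoff_policy)
  if (!nrow(candidates)) {
    out <- candidates
    out$cutoff_discovery <- numeric(0)
    out$cutoff_validation <- numeric(0)
    return(out)
  }
  cy <- validation$cycles
  if (!any(cy$pregnancy)) {
    stop_iui("no pregnancies in the validation period; consistency undefined",
             class = "iui_value_error")
  }
  out <- candidates
  out$cutoff_discovery <- out$cutoff
  out$cutoff_validation <- NA_real_
  for (r in seq_len(nrow(out))) {
    p <- out$parameter[r]
    src <- if (out$source_group[r] == "pregnancy") {
      group_extreme(validation, p, TRUE)
    } else {
      group_extreme(validation, p, FALSE)
    }
    if (!p %in% names(cy) || !length(src)) {
      warning("parameter '", p, "' absent from the validation data; rule dropped",
              call. = FALSE)
      out$status[r] <- "dropped"
      next
    }
    if (out$direction[r] == "upper") {
      ext <- max(src)
      ok <- ext <= out$cutoff[r]
    } else {
      ext <- min(src)
      ok <- ext >= out$cutoff[r]
    }
    out$cutoff_validation[r] <- ext
    out$status[r] <- if (ok) "validated" else "dropped"
    if (ok && cutoff_policy != "discovery") {
      pick <- if (cutoff_policy == "validation") {
        ext
      } else if (out$direction[r] == "upper") {
        min(out$cutoff_discovery[r], ext)
      } else {
        max(out$cutoff_discovery[r], ext)
      }
      out$cutoff[r] <- pick
      if (cutoff_policy == "validation" ||
          !isTRUE(all.equal(pick, out$cutoff_discovery[r]))) {
        out$source_period[r] <- if (pick == out$cutoff_discovery[r]) "discovery" else "validation"
      }
    }
  }
  validate_rules(out)
}

#' Transform a cohort into a binary normal/altered design
#'
#' Each validated rule contributes one 0/1 column: 1 when the cycle's value
#' is strictly beyond the cutoff in the rule's direction, 0 otherwise
#' (values exactly at the cutoff are normal), `NA` when the value is
#' missing. The outcome and couple identifiers ride along for the GEE.
#'
#' @param cohort an `iui_cohort`.
#' @param rules an `iui_rules` set, all with `status = "validated"`.
#' @return An object of class `iui_design`: list with `flags` (data frame
#'   of 0/1/NA, one column per rule), `outcome` (0/1), `cluster_id`.
#' @export
binarize <- function(cohort, rules) {
  if (nrow(rules) && any(rules$status != "validated")) {
    stop_iui("binarize requires validated rules only", class = "iui_value_error")
  }
  cy <- cohort$cycles
  cols <- rule_labels(rules)
  flags <- as.data.frame(matrix(NA_real_, nrow = nrow(cy), ncol = nrow(rules),
                                dimnames = list(NULL, cols)))
  for (r in seq_len(nrow(rules))) {
    v <- cy[[rules$parameter[r]]]
    if (is.null(v)) v <- rep(NA_real_, nrow(cy))
    flags[[r]] <- if (rules$direction[r] == "upper") {
      as.numeric(v > rules$cutoff[r])
    } else {
      as.numeric(v < rules$cutoff[r])
    }
  }
  structure(list(flags = flags, outcome = as.numeric(cy$pregnancy),
                 cluster_id = cy$couple_id),
            class = "iui_design")
}

rule_labels <- function(rules) {
  if (!nrow(rules)) return(character(0))
  lab <- rules$parameter
  dup <- lab %in% lab[duplicated(lab)]
  lab[dup] <- paste(lab[dup], rules$direction[dup], sep = "_")
  lab
}

#' Read/write threshold rules
#'
#' Rules serialize to JSON (array of objects) or CSV depending on the file
#' extension.
#'
#' @param rules an `iui_rules` data frame.
#' @param path destination ending in `.json` or `.csv`.
#' @return `write_rules()` returns `path` invisibly; `read_rules()` an
#'   `iui_rules` data frame.
#' @export
write_rules <- function(rules, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(unclass(rules)), path,
                         auto_unbox = FALSE, digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(rules, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  rules <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path)
  } else {
    utils::read.csv(path)
  }
  if (is.null(rules$source_group)) rules$source_group <- "pregnancy"
  validate_rules(as.data.frame(rules))
}

#' Published validated thresholds
#'
#' The seven male and four female validated rules with their published
#' cutoffs (male age 41 y; ejaculate concentration 10.36 and total count
#' 51.79 million; ejaculate alkaline Comet 72%; swim-up immotile 45%,
#' alkaline Comet 59%, neutral Comet 65%; BMI 45 kg/m2; infertility
#' duration 84 months; LH 27.28 mUI/mL; antral follicle count 3).
#'
#' @return An `iui_rules` data frame of 11 validated rules.
#' @export
published_thresholds <- function() {
  read_rules(system.file("extdata", "published_thresholds.json",
                         package = "iuiselect", mustWork = TRUE))
}
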