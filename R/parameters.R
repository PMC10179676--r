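#' Parameter specifications
#'
#' A parameter set describes every measured covariate the pipeline may use:
#' its compartment (raw ejaculate, post-swim-up, male demographic or female),
#' measurement units, which extreme may be flagged as a threshold
#' (`direction_policy`), which outcome group's extreme defines the cutoff
#' (`source_group`), and whether the parameter enters threshold discovery and
#' the downstream model at all.
#'
#' `direction_policy = "none"` marks a parameter that is carried in the data
#' but never flagged; it forces `include_in_model = FALSE`.
#'
#' @param name character vector of unique parameter identifiers.
#' @param compartment one of `"ejaculate"`, `"swim_up"`, `"male_demographic"`,
#'   `"female"`, recycled to the length of `name`.
#' @param units non-empty character vector of measurement units.
#' @param direction_policy one of `"upper"`, `"lower"`, `"both"`, `"none"`:
#'   which extreme(s) may be flagged for this parameter.
#' @param source_group `"pregnancy"` or `"no_pregnancy"`: whose extreme value
#'   defines the cutoff.
#' @param include_in_model logical; whether the parameter participates in
#'   threshold discovery and the GEE.
#'
#' @return A data frame of class `iui_parameters`.
#' @seealso [published_parameters()] for the shipped reproduction parameter file.
#' @export
parameter_set <- function(name, compartment, units,
                          direction_policy = "none",
                          source_group = "pregnancy",
                          include_in_model = direction_policy != "none") {
  n <- length(name)
  ps <- data.frame(
    name = as.character(name),
    compartment = rep_len(as.character(compartment), n),
    units = rep_len(as.character(units), n),
    direction_policy = rep_len(as.character(direction_policy), n),
    source_group = rep_len(as.character(source_group), n),
    include_in_model = rep_len(as.logical(include_in_model), n),
    stringsAsFactors = FALSE
  )
  class(ps) <- c("iui_parameters", "data.frame")
  validate_parameters(ps)
}

validate_parameters <- function(ps) {
  stopifnot(is.data.frame(ps))
  required <- c("name", "compartment", "units", "direction_policy",
                "source_group", "include_in_model")
  missing <- setdiff(required, names(ps))
  if (length(missing)) {
    stop_iui("parameter set lacks columns: ", paste(missing, collapse = ", "),
             class = "iui_schema_error")
  }
  if (anyDuplicated(ps$name)) {
    stop_iui("duplicate parameter names: ",
             paste(unique(ps$name[duplicated(ps$name)]), collapse = ", "),
             class = "iui_schema_error")
  }
  if (any(!nzchar(ps$units))) {
    stop_iui("empty units for: ", paste(ps$name[!nzchar(ps$units)], collapse = ", "),
             class = "iui_schema_error")
  }
  bad <- !ps$compartment %in% c("ejaculate", "swim_up", "male_demographic", "female")
  if (any(bad)) {
    stop_iui("unknown compartment for: ", paste(ps$name[bad], collapse = ", "),
             class = "iui_schema_error")
  }
  bad <- !ps$direction_policy %in% c("upper", "lower", "both", "none")
  if (any(bad)) {
    stop_iui("unknown direction_policy for: ", paste(ps$name[bad], collapse = ", "),
             class = "iui_schema_error")
  }
  bad <- !ps$source_group %in% c("pregnancy", "no_pregnancy")
  if (any(bad)) {
    stop_iui("unknown source_group for: ", paste(ps$name[bad], collapse = ", "),
             class = "iui_schema_error")
  }
  none_included <- ps$direction_policy == "none" & ps$include_in_model
  if (any(none_included)) {
    stop_iui("direction_policy 'none' forces include_in_model = FALSE for: ",
             paste(ps$name[none_included], collapse = ", "),
             class = "iui_schema_error")
  }
  if (!inherits(ps, "iui_parameters")) class(ps) <- c("iui_parameters", "data.frame")
  ps
}

#' Read or write a parameter set as CSV
#'
#' Columns: `name, compartment, units, direction_policy, source_group,
#' include_in_model` (comma-separated, UTF-8, header mandatory).
#'
#' @param path file path.
#' @return `read_parameters()` returns an `iui_parameters` data frame;
#'   `write_parameters()` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) {
    stop_iui("parameter file not found: ", path, class = "iui_io_error")
  }
  ps <- utils::read.csv(path, stringsAsFactors = FALSE)
  ps$include_in_model <- as.logical(ps$include_in_model)
  class(ps) <- c("iui_parameters", "data.frame")
  validate_parameters(ps)
}

#' @rdname read_parameters
#' @param params an `iui_parameters` data frame.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  utils::write.csv(params, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Paper-reproduction parameter file
#'
#' The parameter set used to reproduce the published IUI thresholds: one
#' clinically coherent flagging direction per parameter (counts and motility
#' lower; age, immotile fraction, DNA-fragmentation and BMI upper), the
#' cutoff sourced from the pregnancy group for male parameters and from the
#' no-pregnancy group for female parameters, and semen volume plus the
#' post-swim-up yield parameters excluded from flagging.
#'
#' @return An `iui_parameters` data frame of 25 parameters.
#' @export
published_parameters <- function() {
  read_parameters(system.file("extdata", "published_parameters.csv",
                              package = "iuiselect", mustWork = TRUE))
}
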