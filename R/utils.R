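#' Log-odds and inverse log-odds
#'
#' @param p probability in (0,1).
#' @param x log-odds.
#' @return `logit(p)` returns `log(p/(1-p))`; `invlogit(x)` its inverse.
#' @export
logit <- function(p) log(p / (1 - p))

#' @rdname logit
#' @export
invlogit <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_iui <- function(..., class) {
  stop(structure(
    class = c(class, "iui_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_choice <- function(x, choices, what) {
  if (length(x) != 1L || !x %in% choices) {
    stop_iui(what, " must be one of: ", paste(choices, collapse = ", "),
             class = "iui_value_error")
  }
  x
}
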