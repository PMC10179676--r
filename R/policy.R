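#' Recommend or decline IUI for each cycle
#'
#' The eligibility rule is a conjunction over the significant validated
#' thresholds: a cycle is declined when at least `k` rules (default 1, i.e.
#' any rule) flag its value as altered. A rule whose parameter is missing
#' for a cycle abstains; with an empty rule set every cycle is recommended.
#'
#' @param cohort an `iui_cohort`.
#' @param rules an `iui_rules` set (validated, significance-filtered).
#' @param k number of altered flags needed to decline (default 1).
#' @return Logical vector, one element per cycle: `TRUE` = recommend IUI.
#' @export
recommend_iui <- function(cohort, rules, k = 1) {
  n <- nrow(cohort$cycles)
  if (!nrow(rules)) return(rep(TRUE, n))
  flags <- binarize(cohort, rules)$flags
  altered <- rowSums(flags, na.rm = TRUE)  # missing flag abstains
  altered < k
}

#' Retrospective evaluation of the eligibility policy
#'
#' Partitions all cycles by recommendation and observed pregnancy and
#' reports the four fractions as percentages of all cycles, the pregnancy
#' rate that would have been observed among retained cycles
#' (`predicted_rate`), the observed per-cycle rate, and the relative
#' increase `(predicted/observed - 1) * 100`.
#'
#' @inheritParams recommend_iui
#' @return An object of class `iui_policy`: list with `per_cycle`
#'   (recommendation vector), the four-way counts and percentages,
#'   `predicted_rate`, `observed_rate` and `relative_increase`, all
#'   unrounded percentages.
#' @export
evaluate_policy <- function(cohort, rules, k = 1) {
  cy <- cohort$cycles
  if (!nrow(cy)) stop_iui("empty cohort", class = "iui_value_error")
  rec <- recommend_iui(cohort, rules, k)
  preg <- cy$pregnancy
  n <- nrow(cy)
  counts <- c(preg_retained = sum(rec & preg),
              nonpreg_retained = sum(rec & !preg),
              preg_declined = sum(!rec & preg),
              nonpreg_declined = sum(!rec & !preg))
  pct <- 100 * counts / n
  retained <- counts[["preg_retained"]] + counts[["nonpreg_retained"]]
  observed <- 100 * sum(preg) / n
  if (retained == 0) {
    warning("no cycles retained; predicted rate undefined", call. = FALSE)
    predicted <- NA_real_
    rel <- NA_real_
  } else {
    predicted <- 100 * counts[["preg_retained"]] / retained
    rel <- relative_increase(predicted, observed)
  }
  structure(list(per_cycle = rec, counts = counts,
                 pct_preg_retained = pct[["preg_retained"]],
                 pct_nonpreg_retained = pct[["nonpreg_retained"]],
                 pct_preg_declined = pct[["preg_declined"]],
                 pct_nonpreg_declined = pct[["nonpreg_declined"]],
                 predicted_rate = predicted, observed_rate = observed,
                 relative_increase = rel, n_cycles = n),
            class = "iui_policy")
}

#' Relative pregnancy-rate increase of a policy
#'
#' @param predicted,observed per-cycle pregnancy rates in percent;
#'   `observed` must be positive.
#' @return `(predicted / observed - 1) * 100`.
#' @export
relative_increase <- function(predicted, observed) {
  if (any(observed <= 0)) {
    stop_iui("observed rate must be positive", class = "iui_value_error")
  }
  (predicted / observed - 1) * 100
}

#' @export
print.iui_policy <- function(x, ...) {
  cat("<iui_policy> retrospective evaluation over", x$n_cycles, "cycles\n")
  cat(sprintf("  retained:  pregnant %.1f%%, non-pregnant %.1f%% of all cycles\n",
              x$pct_preg_retained, x$pct_nonpreg_retained))
  cat(sprintf("  declined:  pregnant %.1f%%, non-pregnant %.1f%% of all cycles\n",
              x$pct_preg_declined, x$pct_nonpreg_declined))
  cat(sprintf("  predicted rate %.2f%% vs observed %.2f%% (relative increase %.1f%%)\n",
              x$predicted_rate, x$observed_rate, x$relative_increase))
  invisible(x)
}

#' Descriptive pregnancy statistics per period and globally
#'
#' For each recruitment period present and for the pooled cohort:
#' couples, cycles, pregnancies, per-cycle pregnancy rate
#' (`100 * pregnancies / cycles`), cumulative rate per couple
#' (`100 * pregnant couples / couples`), the multiple-pregnancy rate among
#' pregnancies, and the count of pregnancies by cycle index.
#'
#' @param cohort an `iui_cohort`.
#' @return An object of class `iui_descriptives`: list with `summary`
#'   (one row per period plus `"global"`) and `by_cycle_index` (pregnancy
#'   counts, periods x cycle index).
#' @export
describe_cohort <- function(cohort) {
  cy <- cohort$cycles
  max_k <- 4
  one <- function(sub, label) {
    if (!nrow(sub)) {
      return(list(row = NULL, byk = NULL))
    }
    preg_couples <- length(unique(sub$couple_id[sub$pregnancy]))
    n_preg <- sum(sub$pregnancy)
    n_multi <- sum(sub$multiple_pregnancy %in% TRUE)
    row <- data.frame(
      period = label,
      couples = length(unique(sub$couple_id)),
      cycles = nrow(sub),
      pregnancies = n_preg,
      rate_per_cycle = 100 * n_preg / nrow(sub),
      cumulative_rate_per_couple = 100 * preg_couples / length(unique(sub$couple_id)),
      multiple_pregnancies = n_multi,
      multiple_pregnancy_rate = if (n_preg) 100 * n_multi / n_preg else 0)
    byk <- vapply(seq_len(max_k), function(k) {
      sum(sub$pregnancy & sub$cycle_index == k)
    }, numeric(1))
    list(row = row, byk = byk)
  }
  labels <- c(intersect(c("discovery", "validation"), unique(cy$period)), "global")
  parts <- lapply(labels, function(lab) {
    sub <- if (lab == "global") cy else cy[cy$period == lab, , drop = FALSE]
    one(sub, lab)
  })
  rows <- do.call(rbind, lapply(parts, `[[`, "row"))
  byk <- do.call(rbind, lapply(parts, `[[`, "byk"))
  if (!is.null(byk)) {
    dimnames(byk) <- list(rows$period, paste0("cycle", seq_len(max_k)))
  }
  structure(list(summary = rows, by_cycle_index = byk),
            class = "iui_descriptives")
}

#' @export
print.iui_descriptives <- function(x, ...) {
  cat("<iui_descriptives>\n")
  if (is.null(x$summary)) {
    cat("  (empty cohort)\n")
    return(invisible(x))
  }
  df <- x$summary
  df$rate_per_cycle <- round(df$rate_per_cycle, 2)
  df$cumulative_rate_per_couple <- round(df$cumulative_rate_per_couple, 2)
  df$multiple_pregnancy_rate <- round(df$multiple_pregnancy_rate, 2)
  print(df, row.names = FALSE)
  cat("pregnancies by cycle index:\n")
  print(x$by_cycle_index)
  invisible(x)
}
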