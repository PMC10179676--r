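#' Covariate model for the synthetic generator
#'
#' Each parameter is drawn once per couple from a truncated normal
#' (rejection sampling) with the given mean, standard deviation and
#' truncation bounds. The shipped defaults ([published_covariates()]) reproduce
#' the published cohort's per-parameter mean/SD/min/max.
#'
#' @param parameter character vector of parameter names.
#' @param mean,sd,low,high numeric vectors (recycled); `sd >= 0`,
#'   `low <= high`.
#' @return A data frame of class `iui_covariates`.
#' @export
covariate_model <- function(parameter, mean, sd, low, high) {
  n <- length(parameter)
  cm <- data.frame(parameter = as.character(parameter),
                   mean = rep_len(as.numeric(mean), n),
                   sd = rep_len(as.numeric(sd), n),
                   low = rep_len(as.numeric(low), n),
                   high = rep_len(as.numeric(high), n))
  if (any(cm$sd < 0)) stop_iui("sd must be >= 0", class = "iui_config_error")
  if (any(cm$low > cm$high)) {
    stop_iui("truncation bounds low > high for: ",
             paste(cm$parameter[cm$low > cm$high], collapse = ", "),
             class = "iui_config_error")
  }
  class(cm) <- c("iui_covariates", "data.frame")
  cm
}

#' @rdname covariate_model
#' @export
published_covariates <- function() {
  cm <- utils::read.csv(system.file("extdata", "published_covariates.csv",
                                    package = "iuiselect", mustWork = TRUE))
  covariate_model(cm$parameter, cm$mean, cm$sd, cm$low, cm$high)
}

#' Outcome model for the synthetic generator
#'
#' Per-cycle clinical pregnancy is Bernoulli with
#' `p = logistic(intercept + b_i + sum(coefficients * covariates))`, where
#' `b_i ~ N(0, random_intercept_sd^2)` is a couple-level latent intercept
#' that induces (approximately exchangeable) within-couple outcome
#' correlation. `hard_rules` force `p = 0` for any cycle whose value lies
#' beyond a rule's cutoff, emulating parameter regions from which no
#' pregnancy is ever obtained.
#'
#' @param intercept log-odds intercept.
#' @param coefficients named numeric vector of per-unit log-odds effects
#'   (may be empty).
#' @param random_intercept_sd non-negative latent SD on the log-odds scale.
#' @param hard_rules optional [threshold_rules()] object of forcing rules.
#' @return A list of class `iui_outcome`.
#' @export
outcome_model <- function(intercept, coefficients = numeric(0),
                          random_intercept_sd = 0, hard_rules = NULL) {
  if (random_intercept_sd < 0) {
    stop_iui("random_intercept_sd must be >= 0", class = "iui_config_error")
  }
  if (length(coefficients) && is.null(names(coefficients))) {
    stop_iui("coefficients must be named by parameter", class = "iui_config_error")
  }
  structure(list(intercept = intercept, coefficients = coefficients,
                 random_intercept_sd = random_intercept_sd,
                 hard_rules = hard_rules),
            class = "iui_outcome")
}

#' Synthetic cohort configuration
#'
#' Defaults state the emulated world: two recruitment periods of 93 and 104
#' couples followed for up to 4 cycles, covariates as published, an
#' intercept giving a ~10.5% marginal per-cycle pregnancy rate under a
#' moderate couple random intercept (SD 0.8 log-odds), and a 0.64
#' probability that a non-pregnant couple returns for a further cycle
#' (which reproduces the observed ~2.1 cycles per couple).
#'
#' @param couples_discovery,couples_validation non-negative couple counts.
#' @param max_cycles maximum cycles per couple (default 4).
#' @param continuation probability in `[0,1]` that a couple without a
#'   pregnancy returns for another cycle.
#' @param covariates a [covariate_model()].
#' @param outcome an [outcome_model()].
#' @param seed integer seed; a fixed seed makes the output fully
#'   reproducible.
#' @return A list of class `iui_synth_config`.
#' @export
synthetic_config <- function(couples_discovery = 93, couples_validation = 104,
                             max_cycles = 4, continuation = 0.64,
                             covariates = published_covariates(),
                             outcome = default_outcome_model(),
                             seed = 1L) {
  if (couples_discovery < 0 || couples_validation < 0) {
    stop_iui("couple counts must be >= 0", class = "iui_config_error")
  }
  if (continuation < 0 || continuation > 1) {
    stop_iui("continuation must lie in [0,1]", class = "iui_config_error")
  }
  structure(list(couples_discovery = as.integer(couples_discovery),
                 couples_validation = as.integer(couples_validation),
                 max_cycles = as.integer(max_cycles),
                 continuation = continuation,
                 covariates = covariates, outcome = outcome,
                 seed = as.integer(seed)),
            class = "iui_synth_config")
}

#' @rdname synthetic_config
#' @export
default_outcome_model <- function() {
  # intercept solves E[logistic(b0 + 0.8 Z)] ~ 0.105 via the standard
  # logit-probit marginalization approximation b0 = logit(p)*sqrt(1+0.346 s^2)
  outcome_model(intercept = logit(0.105) * sqrt(1 + 0.346 * 0.8^2),
                random_intercept_sd = 0.8)
}

rtrunc_norm <- function(n, mean, sd, low, high) {
  if (sd == 0) return(rep(min(max(mean, low), high), n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= low & draw <= high
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

hard_rule_hit <- function(values, rules) {
  if (is.null(rules) || !nrow(rules)) return(FALSE)
  for (r in seq_len(nrow(rules))) {
    v <- values[[rules$parameter[r]]]
    if (is.null(v) || is.na(v)) next
    if (rules$direction[r] == "upper" && v > rules$cutoff[r]) return(TRUE)
    if (rules$direction[r] == "lower" && v < rules$cutoff[r]) return(TRUE)
  }
  FALSE
}

#' Generate a synthetic two-period IUI cohort
#'
#' Covariates are drawn once per couple (ages, BMI and basal hormone levels
#' are measured once in practice; per-cycle semen variability is not
#' modelled). Each couple is then followed cycle by cycle: the pregnancy
#' probability comes from the logistic outcome model with the couple's
#' latent intercept, a pregnancy ends follow-up, and a non-pregnant couple
#' returns with probability `continuation`, up to `max_cycles` cycles.
#'
#' @param config a [synthetic_config()].
#' @param parameters optional [parameter_set()]; defaults to
#'   [published_parameters()] restricted to the covariate-model parameters.
#' @return A validated `iui_cohort`.
#' @export
generate_cohort <- function(config, parameters = NULL) {
  stopifnot(inherits(config, "iui_synth_config"))
  if (is.null(parameters)) {
    pp <- published_parameters()
    parameters <- pp[pp$name %in% config$covariates$parameter, , drop = FALSE]
    extra <- setdiff(config$covariates$parameter, pp$name)
    if (length(extra)) {
      parameters <- rbind(parameters,
                          parameter_set(extra, "female", "arbitrary", "none",
                                        "pregnancy", FALSE))
    }
    parameters <- validate_parameters(parameters)
  }
  set.seed(config$seed)
  cm <- config$covariates
  om <- config$outcome
  ids <- list(); n_cy <- list(); outc <- list(); vals_rows <- list(); per <- list()
  for (period in c("discovery", "validation")) {
    n_couples <- if (period == "discovery") config$couples_discovery else config$couples_validation
    for (i in seq_len(n_couples)) {
      vals <- stats::setNames(
        vapply(seq_len(nrow(cm)), function(k) {
          rtrunc_norm(1, cm$mean[k], cm$sd[k], cm$low[k], cm$high[k])
        }, numeric(1)),
        cm$parameter)
      b <- stats::rnorm(1, 0, om$random_intercept_sd)
      eta <- om$intercept + b
      for (nm in names(om$coefficients)) {
        eta <- eta + om$coefficients[[nm]] * vals[[nm]]
      }
      p <- if (hard_rule_hit(as.list(vals), om$hard_rules)) 0 else invlogit(eta)
      y <- logical(0)
      for (k in seq_len(config$max_cycles)) {
        y[k] <- stats::runif(1) < p
        if (y[k]) break
        if (k < config$max_cycles && stats::runif(1) > config$continuation) break
      }
      j <- length(ids) + 1L
      ids[[j]] <- sprintf("%s_%04d", substr(period, 1, 1), i)
      n_cy[[j]] <- length(y)
      outc[[j]] <- y
      vals_rows[[j]] <- vals
      per[[j]] <- period
    }
  }
  n_cy <- unlist(n_cy) %||% integer(0)
  cycles <- data.frame(
    couple_id = rep(unlist(ids) %||% character(0), n_cy),
    cycle_index = unlist(lapply(n_cy, seq_len)) %||% integer(0),
    period = rep(unlist(per) %||% character(0), n_cy),
    pregnancy = unlist(outc) %||% logical(0),
    multiple_pregnancy = rep(NA, sum(n_cy)),
    stringsAsFactors = FALSE)
  if (length(vals_rows)) {
    vm <- do.call(rbind, vals_rows)[rep(seq_along(n_cy), n_cy), , drop = FALSE]
    cycles <- cbind(cycles, as.data.frame(vm))
  }
  rownames(cycles) <- NULL
  iui_cohort(cycles, parameters)
}

#' Deterministic cohort with exact marginal counts
#'
#' Builds a single-period cohort reproducing stated totals exactly: number
#' of couples and cycles, pregnancies (optionally split by the cycle index
#' at which they occurred) and multiple pregnancies. Pregnant couples get
#' failure cycles followed by the pregnancy cycle; remaining cycles are
#' spread over the non-pregnant couples (1 to `max_cycles` each). No
#' parameter columns are attached.
#'
#' Used to reproduce the published cohort's descriptive statistics, whose
#' exact per-couple structure is otherwise unrecoverable from the printed
#' totals.
#'
#' @param couples,cycles,pregnancies non-negative integers.
#' @param preg_by_cycle integer vector summing to `pregnancies`: how many
#'   pregnancies occurred at each cycle index (default: all at cycle 1).
#' @param multiples number of pregnancies that were multiple.
#' @param period `"discovery"` or `"validation"`.
#' @param max_cycles maximum cycles per couple.
#' @param id_prefix prefix for generated couple identifiers.
#' @return An `iui_cohort` with an empty parameter set.
#' @export
cohort_from_counts <- function(couples, cycles, pregnancies,
                               preg_by_cycle = NULL, multiples = 0,
                               period = "discovery", max_cycles = 4,
                               id_prefix = substr(period, 1, 1)) {
  if (is.null(preg_by_cycle)) {
    preg_by_cycle <- c(pregnancies, rep(0, max_cycles - 1))
  }
  if (sum(preg_by_cycle) != pregnancies) {
    stop_iui("preg_by_cycle must sum to pregnancies", class = "iui_config_error")
  }
  if (pregnancies > couples) {
    stop_iui("more pregnancies than couples", class = "iui_config_error")
  }
  preg_cycles <- sum(preg_by_cycle * seq_along(preg_by_cycle))
  n_free <- couples - pregnancies
  rest <- cycles - preg_cycles
  if (rest < n_free || rest > n_free * max_cycles) {
    stop_iui("cycle total ", cycles, " infeasible for ", couples, " couples with ",
             pregnancies, " pregnancies", class = "iui_config_error")
  }
  rows <- list()
  cid <- 0
  add_couple <- function(n_cycles, pregnant, multiple) {
    cid <<- cid + 1
    id <- sprintf("%s%04d", id_prefix, cid)
    for (k in seq_len(n_cycles)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        couple_id = id, cycle_index = k, period = period,
        pregnancy = pregnant && k == n_cycles,
        multiple_pregnancy = if (pregnant && k == n_cycles) multiple else NA)
    }
  }
  m <- 0
  for (k in seq_along(preg_by_cycle)) {
    for (j in seq_len(preg_by_cycle[k])) {
      m <- m + 1
      add_couple(k, TRUE, m <= multiples)
    }
  }
  # spread the remaining cycles: start everyone at 1, then top up round-robin
  alloc <- rep(1L, n_free)
  extra <- rest - n_free
  i <- 1
  while (extra > 0) {
    if (alloc[i] < max_cycles) {
      alloc[i] <- alloc[i] + 1L
      extra <- extra - 1
    }
    i <- if (i == n_free) 1 else i + 1
  }
  for (n_cycles in alloc) add_couple(n_cycles, FALSE, FALSE)
  cycles_df <- do.call(rbind, rows)
  iui_cohort(cycles_df, parameter_set(character(0), character(0), character(0)))
}

#' Two-period cohort matching the published recruitment counts
#'
#' Discovery period: 93 couples, 193 cycles, 18 pregnancies (by cycle index
#' 9/4/2/3 - the published split 8/4/2/3 sums to 17 of 18, the unplaced
#' pregnancy is put in cycle 1), 2 multiple. Validation period: 104
#' couples, 216 cycles, 25 pregnancies (10/7/7/1), 5 multiple.
#'
#' @return An `iui_cohort` with 409 cycles and no parameter columns.
#' @export
published_counts_cohort <- function() {
  d <- cohort_from_counts(93, 193, 18, preg_by_cycle = c(9, 4, 2, 3),
                          multiples = 2, period = "discovery")
  v <- cohort_from_counts(104, 216, 25, preg_by_cycle = c(10, 7, 7, 1),
                          multiples = 5, period = "validation")
  iui_cohort(rbind(d$cycles, v$cycles), d$parameters)
}

#' Empirical within-couple outcome correlation
#'
#' Moment estimator over all within-couple cycle pairs:
#' `mean((y_j - ybar) (y_k - ybar)) / var(y)`, with the grand mean and the
#' population variance taken over every cycle. Approximates the
#' exchangeable association the GEE working structure assumes.
#'
#' @param cohort an `iui_cohort` with at least two couples contributing two
#'   or more cycles each, or a list with elements `outcome` and
#'   `cluster_id` (test instrumentation: a valid cohort cannot contain
#'   repeated pregnancies, so some degenerate correlation patterns are only
#'   reachable through a raw design).
#' @return The pairwise correlation estimate (may be negative).
#' @export
empirical_icc <- function(cohort) {
  cy <- if (inherits(cohort, "iui_cohort")) {
    data.frame(couple_id = cohort$cycles$couple_id,
               pregnancy = cohort$cycles$pregnancy)
  } else {
    data.frame(couple_id = cohort$cluster_id, pregnancy = cohort$outcome)
  }
  y <- as.numeric(cy$pregnancy)
  ybar <- mean(y)
  v <- mean((y - ybar)^2)
  if (v == 0) stop_iui("outcome is constant; ICC undefined", class = "iui_value_error")
  cross <- 0
  npair <- 0
  multi <- 0
  for (id in unique(cy$couple_id)) {
    e <- y[cy$couple_id == id] - ybar
    n <- length(e)
    if (n < 2) next
    multi <- multi + 1
    cross <- cross + (sum(e)^2 - sum(e^2)) / 2
    npair <- npair + n * (n - 1) / 2
  }
  if (multi < 2) {
    stop_iui("need >= 2 couples with >= 2 cycles for the ICC",
             class = "iui_value_error")
  }
  (cross / npair) / v
}
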