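test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(couples_discovery = 20, couples_validation = 20,
                          seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(synthetic_config(couples_discovery = 20,
                                         couples_validation = 20, seed = 12))
  expect_false(identical(a$cycles, c2$cycles))
})

test_that("covariates respect truncation bounds and are couple-constant", {
  co <- generate_cohort(synthetic_config(couples_discovery = 40,
                                         couples_validation = 0, seed = 5))
  cm <- published_covariates()
  for (j in seq_len(nrow(cm))) {
    v <- co$cycles[[cm$parameter[j]]]
    expect_true(all(v >= cm$low[j] & v <= cm$high[j]), label = cm$parameter[j])
  }
  per_couple <- tapply(co$cycles$male_age, co$cycles$couple_id,
                       function(v) length(unique(v)))
  expect_true(all(per_couple == 1))
})

test_that("intercept-only rate matches the closed-form binomial mean", {
  p <- 0.105
  cfg <- synthetic_config(
    couples_discovery = 10000, couples_validation = 0, max_cycles = 1,
    covariates = covariate_model("x", 0, 1, -3, 3),
    outcome = outcome_model(logit(p), random_intercept_sd = 0), seed = 21)
  co <- generate_cohort(cfg)
  mc_se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(mean(co$cycles$pregnancy) - p), 3 * mc_se)
})

test_that("hard rules force zero pregnancies beyond the cutoff", {
  hard <- threshold_rules("male_age", "upper", 41, status = "validated")
  cfg <- synthetic_config(
    couples_discovery = 1500, couples_validation = 0, max_cycles = 4,
    outcome = outcome_model(logit(0.3), random_intercept_sd = 0.5,
                            hard_rules = hard), seed = 8)
  co <- generate_cohort(cfg)
  expect_gt(nrow(co$cycles), 2500)
  hit <- co$cycles$male_age > 41
  expect_gt(sum(hit), 0)
  expect_equal(sum(co$cycles$pregnancy[hit]), 0)
  expect_gt(sum(co$cycles$pregnancy[!hit]), 0)
})

test_that("cycle structure: pregnancy ends follow-up, never more than 4 cycles", {
  co <- generate_cohort(synthetic_config(couples_discovery = 60,
                                         couples_validation = 60, seed = 2))
  expect_silent(validate_cohort(co))  # includes the no-cycle-after-pregnancy scan
  expect_true(all(co$cycles$cycle_index <= 4))
})

test_that("empirical ICC behaves at the independence and perfect-agreement limits", {
  cfg <- synthetic_config(couples_discovery = 3000, couples_validation = 0,
                          continuation = 1,
                          covariates = covariate_model("x", 0, 1, -3, 3),
                          outcome = outcome_model(logit(0.3),
                                                  random_intercept_sd = 0),
                          seed = 13)
  co <- generate_cohort(cfg)
  expect_lt(abs(empirical_icc(co)), 0.03)

  # perfect within-couple agreement -> ICC exactly 1 (raw design: a valid
  # cohort cannot hold repeated pregnancies, follow-up stops at the first)
  agree <- list(outcome = rep(c(0, 1), each = 3),
                cluster_id = rep(c("a", "b"), each = 3))
  expect_equal(empirical_icc(agree), 1)

  # degenerate inputs are signalled
  expect_error(empirical_icc(list(outcome = rep(0, 6),
                                  cluster_id = rep(c("a", "b"), each = 3))),
               "constant", class = "iui_value_error")
  expect_error(empirical_icc(list(outcome = c(0, 1), cluster_id = c("a", "b"))),
               ">= 2 couples", class = "iui_value_error")
})

test_that("empirical ICC matches a direct simulation of the same latent model", {
  # independent oracle: re-simulate the generative law (couple random
  # intercept, stop at first pregnancy, 4-cycle cap) with its own code and
  # estimate the pairwise correlation by brute force over couples
  sim_icc <- function(seed, sd_b, intercept, n) {
    set.seed(seed)
    ys <- vector("list", n)
    for (i in seq_len(n)) {
      p <- plogis(intercept + rnorm(1, 0, sd_b))
      y <- integer(0)
      for (k in 1:4) {
        y[k] <- rbinom(1, 1, p)
        if (y[k] == 1) break
      }
      ys[[i]] <- y
    }
    all_y <- unlist(ys)
    ybar <- mean(all_y); v <- mean((all_y - ybar)^2)
    cross <- 0; npair <- 0
    for (y in ys) {
      e <- y - ybar
      if (length(e) < 2) next
      cross <- cross + (sum(e)^2 - sum(e^2)) / 2
      npair <- npair + length(e) * (length(e) - 1) / 2
    }
    (cross / npair) / v
  }
  oracle <- sim_icc(31, 2, -2, 4000)
  cfg <- synthetic_config(
    couples_discovery = 4000, couples_validation = 0, continuation = 1,
    covariates = covariate_model("x", 0, 1, -3, 3),
    outcome = outcome_model(-2, random_intercept_sd = 2), seed = 77)
  got <- empirical_icc(generate_cohort(cfg))
  expect_gt(got, 0.03)               # correlation present
  expect_lt(abs(got - oracle), 0.04) # agrees with the independent simulation
})

test_that("cohort_from_counts reproduces stated totals exactly", {
  co <- cohort_from_counts(93, 193, 18, preg_by_cycle = c(9, 4, 2, 3),
                           multiples = 2, period = "discovery")
  cy <- co$cycles
  expect_equal(length(unique(cy$couple_id)), 93)
  expect_equal(nrow(cy), 193)
  expect_equal(sum(cy$pregnancy), 18)
  expect_equal(sum(cy$multiple_pregnancy %in% TRUE), 2)
  expect_equal(as.vector(table(cy$cycle_index[cy$pregnancy])[c("1", "2", "3", "4")]),
               c(9, 4, 2, 3))
  expect_error(cohort_from_counts(10, 45, 0), "infeasible",
               class = "iui_config_error")
})

test_that("extreme fixtures realize the requested group extremes exactly", {
  ex <- data.frame(period = rep(c("discovery", "validation"), each = 4),
                   group = rep(c("pregnancy", "no_pregnancy"), 4),
                   parameter = rep(c("x", "x", "w", "w"), 2),
                   min = c(2, 1, 5, 5, 3, 0, 5, 4),
                   max = c(4, 6, 5, 9, 3.5, 7, 5, 8))
  ps <- toy_params(c("x", "w"))
  fx <- fixture_from_extremes(ex, ps, n_per_group = 9, seed = 4)
  # brute-force min/max scan per block must equal the input table
  for (i in seq_len(nrow(ex))) {
    sub <- fx$cycles[fx$cycles$period == ex$period[i] &
                     fx$cycles$pregnancy == (ex$group[i] == "pregnancy"), ]
    expect_equal(min(sub[[ex$parameter[i]]]), ex$min[i])
    expect_equal(max(sub[[ex$parameter[i]]]), ex$max[i])
  }
  # degenerate min = max: the whole block is constant
  sub <- fx$cycles[fx$cycles$period == "discovery" & fx$cycles$pregnancy, ]
  expect_true(all(sub$w == 5))
  expect_error(fixture_from_extremes(ex, ps, n_per_group = 1),
               "n_per_group", class = "iui_config_error")
})

test_that("the shipped extremes table matches the published all-patient ranges", {
  ex <- published_extremes()
  cm <- published_covariates()
  # discovery-period group ranges must lie inside the all-patient bounds
  d <- ex[ex$period == "discovery", ]
  for (i in seq_len(nrow(d))) {
    b <- cm[cm$parameter == d$parameter[i], ]
    expect_gte(d$min[i], b$low)
    expect_lte(d$max[i], b$high)
  }
})
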