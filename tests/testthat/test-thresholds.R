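published_rules_run <- function(cutoff_policy = "discovery", n_per_group = 8,
                            seed = 2) {
  fx <- fixture_from_extremes(published_extremes(), n_per_group = n_per_group,
                              seed = seed)
  per <- split_periods(fx)
  cand <- discover_thresholds(per$discovery, fx$parameters)
  list(candidates = cand,
       rules = validate_thresholds(cand, per$validation,
                                   cutoff_policy = cutoff_policy))
}

get_rule <- function(rules, parameter) {
  rules[rules$parameter == parameter, , drop = FALSE]
}

test_that("discovery flags group extremes strictly contained in the other group", {
  # toy data {preg: 2,3,4; no-preg: 1,5}: brute-force group min/max comparison
  preg <- c(2, 3, 4); nopreg <- c(1, 5)
  co <- toy_cohort(disc_preg = preg, disc_nopreg = nopreg, val_preg = 3)
  cand <- discover_thresholds(split_periods(co)$discovery, co$parameters)
  expect_setequal(cand$direction, c("lower", "upper"))
  expect_equal(get_rule(cand, "x")$cutoff[get_rule(cand, "x")$direction == "lower"],
               min(preg))  # 2, since min(preg) > min(nopreg)
  expect_equal(get_rule(cand, "x")$cutoff[get_rule(cand, "x")$direction == "upper"],
               max(preg))  # 4, since max(preg) < max(nopreg)
  expect_true(all(cand$status == "candidate"))
})

test_that("ties defeat the strict-containment condition", {
  # pregnancy max equals no-pregnancy max: no upper rule
  co <- toy_cohort(disc_preg = c(33, 90), disc_nopreg = c(23, 90), val_preg = 50,
                   direction = "upper")
  cand <- discover_thresholds(split_periods(co)$discovery, co$parameters)
  expect_equal(nrow(cand), 0)
})

test_that("discovery requires both outcome groups and handles missingness", {
  co <- toy_cohort(disc_preg = numeric(0), disc_nopreg = c(1, 2), val_preg = 1)
  expect_error(discover_thresholds(split_periods(co)$discovery, co$parameters),
               "no pregnancies", class = "iui_value_error")
  co2 <- toy_cohort(disc_preg = c(2, 3), disc_nopreg = c(1, 5), val_preg = 2)
  co2$cycles$x[co2$cycles$period == "discovery" & co2$cycles$pregnancy] <- NA
  expect_warning(
    cand <- discover_thresholds(split_periods(co2)$discovery, co2$parameters),
    "entirely missing")
  expect_equal(nrow(cand), 0)
})

test_that("validation is boundary-inclusive and keeps the discovery cutoff", {
  # upper candidate 41; validation pregnancy max exactly 41 -> survives
  co <- toy_cohort(disc_preg = c(26, 41), disc_nopreg = c(26, 44),
                   val_preg = c(25, 41), direction = "upper")
  run <- validate_thresholds(
    discover_thresholds(split_periods(co)$discovery, co$parameters),
    split_periods(co)$validation)
  expect_equal(run$status, "validated")
  expect_equal(run$cutoff, 41)
  # lower candidate 18; validation pregnancy min 6 -> dropped
  co2 <- toy_cohort(disc_preg = c(18, 74), disc_nopreg = c(5, 86),
                    val_preg = c(6, 79), direction = "lower")
  run2 <- validate_thresholds(
    discover_thresholds(split_periods(co2)$discovery, co2$parameters),
    split_periods(co2)$validation)
  expect_equal(run2$status, "dropped")
})

test_that("empty candidate sets and absent parameters are handled", {
  co <- toy_cohort(disc_preg = 1, disc_nopreg = 2, val_preg = 1)
  empty <- threshold_rules(character(0), character(0), numeric(0))
  out <- validate_thresholds(empty, split_periods(co)$validation)
  expect_equal(nrow(out), 0)
  ghost <- threshold_rules("nope", "upper", 10)
  expect_warning(
    out2 <- validate_thresholds(ghost, split_periods(co)$validation),
    "absent")
  expect_equal(out2$status, "dropped")
})

test_that("self-consistency: discovery data never contradicts its own extremes", {
  for (seed in 1:8) {
    co <- random_cohort(seed, n_couples = 16)
    disc <- split_periods(co)$discovery
    if (!any(disc$cycles$pregnancy) || all(disc$cycles$pregnancy)) next
    cand <- discover_thresholds(disc, co$parameters)
    if (!nrow(cand)) next
    res <- validate_thresholds(cand, disc)  # validate against the same period
    expect_true(all(res$status == "validated"), label = paste("seed", seed))
  }
})

test_that("emitted rules always have the pregnancy extreme strictly inside", {
  for (seed in 11:18) {
    co <- random_cohort(seed, n_couples = 16)
    disc <- split_periods(co)$discovery
    if (!any(disc$cycles$pregnancy) || all(disc$cycles$pregnancy)) next
    cand <- discover_thresholds(disc, co$parameters)
    cy <- disc$cycles
    for (r in seq_len(nrow(cand))) {
      pv <- cy$x[cy$pregnancy]; nv <- cy$x[!cy$pregnancy]
      if (cand$direction[r] == "upper") expect_lt(max(pv), max(nv))
      if (cand$direction[r] == "lower") expect_gt(min(pv), min(nv))
    }
  }
})

test_that("the published male and female thresholds are reproduced", {
  run <- published_rules_run("discovery")
  rules <- run$rules
  val <- rules[rules$status == "validated", ]
  expect_setequal(
    val$parameter,
    c("male_age", "ej_concentration", "ej_total_count", "ej_alkaline_comet",
      "su_immotile", "su_alkaline_comet", "su_neutral_comet",
      "bmi", "infertility_duration", "lh", "antral_follicle_count"))
  expect_equal(get_rule(val, "male_age")$cutoff, 41)
  expect_equal(get_rule(val, "ej_concentration")$cutoff, 10.36)
  expect_equal(get_rule(val, "ej_total_count")$cutoff, 51.79)
  expect_equal(get_rule(val, "ej_alkaline_comet")$cutoff, 72)
  expect_equal(get_rule(val, "su_immotile")$cutoff, 45)
  expect_equal(get_rule(val, "su_alkaline_comet")$cutoff, 59)
  expect_equal(get_rule(val, "bmi")$cutoff, 45)
  expect_equal(get_rule(val, "lh")$cutoff, 27.28)
  expect_equal(get_rule(val, "antral_follicle_count")$cutoff, 3)
  # dropped for inconsistency, as published
  expect_equal(get_rule(rules, "ej_progressive_motility")$status, "dropped")
  expect_equal(get_rule(rules, "female_age")$status, "dropped")
  expect_equal(get_rule(rules, "estradiol")$status, "dropped")
})

test_that("cutoff_policy selects the period the published mixed cutoffs use", {
  val <- published_rules_run("validation")$rules
  val <- val[val$status == "validated", ]
  expect_equal(get_rule(val, "su_neutral_comet")$cutoff, 65)
  expect_equal(get_rule(val, "infertility_duration")$cutoff, 84)
  expect_equal(get_rule(val, "bmi")$cutoff, 45)
  tight <- published_rules_run("tighter")$rules
  tight <- tight[tight$status == "validated", ]
  # tighter keeps whichever cutoff flags more cycles
  expect_equal(get_rule(tight, "su_neutral_comet")$cutoff, 65)   # min of 82/65
  expect_equal(get_rule(tight, "ej_concentration")$cutoff, 14.26) # max of 10.36/14.26
})

test_that("binarize flags strictly beyond the cutoff and propagates missingness", {
  rules <- threshold_rules("x", "upper", 41, status = "validated")
  co <- toy_cohort(disc_preg = c(30, 41), disc_nopreg = c(44, NA), val_preg = 35)
  d <- binarize(co, rules)
  expect_equal(d$flags$x, c(0, 0, 1, NA, 0))
  expect_equal(d$outcome, as.numeric(co$cycles$pregnancy))
  expect_equal(nrow(d$flags), nrow(co$cycles))
  # monotone: raising a value can only switch an upper flag 0 -> 1
  v <- sort(runif(50, 20, 60))
  f <- as.numeric(v > 41)
  expect_true(all(diff(f) >= 0))
  expect_error(binarize(co, threshold_rules("x", "upper", 1)),
               "validated", class = "iui_value_error")
})

test_that("rules serialize losslessly to JSON and CSV", {
  rules <- published_thresholds()
  expect_equal(nrow(rules), 11)
  for (ext in c(".json", ".csv")) {
    f <- tempfile(fileext = ext)
    write_rules(rules, f)
    back <- read_rules(f)
    expect_equal(back$parameter, rules$parameter)
    expect_equal(back$cutoff, rules$cutoff)
    expect_equal(back$status, rules$status)
  }
})

test_that("thresholds discovered on hard-ruled synthetic data equal the pregnancy extreme", {
  hard <- threshold_rules(c("male_age", "ej_alkaline_comet"),
                          c("upper", "upper"), c(41, 72), status = "validated")
  cfg <- synthetic_config(
    couples_discovery = 400, couples_validation = 400,
    outcome = outcome_model(logit(0.3), random_intercept_sd = 0.5,
                            hard_rules = hard), seed = 14)
  co <- generate_cohort(cfg)
  disc <- split_periods(co)$discovery
  cand <- discover_thresholds(disc, co$parameters)
  cy <- disc$cycles
  for (p in c("male_age", "ej_alkaline_comet")) {
    rule <- cand[cand$parameter == p & cand$direction == "upper", ]
    expect_equal(nrow(rule), 1)
    # exact recovery: cutoff equals the brute-force pregnancy-group maximum
    expect_identical(rule$cutoff, max(cy[[p]][cy$pregnancy]))
    # and respects the embedded hard bound
    expect_lte(rule$cutoff, if (p == "male_age") 41 else 72)
  }
})
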