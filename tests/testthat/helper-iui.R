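# shared fixtures built in code

toy_params <- function(names = "x", direction = "both",
                       source_group = "pregnancy") {
  parameter_set(names, "female", "units", direction, source_group, TRUE)
}

# minimal single-parameter two-period cohort from explicit value/outcome vectors
toy_cohort <- function(disc_preg, disc_nopreg, val_preg, val_nopreg = numeric(0),
                       param = "x", direction = "both",
                       source_group = "pregnancy") {
  mk <- function(vals, preg, period, prefix) {
    if (!length(vals)) return(NULL)
    data.frame(couple_id = paste0(prefix, seq_along(vals)),
               cycle_index = 1L, period = period, pregnancy = preg,
               multiple_pregnancy = NA, x = vals)
  }
  cy <- rbind(mk(disc_preg, TRUE, "discovery", "dp"),
              mk(disc_nopreg, FALSE, "discovery", "dn"),
              mk(val_preg, TRUE, "validation", "vp"),
              mk(val_nopreg, FALSE, "validation", "vn"))
  names(cy)[names(cy) == "x"] <- param
  iui_cohort(cy, toy_params(param, direction, source_group))
}

# exchangeable-correlated binary outcomes with EXACT marginal logistic means,
# via a Gaussian copula (latent exchangeable normal, probit thresholding)
sim_exchangeable_binary <- function(n_clusters, cluster_size, beta,
                                    latent_rho = 0.5) {
  n <- n_clusters * cluster_size
  x1 <- stats::rbinom(n, 1, 0.5)
  x2 <- stats::rnorm(n)
  eta <- beta[1] + beta[2] * x1 + beta[3] * x2
  zc <- rep(stats::rnorm(n_clusters), each = cluster_size)
  z <- sqrt(latent_rho) * zc + sqrt(1 - latent_rho) * stats::rnorm(n)
  y <- as.numeric(stats::pnorm(z) < stats::plogis(eta))
  list(flags = data.frame(x1 = x1, x2 = x2), outcome = y,
       cluster_id = rep(seq_len(n_clusters), each = cluster_size))
}

# random small cohort generator for property tests
random_cohort <- function(seed, n_couples = 12, param = "x") {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_couples)) {
    period <- if (i <= n_couples / 2) "discovery" else "validation"
    n_cy <- sample(1:4, 1)
    preg_at <- if (stats::runif(1) < 0.5) sample(seq_len(n_cy), 1) else Inf
    for (k in seq_len(min(n_cy, preg_at))) {
      rows[[length(rows) + 1L]] <- data.frame(
        couple_id = paste0("c", i), cycle_index = k, period = period,
        pregnancy = k == preg_at, multiple_pregnancy = NA,
        x = round(stats::runif(1, 0, 100), 1))
    }
  }
  cy <- do.call(rbind, rows)
  names(cy)[names(cy) == "x"] <- param
  iui_cohort(cy, toy_params(param))
}
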