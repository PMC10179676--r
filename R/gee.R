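#' Binomial-logistic GEE with exchangeable working correlation
#'
#' Solves the generalized estimating equations
#' `sum_i D_i' V_i^-1 (y_i - mu_i) = 0` for clustered binary outcomes with
#' `mu = logistic(X b)`, `D_i = A_i X_i`, `A_i = diag(mu(1-mu))` and
#' working covariance `V_i = phi A_i^{1/2} R(alpha) A_i^{1/2}`, `R`
#' exchangeable (or the identity under `correlation = "independence"`).
#' Each quasi-scoring step re-estimates the dispersion `phi` from all
#' Pearson residuals and the association `alpha` from all within-cluster
#' residual pairs, both with an `N - p` degrees-of-freedom correction.
#' Standard errors come from the robust sandwich
#' `B^-1 M B^-1` with `B = sum D'V^-1 D` and
#' `M = sum D'V^-1 (y-mu)(y-mu)' V^-1 D`, so inference is valid even when
#' the working correlation is wrong.
#'
#' Rows with a missing flag or outcome are dropped (complete case) with a
#' message. The intercept enters first. Iteration starts at the
#' independence GLM estimate and stops when the largest coefficient change
#' falls below `tol`.
#'
#' @param design an `iui_design` from [binarize()], or any list with
#'   `flags` (data frame of numeric covariates), `outcome` (0/1) and
#'   `cluster_id`.
#' @param correlation working structure, `"exchangeable"` (default) or
#'   `"independence"`.
#' @param max_iter,tol iteration controls (defaults 100 and 1e-6 on the
#'   max absolute coefficient change).
#' @param on_separation `"error"` (default): diverging coefficients abort
#'   with an explicit complete-separation error. `"drop"`: the offending
#'   columns are removed and the model refitted; their names are returned
#'   in `$separated`. Threshold flags validated on the same cohort are
#'   *deterministic* failure predictors (a flagged cycle is never pregnant,
#'   by construction), so their log-odds diverge and no finite Wald test
#'   exists; `"drop"` lets the remaining terms be tested while recording
#'   the deterministic ones.
#' @return An object of class `iui_gee` with elements `coefficients`,
#'   `robust_covariance`, `alpha`, `dispersion`, `n_clusters`, `n_obs`,
#'   `n_excluded`, `iterations`, `converged`, `score` (the estimating
#'   function at the solution) and `correlation`.
#' @export
fit_gee <- function(design, correlation = c("exchangeable", "independence"),
                    max_iter = 100, tol = 1e-6,
                    on_separation = c("error", "drop")) {
  correlation <- match.arg(correlation)
  on_separation <- match.arg(on_separation)
  flags <- as.data.frame(design$flags)
  y <- as.numeric(design$outcome)
  cl <- as.character(design$cluster_id)
  keep <- !is.na(y)
  if (ncol(flags)) keep <- keep & stats::complete.cases(flags)
  n_excluded <- sum(!keep)
  if (n_excluded) {
    message(n_excluded, " row(s) with missing flags or outcome excluded (complete case)")
  }
  flags <- flags[keep, , drop = FALSE]
  y <- y[keep]
  cl <- factor(cl[keep])
  X <- cbind("(intercept)" = 1, as.matrix(flags))
  n <- nrow(X)
  p <- ncol(X)
  if (nlevels(cl) < 2) stop_iui("need >= 2 clusters", class = "iui_value_error")
  if (length(unique(y)) < 2) {
    stop_iui("outcome is constant; model not estimable", class = "iui_value_error")
  }
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop_iui("collinear design columns: ", paste(bad, collapse = ", "),
             class = "iui_singular_error")
  }
  sizes <- tabulate(cl)
  nmax <- max(sizes)
  npairs <- sum(sizes * (sizes - 1) / 2)
  beta <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial())$coefficients)
  alpha <- 0
  phi <- 1
  moments <- function(beta) {
    mu <- invlogit(drop(X %*% beta))
    a <- mu * (1 - mu)
    e <- (y - mu) / sqrt(a)
    phi <- sum(e^2) / (n - p)
    alpha <- 0
    if (correlation == "exchangeable" && npairs > 0) {
      se_cl <- rowsum(e, cl)
      se2_cl <- rowsum(e^2, cl)
      cross <- sum(se_cl^2 - se2_cl) / 2
      alpha <- cross / (max(npairs - p, 1) * phi)
      lower <- if (nmax > 1) -1 / (nmax - 1) + 1e-6 else 0
      alpha <- min(max(alpha, lower), 1 - 1e-6)
    }
    list(mu = mu, a = a, e = e, phi = phi, alpha = alpha)
  }
  # B (without 1/phi), score (without 1/phi) and per-cluster score rows
  pieces <- function(mm) {
    aa <- 1 / (1 - mm$alpha)
    bb <- -aa * mm$alpha / (1 + (sizes - 1) * mm$alpha)  # per cluster
    Xt <- X * sqrt(mm$a)
    S <- rowsum(Xt, cl)
    sumE <- rowsum(mm$e, cl)
    w <- aa * mm$e + (bb * sumE)[as.integer(cl)]
    B <- aa * crossprod(Xt) + crossprod(S, S * bb)
    list(B = B, score = drop(crossprod(Xt, w)), G = rowsum(Xt * w, cl))
  }
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    mm <- moments(beta)
    pc <- pieces(mm)
    delta <- solve(pc$B, pc$score)
    beta <- beta + delta
    if (any(abs(beta) > 30)) {
      runaway <- setdiff(colnames(X)[abs(beta) > 30], "(intercept)")
      if (on_separation == "drop" && length(runaway)) {
        message("dropping separated column(s): ",
                paste(runaway, collapse = ", "))
        sub <- design
        sub$flags <- as.data.frame(design$flags)[
          , setdiff(colnames(as.data.frame(design$flags)), runaway),
          drop = FALSE]
        refit <- fit_gee(sub, correlation = correlation, max_iter = max_iter,
                         tol = tol, on_separation = "drop")
        refit$separated <- c(runaway, refit$separated)
        return(refit)
      }
      stop_iui("coefficients diverging (|beta| > 30): complete separation suspected",
               class = "iui_separation_error")
    }
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("GEE did not converge in ", max_iter, " iterations", call. = FALSE)
  }
  mm <- moments(beta)
  pc <- pieces(mm)
  Binv <- solve(pc$B)
  vcov <- Binv %*% crossprod(pc$G) %*% Binv
  vcov <- (vcov + t(vcov)) / 2
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 robust_covariance = vcov,
                 alpha = mm$alpha, dispersion = mm$phi,
                 n_clusters = nlevels(cl), n_obs = n,
                 n_excluded = n_excluded, iterations = iter,
                 converged = converged, score = pc$score,
                 correlation = correlation, separated = character(0)),
            class = "iui_gee")
}

#' @export
print.iui_gee <- function(x, ...) {
  cat(sprintf("<iui_gee> %s working correlation, %d obs in %d clusters\n",
              x$correlation, x$n_obs, x$n_clusters))
  cat(sprintf("  converged: %s (%d iterations), alpha = %.4f, dispersion = %.4f\n",
              x$converged, x$iterations, x$alpha, x$dispersion))
  print(wald_report(x), digits = 4)
  invisible(x)
}

#' Per-term Wald tests and odds ratios
#'
#' For each coefficient: robust SE, `z = estimate/SE`, two-sided normal
#' p-value, odds ratio `exp(estimate)` and its 95% Wald interval
#' `exp(estimate +- 1.96 SE)`. For a main-effects binary design the
#' per-coefficient Wald test coincides with the Type III test of the term.
#'
#' @param fit a converged `iui_gee`.
#' @return Data frame with columns `term, estimate, se, z, p, odds_ratio,
#'   ci_low, ci_high`.
#' @export
wald_report <- function(fit) {
  if (!fit$converged) {
    stop_iui("Wald report requires a converged fit", class = "iui_value_error")
  }
  est <- fit$coefficients
  se <- sqrt(diag(fit$robust_covariance))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  if (any(se == 0)) {
    warning("zero robust SE; p-value undefined for: ",
            paste(names(est)[se == 0], collapse = ", "), call. = FALSE)
    p[se == 0] <- NA_real_
    z[se == 0] <- NA_real_
  }
  q <- stats::qnorm(0.975)
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             z = unname(z), p = unname(p),
             odds_ratio = exp(unname(est)),
             ci_low = exp(unname(est - q * se)),
             ci_high = exp(unname(est + q * se)))
}

#' Select the significant model terms
#'
#' @param report a [wald_report()] table.
#' @param alpha_level significance level (default 0.05); terms with
#'   `p < alpha_level` are selected, the intercept never is.
#' @return Character vector of selected term names.
#' @export
select_significant <- function(report, alpha_level = 0.05) {
  sel <- !is.na(report$p) & report$p < alpha_level & report$term != "(intercept)"
  report$term[sel]
}
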