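#' Logistic regression by iteratively reweighted least squares
#'
#' Thin wrapper around base R's IRLS fitter with a tight convergence
#' criterion (relative coefficient change below 1e-8, at most 100
#' iterations). Detects singular designs (error naming the aliased
#' columns) and flags likely separation (diverging coefficients) with a
#' warning rather than an error.
#'
#' @param x Design matrix including the intercept column.
#' @param y Binary response vector (0/1 or logical).
#' @param weights Optional positive case weights.
#' @return A list with `coefficients`, `fitted` (probabilities),
#'   `converged`, `iterations` and `separation` (logical flag).
#' @export
#' @examples
#' x <- cbind(1, c(0, 0, 1, 1, 0, 1))
#' y <- c(0, 1, 1, 1, 0, 1)
#' fit_logistic(x, y)$coefficients
fit_logistic <- function(x, y, weights = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (is.null(weights)) weights <- rep(1, length(y))
  if (any(weights <= 0)) stop("weights must be positive")
  if (nrow(x) <= ncol(x)) {
    stop("need more observations than parameters")
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("singular design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::glm.fit(x, y, weights = weights,
                        family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-8,
                                                     maxit = 100))
  separation <- any(abs(fit$coefficients) > 15, na.rm = TRUE) ||
    !fit$converged
  if (separation) {
    warning("possible separation: coefficient estimates may be diverging")
  }
  list(coefficients = fit$coefficients,
       fitted = fit$fitted.values,
       converged = fit$converged,
       iterations = fit$iter,
       separation = separation)
}

#' Inverse probability of treatment weights
#'
#' The weight is the inverse of the propensity score for exposed persons
#' and the inverse of one minus the propensity score for comparison
#' persons. Optionally stabilized by the marginal exposure prevalence
#' and/or truncated at symmetric percentiles.
#'
#' @param propensity Numeric vector of propensity scores, strictly in
#'   (0, 1).
#' @param exposed Binary (0/1 or logical) exposure vector.
#' @param stabilize Multiply by the marginal exposure (or non-exposure)
#'   probability? Default `FALSE`.
#' @param truncate Optional percentile (e.g. 0.01) at which both weight
#'   tails are capped; default `NULL` (no truncation).
#' @return Numeric vector of weights.
#' @export
#' @examples
#' iptw_weights(c(0.2, 0.2), c(1, 0))  # 5, 1.25
iptw_weights <- function(propensity, exposed, stabilize = FALSE,
                         truncate = NULL) {
  if (any(propensity <= 0 | propensity >= 1)) {
    stop("propensity scores must lie strictly in (0, 1)")
  }
  e <- as.numeric(exposed)
  w <- ifelse(e == 1, 1 / propensity, 1 / (1 - propensity))
  if (stabilize) {
    pe <- mean(e)
    w <- w * ifelse(e == 1, pe, 1 - pe)
  }
  if (!is.null(truncate)) {
    q <- stats::quantile(w, c(truncate, 1 - truncate))
    w <- pmin(pmax(w, q[1]), q[2])
  }
  w
}

#' Standardized mean difference
#'
#' SMD = |mean(exposed) - mean(comparison)| / sqrt((v1 + v0) / 2), with
#' weighted means and variances when weights are given. Binary covariates
#' use the Bernoulli variance p(1 - p); continuous covariates use the
#' (reliability-weighted) sample variance, which reduces to the usual
#' n - 1 denominator under unit weights. Zero pooled variance gives 0 when
#' the means agree and `Inf` when they differ.
#'
#' @param x Numeric covariate (continuous, or coded 0/1).
#' @param exposed Binary exposure vector.
#' @param weights Optional positive weights (e.g. IPT weights).
#' @return Nonnegative number (possibly `Inf`).
#' @export
#' @examples
#' smd(c(0, 0, 1, 1), c(0, 0, 1, 1))  # Inf: disjoint distributions
smd <- function(x, exposed, weights = NULL) {
  x <- as.numeric(x)
  e <- as.numeric(exposed)
  if (is.null(weights)) weights <- rep(1, length(x))
  binary <- all(x %in% c(0, 1))
  stat <- function(grp) {
    w <- weights[e == grp]
    xx <- x[e == grp]
    m <- sum(w * xx) / sum(w)
    if (binary) {
      v <- m * (1 - m)
    } else {
      denom <- sum(w) - sum(w^2) / sum(w)
      v <- if (denom > 0) sum(w * (xx - m)^2) / denom else 0
    }
    c(m, v)
  }
  s1 <- stat(1); s0 <- stat(0)
  pooled <- (s1[2] + s0[2]) / 2
  diff <- abs(s1[1] - s0[1])
  if (pooled == 0) {
    if (diff == 0) 0 else Inf
  } else {
    diff / sqrt(pooled)
  }
}

#' Unweighted and IP-weighted odds ratios for a binary outcome
#'
#' Fits logistic regressions of the outcome on the exposure indicator,
#' once unweighted and once with the supplied IPT weights. The weighted
#' confidence interval uses a heteroskedasticity-robust (HC0 sandwich)
#' variance to account for the weighting; the unweighted interval is the
#' usual Wald interval.
#'
#' @param outcome Binary outcome vector.
#' @param exposed Binary exposure vector.
#' @param weights Positive weights (IPT weights; unit weights reproduce
#'   the unweighted OR).
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `unweighted_or`, `unweighted_ci`, `weighted_or`,
#'   `ci_low`, `ci_high`, `n_exposed`, `n_comparison` and `events`
#'   (a 2-vector of event counts per arm).
#' @export
weighted_or <- function(outcome, exposed, weights, conf_level = 0.95) {
  y <- as.numeric(outcome)
  e <- as.numeric(exposed)
  tab <- table(factor(y, 0:1), factor(e, 0:1))
  if (any(tab == 0)) {
    stop("zero cell in the outcome-by-exposure table; ",
         "continuity handling is out of scope")
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  ctrl <- stats::glm.control(epsilon = 1e-12, maxit = 100)
  fit_u <- stats::glm(y ~ e, family = stats::binomial(), control = ctrl)
  b_u <- stats::coef(fit_u)[["e"]]
  se_u <- sqrt(stats::vcov(fit_u)["e", "e"])

  fit_w <- stats::glm(y ~ e, family = stats::quasibinomial(),
                      weights = weights, control = ctrl)
  b_w <- stats::coef(fit_w)[["e"]]
  se_w <- sqrt(sandwich::vcovHC(fit_w, type = "HC0")["e", "e"])

  list(
    unweighted_or = exp(b_u),
    unweighted_ci = exp(b_u + c(-1, 1) * z * se_u),
    weighted_or = exp(b_w),
    ci_low = exp(b_w - z * se_w),
    ci_high = exp(b_w + z * se_w),
    n_exposed = sum(e == 1),
    n_comparison = sum(e == 0),
    events = c(comparison = sum(y[e == 0]), exposed = sum(y[e == 1]))
  )
}

#' Fit an IPTW-adjusted exposure-outcome model
#'
#' The central estimator: fits a propensity model for the exposure by
#' logistic regression on the baseline covariates, converts the fitted
#' scores into inverse-probability-of-treatment weights, checks covariate
#' balance by standardized mean differences before and after weighting,
#' and estimates the marginal odds ratio of a binary outcome by weighted
#' logistic regression with a robust (sandwich) confidence interval. The
#' unweighted OR is reported alongside.
#'
#' @param formula Propensity model formula: `exposure ~ covariates`, where
#'   the left-hand side is the binary exposure indicator.
#' @param data data.frame containing the exposure, the covariates and the
#'   outcome.
#' @param outcome Name of the binary outcome column in `data`.
#' @param stabilize,truncate Passed to [iptw_weights()].
#' @param ci `"sandwich"` (default) or `"bootstrap"` for the weighted-OR
#'   confidence interval.
#' @param boot Number of bootstrap replicates when `ci = "bootstrap"`.
#' @param boot_seed Seed for the bootstrap resampling.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `"iptw_fit"`; see [summary.iptw_fit()],
#'   [coef.iptw_fit()], [plot.iptw_fit()].
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(500))
#' d$e <- rbinom(500, 1, plogis(0.5 * d$x))
#' d$y <- rbinom(500, 1, plogis(-2 + 0.4 * d$e + 0.4 * d$x))
#' f <- iptw_fit(e ~ x, d, outcome = "y")
#' coef(f)
iptw_fit <- function(formula, data, outcome,
                     stabilize = FALSE, truncate = NULL,
                     ci = c("sandwich", "bootstrap"), boot = 200,
                     boot_seed = 1, conf_level = 0.95) {
  ci <- match.arg(ci)
  stopifnot(is.character(outcome), outcome %in% names(data))
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  X <- stats::model.matrix(formula, mf)
  e <- as.numeric(stats::model.response(mf))
  if (!all(e %in% c(0, 1))) stop("exposure must be binary 0/1")
  y <- as.numeric(data[[outcome]])

  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("singular propensity design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  ps_fit <- stats::glm(formula, data = mf, family = stats::binomial(),
                       control = stats::glm.control(epsilon = 1e-8,
                                                    maxit = 100))
  if (any(abs(stats::coef(ps_fit)) > 15) || !ps_fit$converged) {
    warning("possible separation in the propensity model")
  }
  ps <- stats::fitted(ps_fit)
  w <- iptw_weights(ps, e, stabilize = stabilize, truncate = truncate)

  covs <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  bal <- data.frame(
    covariate = colnames(covs),
    smd_unweighted = apply(covs, 2, smd, exposed = e),
    smd_weighted = apply(covs, 2, smd, exposed = e, weights = w),
    stringsAsFactors = FALSE
  )
  bal$balanced <- bal$smd_weighted < 0.1
  rownames(bal) <- NULL

  res <- weighted_or(y, e, w, conf_level)
  if (ci == "bootstrap") {
    bres <- iptw_boot(formula, data, outcome, stabilize, truncate,
                      boot, boot_seed)
    res$ci_low <- stats::quantile(bres, (1 - conf_level) / 2, names = FALSE)
    res$ci_high <- stats::quantile(bres, 1 - (1 - conf_level) / 2,
                                   names = FALSE)
  }

  structure(list(
    call = match.call(),
    formula = formula,
    outcome = outcome,
    propensity = ps_fit,
    ps = ps,
    exposed = e,
    w = w,
    balance = bal,
    result = res,
    ci_method = ci,
    conf_level = conf_level
  ), class = "iptw_fit")
}

iptw_boot <- function(formula, data, outcome, stabilize, truncate,
                      boot, boot_seed) {
  set.seed(boot_seed)
  n <- nrow(data)
  vapply(seq_len(boot), function(i) {
    d <- data[sample.int(n, n, replace = TRUE), , drop = FALSE]
    ps <- stats::fitted(stats::glm(formula, data = d,
                                   family = stats::binomial()))
    mf <- stats::model.frame(formula, d)
    e <- as.numeric(stats::model.response(mf))
    w <- iptw_weights(pmin(pmax(ps, 1e-12), 1 - 1e-12), e,
                      stabilize = stabilize, truncate = truncate)
    fit <- stats::glm(as.numeric(d[[outcome]]) ~ e,
                      family = stats::quasibinomial(), weights = w)
    exp(stats::coef(fit)[["e"]])
  }, 0)
}

#' @export
print.iptw_fit <- function(x, ...) {
  r <- x$result
  cat("IPTW-weighted exposure-outcome analysis\n")
  cat(sprintf("  n = %d (%d exposed, %d comparison); events = %d / %d\n",
              r$n_exposed + r$n_comparison, r$n_exposed, r$n_comparison,
              r$events[["exposed"]], r$events[["comparison"]]))
  cat(sprintf("  unweighted OR: %.3f (%.3f-%.3f)\n", r$unweighted_or,
              r$unweighted_ci[1], r$unweighted_ci[2]))
  cat(sprintf("  IP-weighted OR: %.3f (%.3f-%.3f) [%s CI]\n",
              r$weighted_or, r$ci_low, r$ci_high, x$ci_method))
  nb <- sum(!x$balance$balanced)
  cat(sprintf("  balance: max SMD after weighting %.3f; %d covariate(s) >= 0.1\n",
              max(x$balance$smd_weighted), nb))
  invisible(x)
}

#' Summary of an IPTW fit
#'
#' @param object An `"iptw_fit"` object.
#' @param ... Unused.
#' @return A list of class `"summary.iptw_fit"` carrying the OR estimates
#'   and the full balance table.
#' @export
summary.iptw_fit <- function(object, ...) {
  structure(list(result = object$result, balance = object$balance,
                 ci_method = object$ci_method,
                 propensity = summary(object$propensity)$coefficients),
            class = "summary.iptw_fit")
}

#' @export
print.summary.iptw_fit <- function(x, ...) {
  r <- x$result
  cat(sprintf("IP-weighted OR %.3f (95%% CI %.3f-%.3f, %s); unweighted %.3f\n\n",
              r$weighted_or, r$ci_low, r$ci_high, x$ci_method,
              r$unweighted_or))
  cat("Covariate balance (standardized mean differences):\n")
  print(x$balance, digits = 3)
  invisible(x)
}

#' Coefficients of an IPTW fit
#'
#' @param object An `"iptw_fit"` object.
#' @param model `"outcome"` (default) returns the marginal log odds ratio
#'   of the exposure; `"propensity"` returns the propensity model
#'   coefficients.
#' @param ... Unused.
#' @export
coef.iptw_fit <- function(object, model = c("outcome", "propensity"), ...) {
  model <- match.arg(model)
  if (model == "propensity") return(stats::coef(object$propensity))
  c(log_or = log(object$result$weighted_or))
}

#' Propensity scores from an IPTW fit
#'
#' @param object An `"iptw_fit"` object.
#' @param newdata Optional data.frame of new covariate values.
#' @param ... Unused.
#' @export
predict.iptw_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$ps)
  stats::predict(object$propensity, newdata = newdata, type = "response")
}

#' @export
weights.iptw_fit <- function(object, ...) object$w

#' Covariate balance (love) plot
#'
#' Dot chart of per-covariate standardized mean differences before and
#' after weighting, with the conventional 0.1 balance threshold marked.
#'
#' @param x An `"iptw_fit"` object.
#' @param ... Passed to [graphics::dotchart()].
#' @export
plot.iptw_fit <- function(x, ...) {
  b <- x$balance[order(x$balance$smd_unweighted), ]
  graphics::dotchart(b$smd_unweighted, labels = b$covariate,
                     xlim = range(0, b$smd_unweighted, b$smd_weighted,
                                  0.12, finite = TRUE),
                     pch = 1, xlab = "standardized mean difference", ...)
  graphics::points(b$smd_weighted, seq_len(nrow(b)), pch = 16)
  graphics::abline(v = 0.1, lty = 2)
  graphics::legend("bottomright", pch = c(1, 16),
                   legend = c("unweighted", "IPT-weighted"), bty = "n")
  invisible(x)
}

#' Run one of the three cohort analyses
#'
#' Applies the analysis-specific restriction and exposure definition to a
#' built cohort and fits the IPTW model on all 24 baseline covariates:
#' analysis `"A"` contrasts phenotypic IM/PM vs phenotypic NM/UM over the
#' whole cohort, `"B"` contrasts inhibitor-exposed vs inhibitor-free
#' within genotypic NMs, and `"C"` contrasts genotypic IM/PM vs NM/UM
#' within inhibitor-free persons. Drug subgroups restrict to
#' hydrocodone/tramadol/codeine (`"htc"`) or to oxycodone.
#'
#' @param cohort Output of [build_cohort()].
#' @param analysis `"A"`, `"B"` or `"C"`.
#' @param subgroup `"all"`, `"htc"` or `"oxycodone"`.
#' @param ... Passed to [iptw_fit()].
#' @return An `"iptw_fit"` object (with `analysis` and `subgroup` fields).
#' @export
analyze_cohort <- function(cohort, analysis = c("A", "B", "C"),
                           subgroup = c("all", "htc", "oxycodone"), ...) {
  analysis <- match.arg(analysis)
  subgroup <- match.arg(subgroup)
  d <- cohort
  if (subgroup != "all") d <- d[d$subgroup == subgroup, , drop = FALSE]
  d$.exposed <- switch(analysis,
    A = d$a_exposed,
    B = d$b_exposed,
    C = d$c_exposed
  )
  if (analysis == "B") d <- d[d$in_b, , drop = FALSE]
  if (analysis == "C") d <- d[d$in_c, , drop = FALSE]
  d$sex <- factor(d$sex)
  d$race_ethnicity <- factor(d$race_ethnicity)
  f <- stats::reformulate(covariate_cols(), response = ".exposed")
  fit <- iptw_fit(f, d, outcome = "outcome", ...)
  fit$analysis <- analysis
  fit$subgroup <- subgroup
  fit
}
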