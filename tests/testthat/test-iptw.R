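test_that("logistic IRLS recovers closed-form fits", {
  # intercept-only: coefficient is the logit of the event rate
  y <- rep(c(1, 0), c(25, 75))
  f <- fit_logistic(matrix(1, 100), y)
  expect_equal(unname(f$coefficients), log(1 / 3), tolerance = 1e-10)
  expect_true(f$converged)
  # 2x2 saturated: slope is the log cross-product ratio
  e <- rep(c(1, 1, 0, 0), c(30, 70, 20, 80))
  y <- rep(c(1, 0, 1, 0), c(30, 70, 20, 80))
  f <- fit_logistic(cbind(1, e), y)
  expect_equal(unname(f$coefficients[2]),
               log((30 * 80) / (70 * 20)), tolerance = 1e-9)
  # null effect on a perfectly balanced design
  x <- rep(c(0, 0, 1, 1), 25)
  f <- fit_logistic(cbind(1, x), rep(c(0, 1, 0, 1), 25))
  expect_equal(unname(f$coefficients[2]), 0, tolerance = 1e-9)
})

test_that("singular designs error and separation warns", {
  x <- cbind(`(Intercept)` = 1, a = c(1, 2, 3, 4, 5, 6),
             b = 2 * c(1, 2, 3, 4, 5, 6))
  expect_error(fit_logistic(x, c(0, 1, 0, 1, 0, 1)), "b")
  xs <- cbind(1, x = c(rep(0, 10), rep(1, 10)))
  expect_warning(fit_logistic(xs, c(rep(0, 10), rep(1, 10))), "separation")
})

test_that("IPT weights follow the inverse-probability formula", {
  expect_equal(iptw_weights(0.5, 1), 2)
  expect_equal(iptw_weights(c(0.2, 0.2), c(1, 0)), c(5, 1.25))
  expect_error(iptw_weights(c(0, 0.5), c(1, 0)), "strictly")
  expect_error(iptw_weights(1, 1), "strictly")
  # stabilized weights multiply by the arm prevalence
  w <- iptw_weights(c(0.25, 0.25, 0.5, 0.5), c(1, 0, 1, 0),
                    stabilize = TRUE)
  expect_equal(w, c(0.5 / 0.25, 0.5 / 0.75, 0.5 / 0.5, 0.5 / 0.5))
  # truncation caps the tails
  p <- c(0.001, rep(0.5, 98), 0.999)
  wt <- iptw_weights(p, rep(c(1, 0), 50), truncate = 0.05)
  expect_true(max(wt) < 1000)
})

test_that("standardized mean differences follow the pooled-SD formula", {
  expect_equal(smd(c(1, 2, 3, 1, 2, 3), c(0, 0, 0, 1, 1, 1)), 0)
  set.seed(2)
  x <- c(rnorm(500), rnorm(500) + 1)
  e <- rep(0:1, each = 500)
  m <- smd(x, e)
  v1 <- var(x[e == 1]); v0 <- var(x[e == 0])
  expect_equal(m, abs(mean(x[e == 1]) - mean(x[e == 0])) /
                 sqrt((v1 + v0) / 2))
  # binary covariates use p(1-p) variance
  b <- rep(c(0, 1, 0, 0), 25)
  eb <- rep(0:1, 50)
  p1 <- mean(b[eb == 1]); p0 <- mean(b[eb == 0])
  expect_equal(smd(b, eb),
               abs(p1 - p0) / sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2))
  # degenerate: zero pooled variance with unequal means
  expect_equal(smd(c(0, 0, 1, 1), c(0, 0, 1, 1)), Inf)
  expect_equal(smd(rep(1, 4), c(0, 0, 1, 1)), 0)
  # unit weights reproduce the unweighted value
  expect_equal(smd(x, e, weights = rep(1, 1000)), smd(x, e))
})

test_that("weighted OR reduces to the cross-product ratio under unit weights", {
  y <- rep(c(1, 0, 1, 0), c(21, 979, 18, 982))
  e <- rep(c(1, 1, 0, 0), c(21, 979, 18, 982))
  r <- weighted_or(y, e, weights = rep(1, 2000))
  expect_equal(r$weighted_or, (21 * 982) / (979 * 18), tolerance = 1e-9)
  expect_equal(r$unweighted_or, r$weighted_or, tolerance = 1e-9)
  expect_equal(r$n_exposed, 1000)
  expect_equal(unname(r$events), c(18, 21))
  # any constant weight gives the same OR
  r2 <- weighted_or(y, e, weights = rep(2.5, 2000))
  expect_equal(r2$weighted_or, r$weighted_or, tolerance = 1e-9)
  expect_error(weighted_or(c(0, 0, 1, 1), c(0, 0, 1, 1), rep(1, 4)),
               "zero cell")
})

test_that("the robust variance matches a hand-assembled sandwich", {
  set.seed(5)
  n <- 400
  e <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-1 + 0.5 * e))
  w <- runif(n, 0.5, 3)
  fit <- glm(y ~ e, family = quasibinomial(), weights = w)
  X <- cbind(1, e)
  mu <- fitted(fit)
  A <- t(X) %*% (w * mu * (1 - mu) * X)
  B <- t(X) %*% ((w * (y - mu))^2 * X)
  V <- solve(A) %*% B %*% solve(A)
  expect_equal(unname(sandwich::vcovHC(fit, type = "HC0")[2, 2]),
               V[2, 2], tolerance = 1e-8)
})

test_that("equal propensities make the weighted OR equal the crude OR", {
  set.seed(8)
  n <- 2000
  e <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-3 + 0.4 * e))
  w <- iptw_weights(rep(0.5, n), e)
  expect_equal(unique(w), 2)
  r <- weighted_or(y, e, w)
  expect_equal(r$weighted_or, r$unweighted_or, tolerance = 1e-9)
})

test_that("iptw_fit balances confounders and de-biases the estimate", {
  d <- simulate_cohort_frame(8000, pain_ed_scenario("confounded"), seed = 21)
  d$sex <- factor(d$sex); d$race_ethnicity <- factor(d$race_ethnicity)
  f <- reformulate(covariate_cols(), response = "exposed")
  fit <- iptw_fit(f, d, outcome = "outcome")
  truth <- attr(d, "truth")$marginal_or
  conf <- c("cm_depression", "cm_anxiety", "med_benzo", "pain_back", "age")
  bal <- fit$balance
  expect_true(all(bal$smd_unweighted[bal$covariate %in% conf] > 0.1))
  expect_true(all(bal$smd_weighted[bal$covariate %in% conf] < 0.1))
  # weighting moves the estimate toward the truth
  expect_lt(abs(log(fit$result$weighted_or) - log(truth)),
            abs(log(fit$result$unweighted_or) - log(truth)))
  # accessors
  expect_equal(weights(fit), fit$w)
  expect_equal(unname(coef(fit)), log(fit$result$weighted_or))
  expect_length(coef(fit, "propensity"), 26)
  expect_equal(predict(fit), fit$ps)
  expect_output(print(fit), "IP-weighted OR")
  expect_output(print(summary(fit)), "Covariate balance")
})

test_that("collinear covariates are reported by name", {
  d <- data.frame(e = rep(0:1, 50), x1 = rnorm(100))
  d$x2 <- 2 * d$x1
  d$y <- rbinom(100, 1, 0.3)
  expect_error(iptw_fit(e ~ x1 + x2, d, outcome = "y"), "x2")
})

test_that("bootstrap confidence intervals bracket the point estimate", {
  set.seed(31)
  n <- 1500
  x <- rnorm(n)
  e <- rbinom(n, 1, plogis(0.4 * x))
  y <- rbinom(n, 1, plogis(-2.5 + 0.5 * e + 0.4 * x))
  d <- data.frame(x = x, e = e, y = y)
  fit <- iptw_fit(e ~ x, d, outcome = "y", ci = "bootstrap", boot = 60,
                  boot_seed = 4)
  expect_lt(fit$result$ci_low, fit$result$weighted_or)
  expect_gt(fit$result$ci_high, fit$result$weighted_or)
  # bootstrap is reproducible under the same seed
  fit2 <- iptw_fit(e ~ x, d, outcome = "y", ci = "bootstrap", boot = 60,
                   boot_seed = 4)
  expect_equal(fit$result$ci_low, fit2$result$ci_low)
})
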