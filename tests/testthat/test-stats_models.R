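test_that("period prevalence reports percentages to two decimals", {
  expect_equal(period_prevalence(3202, 93767), 3.41)
  expect_equal(period_prevalence(0, 100), 0)
  expect_equal(period_prevalence(2704, 3202), 84.45)
  expect_error(period_prevalence(1, 0), "positive")
  expect_error(period_prevalence(5, 3), "lie in")
})

test_that("round_half_up rounds halves away from zero", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(2.675, 2), 2.68)   # would be 2.67 under round()
  expect_equal(round_half_up(-0.125, 2), -0.13)
})

test_that("crosstab counts, column percentages, and missing handling", {
  d <- data.frame(x = c("a", "a", "b", NA, "b", "a"),
                  g = c("u", "e", "u", "u", "e", "u"))
  ct <- crosstab(d, "x", "g")
  expect_equal(ct$n_missing, 1L)
  expect_equal(sum(ct$counts), 5L)
  expect_equal(colSums(ct$col_pct), c(e = 100, u = 100))
  # permutation invariance
  ct2 <- crosstab(d[sample(nrow(d)), ], "x", "g")
  expect_identical(ct$counts, ct2$counts)
  expect_error(crosstab(data.frame(x = c(NA, NA), g = c("u", "e")), "x", "g"),
               "missing")
})

test_that("chi-squared matches the hand-computed Pearson statistic", {
  t0 <- matrix(c(10, 10, 10, 10), 2)
  r <- chi_squared_test(t0)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r <- chi_squared_test(matrix(c(30, 10, 10, 30), 2))
  expect_equal(r$statistic, 20)  # sum((O-E)^2/E) with E = 20 everywhere
  expect_equal(r$df, 1L)
  # agreement with the base implementation on random tables
  set.seed(31)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 30) + 1, 2, 3)
    r <- chi_squared_test(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(r$statistic, unname(ref$statistic))
    expect_equal(r$p_value, ref$p.value)
  }
  expect_error(chi_squared_test(matrix(c(0, 0, 5, 5), 2)), "expected")
})

test_that("pooled t-test matches the base oracle", {
  expect_equal(students_t_test(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(students_t_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  set.seed(41)
  a <- rnorm(30); b <- rnorm(25, 0.5)
  r <- students_t_test(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(r$t, unname(ref$statistic))
  expect_equal(r$df, unname(ref$parameter))
  expect_equal(r$p_value, ref$p.value)
  expect_error(students_t_test(c(1, 1), c(2, 2)), "variance")
})

test_that("odds ratio and Wald CI follow the cross-product form", {
  # cesarean counts: exposed 443/2756 vs unexposed 8983/81463
  tab <- matrix(c(443, 2756, 8983, 81463), 2,
                dimnames = list(c("yes", "no"), c("exposed", "unexposed")))
  r <- odds_ratio_ci(tab)
  expect_equal(r$or, 1.4578, tolerance = 1e-4)
  expect_true(r$ci_low < r$or && r$or < r$ci_high)
  # proportional table: OR exactly 1
  expect_equal(odds_ratio_ci(matrix(c(12, 30, 12, 30), 2))$or, 1)
  # swapping the exposure columns inverts the OR
  r2 <- odds_ratio_ci(tab[, 2:1])
  expect_equal(r2$or, 1 / r$or)
  expect_error(odds_ratio_ci(matrix(c(0, 5, 5, 5), 2)), "positive")
})

test_that("dose-response coding uses zero diagnoses as reference", {
  m <- dose_response_coding(c("0", "1", "2+"))
  expect_equal(m[1, ], c(burden1 = 0L, burden2plus = 0L))
  expect_equal(m[2, ], c(burden1 = 1L, burden2plus = 0L))
  expect_equal(m[3, ], c(burden1 = 0L, burden2plus = 1L))
  expect_error(dose_response_coding("3"), "burden")
})

test_that("IRLS logistic matches glm and the saturated 2x2 closed form", {
  set.seed(51)
  n <- 400
  X <- cbind(1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * X[, 2] - 0.4 * X[, 3]))
  fit <- fit_binary_logistic(X, y)
  ref <- glm(y ~ X[, 2] + X[, 3], family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_true(fit$converged)
  # saturated 2x2: exp(beta) equals the cross-product OR exactly
  xb <- rep(c(0, 1), c(200, 200))
  yb <- c(rbinom(200, 1, 0.2), rbinom(200, 1, 0.4))
  tab <- table(factor(yb, c(1, 0)), factor(xb, c(1, 0)))
  fit2 <- fit_binary_logistic(cbind(1, xb), yb)
  expect_equal(exp(fit2$coefficients[2]),
               unname(odds_ratio_ci(unclass(tab))$or),
               tolerance = 1e-8, ignore_attr = TRUE)
  # null model: intercept = logit(mean)
  fit3 <- fit_binary_logistic(matrix(1, n), y)
  expect_equal(unname(fit3$coefficients), qlogis(mean(y)), tolerance = 1e-8)
})

test_that("logistic fitter rejects rank deficiency and flags separation", {
  X <- cbind(intercept = 1, a = rnorm(50))
  X <- cbind(X, a_copy = X[, "a"])
  expect_error(fit_binary_logistic(X, rbinom(50, 1, 0.5)), "a_copy")
  # perfectly separated data
  xs <- c(rep(0, 20), rep(1, 20))
  ys <- xs
  fit <- fit_binary_logistic(cbind(1, xs), ys)
  expect_false(fit$converged)
  expect_true(any(fit$separation))
})

test_that("multinomial Newton-Raphson matches nnet and the binary fitter", {
  skip_if_not_installed("nnet")
  set.seed(61)
  n <- 800
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5)
  e1 <- -1 + 0.7 * x1 - 0.3 * x2
  e2 <- -2 + 0.2 * x1 + 0.9 * x2
  den <- 1 + exp(e1) + exp(e2)
  u <- runif(n)
  y <- ifelse(u < exp(e1) / den, "B", ifelse(u < (exp(e1) + exp(e2)) / den, "C", "A"))
  X <- cbind(1, x1 = x1, x2 = x2)
  fit <- fit_multinomial_logistic(X, y, reference = "A")
  ref <- nnet::multinom(factor(y, c("A", "B", "C")) ~ x1 + x2,
                        trace = FALSE, reltol = 1e-12)
  expect_equal(unname(t(fit$coefficients)), unname(coef(ref)), tolerance = 1e-4)
  expect_true(fit$converged)
  # fitted category probabilities sum to one
  P <- fit$fitted_probs
  expect_true(max(abs(rowSums(P) - 1)) < 1e-10)
  # K = 2 reduces exactly to binary logistic
  yb <- rbinom(n, 1, plogis(-0.5 + x1))
  fitm <- fit_multinomial_logistic(X, factor(yb, 0:1), reference = "0")
  fitb <- fit_binary_logistic(X, yb)
  expect_equal(unname(fitm$coefficients[, 1]), unname(fitb$coefficients),
               tolerance = 1e-6)
  expect_error(fit_multinomial_logistic(X, factor(rep("A", n), c("A", "B"))),
               "two outcome levels")
})

test_that("covariates independent of the outcome estimate ORs near 1", {
  set.seed(71)
  n <- 4000
  x <- rbinom(n, 1, 0.3)         # exposure with a real effect
  z <- rbinom(n, 1, 0.5)         # pure noise covariate
  y <- rbinom(n, 1, plogis(-1 + 0.6 * x))
  fit <- fit_binary_logistic(cbind(1, x = x, z = z), y)
  expect_lt(abs(fit$coefficients["z"]), 2.5 * fit$se["z"])
  expect_gt(fit$coefficients["x"], 0.3)
})
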