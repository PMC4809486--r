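test_that("logistic fit recovers known coefficients and matches glm", {
  set.seed(601)
  n <- 2e4
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0 + 1 * x))
  fit <- fit_bayes_logistic(cbind(x), y)
  expect_true(fit$converged)
  se <- sqrt(diag(fit$cov))
  expect_lt(abs(fit$beta[1] - 0), 4 * se[1])
  expect_lt(abs(fit$beta[2] - 1), 4 * se[2])
  # with a negligible penalty the fit is the ML fit
  g <- glm(y ~ x, family = binomial())
  expect_equal(unname(fit$beta), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(fit$cov), unname(vcov(g)), tolerance = 0.01)
})

test_that("balanced criterion independent of the predictor gives a null fit", {
  set.seed(602)
  x <- rnorm(4e3)
  y <- rep(0:1, 2e3)
  fit <- fit_bayes_logistic(cbind(x), y)
  expect_lt(abs(fit$beta[1]), 0.1)
  expect_lt(abs(fit$beta[2]), 0.1)
  expect_error(fit_bayes_logistic(cbind(x), rep(1, 4e3)),
               class = "validmi_degenerate")
})

test_that("weighted observations enter the fit with their weights", {
  set.seed(603)
  x <- rnorm(500)
  y <- rbinom(500, 1, plogis(x))
  dup <- fit_bayes_logistic(cbind(c(x, x[1:100])), c(y, y[1:100]))
  wtd <- fit_bayes_logistic(cbind(x), y,
                            weights = c(rep(2, 100), rep(1, 400)))
  expect_equal(unname(dup$beta), unname(wtd$beta), tolerance = 1e-6)
})

test_that("posterior draws have the fitted mean and covariance", {
  set.seed(604)
  x <- rnorm(2e3)
  y <- rbinom(2e3, 1, plogis(0.3 + 0.8 * x))
  fit <- fit_bayes_logistic(cbind(x), y)
  draws <- t(replicate(2e4, draw_beta(fit)))
  expect_equal(colMeans(draws), fit$beta, tolerance = 0.005)
  expect_equal(cov(draws), fit$cov, tolerance = 0.15) # relative MC error
  # degenerate posterior returns the mean exactly
  fit0 <- fit
  fit0$cov <- matrix(0, 2, 2)
  expect_warning(b0 <- draw_beta(fit0), "not positive definite")
  expect_identical(b0, fit$beta)
})

test_that("single imputation draws Bernoulli values at the fitted probabilities", {
  d <- tibble::tibble(x = c(rep(0, 5), rep(1, 4000)),
                      y = c(rep(0L, 3), 1L, 1L, rep(NA_integer_, 4000)))
  # eta = logit(.8) at x = 1, so imputed values should be 1 about 80% of the time
  set.seed(605)
  yc <- impute_once(d, c(qlogis(0.8), 0), scenario = "DRR")
  expect_identical(yc[1:5], d$y[1:5]) # observed rows untouched
  expect_equal(mean(yc[-(1:5)]), 0.8, tolerance = 0.02)
  # a zero coefficient vector imputes fair coin flips
  y0 <- impute_once(d, c(0, 0), scenario = "DRR")
  expect_equal(mean(y0[-(1:5)]), 0.5, tolerance = 0.03)
  # saturated probabilities are deterministic
  ysat <- impute_once(d, c(-50, 0), scenario = "DRR")
  expect_true(all(ysat[-(1:5)] == 0L))
  expect_error(impute_once(d, c(0, 0, 0), scenario = "DRR"), "predictor set")
})

test_that("multiple imputation is a bit-for-bit no-op without missing values", {
  set.seed(606)
  pop <- simulate_population(300, "DRR", "natural", rho_xy = 0.5, br = 0.5)
  full <- restrict_sample(pop, 1)
  imp <- multiple_impute(full, m = 20)
  expect_length(imp, 20)
  for (d in imp) expect_identical(d$y, as.integer(pop$y))
  est <- mice_estimate(full, kind = "natural", scenario = "DRR")
  expect_identical(est$r_pb, point_biserial(pop$x, pop$y))
  expect_identical(est$br, mean(pop$y))
})

test_that("imputations preserve observed values and are seed-reproducible", {
  set.seed(607)
  pop <- simulate_population(400, "DRR", "natural", rho_xy = 0.6, br = 0.5)
  r <- restrict_sample(pop, 0.5)
  sel <- r$selected
  set.seed(1); imp1 <- multiple_impute(r, m = 5)
  set.seed(1); imp2 <- multiple_impute(r, m = 5)
  expect_identical(imp1, imp2)
  for (d in imp1) {
    expect_identical(d$y[sel], as.integer(pop$y[sel]))
    expect_false(anyNA(d$y))
  }
})

test_that("pooling is the arithmetic mean of per-imputation estimates", {
  set.seed(608)
  pop <- simulate_population(300, "DRR", "artificial", rho_xy = 0.5, br = 0.5)
  r <- restrict_sample(pop, 0.5)
  est <- mice_estimate(r, kind = "artificial", scenario = "DRR", m = 7)
  per <- attr(est, "per_imputation")
  expect_identical(nrow(per), 7L)
  expect_equal(est$r_pb, mean(per$r_pb), tolerance = 1e-12)
  expect_equal(est$r_b, mean(per$r_b), tolerance = 1e-12)
  expect_equal(est$br, mean(per$br), tolerance = 1e-12)
  # completed-dataset interface agrees
  set.seed(609)
  pooled <- pool_estimates(multiple_impute(r, m = 7), kind = "artificial")
  expect_identical(names(pooled), c("r_pb", "r_b", "br", "m"))
})

test_that("imputation under indirect selection uses both predictors", {
  set.seed(610)
  pop <- simulate_population(500, "IRR", "natural", rho_xy = 0.5, br = 0.5,
                             rho_zx = 0.4, rho_zy = 0.6)
  r <- restrict_sample(pop, 0.4)
  est <- mice_estimate(r, kind = "natural", scenario = "IRR")
  expect_false(is.na(est$r_pb))
  tp <- true_params(pop)
  expect_lt(abs(est$r_pb - tp$r_pb), 0.25)
})
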