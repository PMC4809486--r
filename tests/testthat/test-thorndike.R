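test_that("direct-restriction correction matches hand-computed values", {
  r <- c(-0.8, -0.3, 0, 0.2, 0.5, 0.9)
  expect_identical(correct_drr(r, 1), r) # no restriction: exact identity
  expect_equal(correct_drr(0.5, 2), 1 / sqrt(1.75), tolerance = 1e-12)
  expect_error(correct_drr(0.5, 0), class = "validmi_degenerate")
})

test_that("indirect-restriction correction matches hand-computed values", {
  expect_identical(as.numeric(correct_irr(0.3, 0.5, 0.4, 1)), 0.3)
  expect_equal(as.numeric(correct_irr(0.3, 0.5, 0.4, 2)),
               0.9 / (sqrt(1.75) * sqrt(1.48)), tolerance = 1e-12)
  expect_equal(as.numeric(correct_irr(0.3, 0.5, 0.4, 2)), 0.5592,
               tolerance = 1e-4)
  expect_error(correct_irr(0.3, 0.5, 0.4, 0), class = "validmi_degenerate")
})

test_that("corrected correlations stay inside [-1, 1] and are monotone", {
  set.seed(501)
  r <- runif(1e5, -1, 1)
  k <- exp(runif(1e5, -2, 2))
  out <- correct_drr(r, k)
  expect_true(all(abs(out) <= 1 + 1e-12))
  # strictly increasing in r for fixed k, increasing in k for positive r
  rs <- seq(-0.99, 0.99, by = 0.01)
  expect_true(all(diff(correct_drr(rs, 1.7)) > 0))
  ks <- seq(0.2, 5, by = 0.1)
  expect_true(all(diff(correct_drr(0.4, ks)) > 0))
})

test_that("the correction recovers the latent correlation under true truncation", {
  # bivariate normal with continuous criterion: the regime where the
  # correction is exact
  set.seed(502)
  n <- 5e5; rho <- 0.6
  x <- rnorm(n)
  yc <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  sel <- x > qnorm(0.6)
  r_res <- cor(x[sel], yc[sel])
  expect_lt(r_res, rho) # attenuation
  expect_equal(correct_drr(r_res, sd(x) / sd(x[sel])), rho, tolerance = 0.01)

  # trivariate normal, selection on the third variable
  z <- 0.5 * x + sqrt(0.75) * rnorm(n)
  selz <- z > qnorm(0.5)
  corrected <- correct_irr(cor(x[selz], yc[selz]),
                           cor(z[selz], x[selz]),
                           cor(z[selz], yc[selz]),
                           sd(z) / sd(z[selz]))
  expect_equal(as.numeric(corrected), rho, tolerance = 0.015)
})

test_that("sample-level correction is the identity at full selection", {
  set.seed(503)
  pop <- simulate_population(400, "DRR", "natural", rho_xy = 0.5, br = 0.6)
  r <- restrict_sample(pop, 1)
  est <- thorndike_estimate(r)
  expect_identical(est$r_pb, point_biserial(pop$x, pop$y))
  expect_true(is.na(est$br)) # no base-rate estimate from this approach

  popa <- simulate_population(400, "DRR", "artificial", rho_xy = 0.5, br = 0.6)
  ra <- restrict_sample(popa, 1)
  esta <- thorndike_estimate(ra)
  tp <- true_params(popa)
  expect_equal(esta$r_b, tp$r_b, tolerance = 1e-12)
})

test_that("sample-level correction reduces attenuation under restriction", {
  set.seed(504)
  me_raw <- me_cor <- numeric(40)
  for (i in 1:40) {
    pop <- simulate_population(500, "DRR", "natural", rho_xy = 0.6, br = 0.5)
    tp <- true_params(pop)
    r <- restrict_sample(pop, 0.4)
    raw <- point_biserial(r$x[r$selected], r$y[r$selected])
    me_raw[i] <- raw - tp$r_pb
    me_cor[i] <- thorndike_estimate(r)$r_pb - tp$r_pb
  }
  expect_lt(mean(me_raw), -0.25) # uncorrected is badly attenuated
  # the correction removes most, though not all, of the attenuation: the
  # dichotomous criterion violates the linearity the formula assumes
  expect_lt(abs(mean(me_cor)), abs(mean(me_raw)) / 2)
})
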