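test_that("factor draws respect bounds and feasibility", {
  set.seed(301)
  f <- draw_factors("DRR", "natural")
  expect_true(all(c("rho_xy", "br") %in% names(f)))
  expect_true(f$rho_xy >= 0.1 && f$rho_xy <= 0.9)
  for (i in 1:25) {
    g <- draw_factors("IRR", "natural")
    d_x <- d_from_pb(g$rho_xy, g$br)
    d_z <- d_from_pb(g$rho_zy, g$br)
    expect_silent(solve_within_corr(g$rho_zx, d_x, d_z, g$br))
    h <- draw_factors("IRR", "artificial")
    sigma <- matrix(c(1, h$rho_xy, h$rho_zx,
                      h$rho_xy, 1, h$rho_zy,
                      h$rho_zx, h$rho_zy, 1), 3, 3)
    expect_true(min(eigen(sigma, only.values = TRUE)$values) > 0)
  }
})

test_that("dichotomized-normal generator hits its cut-off, base rate and correlations", {
  set.seed(302)
  pop <- simulate_population(1e6, "DRR", "artificial", rho_xy = 0.6, br = 0.5)
  expect_equal(nrow(pop), 1e6)
  expect_false(anyNA(pop))
  expect_equal(mean(pop$y), 0.5, tolerance = 0.005)
  # the dichotomy at br = .5 cuts at zero, so the biserial of the sample
  # recovers the latent correlation
  tp <- true_params(pop)
  expect_equal(tp$r_b, 0.6, tolerance = 0.01)
  # extreme base rate: sample proportion within binomial error
  pop9 <- simulate_population(1e5, "DRR", "artificial", rho_xy = 0.3, br = 0.9)
  expect_equal(mean(pop9$y), 0.9, tolerance = 3 * sqrt(0.09 / 1e5) + 1e-3)
})

test_that("dichotomized-normal generator reproduces IRR target correlations", {
  set.seed(303)
  pop <- simulate_population(1e6, "IRR", "artificial", rho_xy = 0.5,
                             br = 0.4, rho_zx = 0.6, rho_zy = 0.3)
  expect_true("z" %in% names(pop))
  expect_equal(cor(pop$z, pop$x), 0.6, tolerance = 0.01)
  tp <- true_params(pop)
  expect_equal(tp$r_b, 0.5, tolerance = 0.01)
})

test_that("non-positive-definite latent targets are rejected", {
  expect_error(
    simulate_population(100, "IRR", "artificial", rho_xy = 0.9, br = 0.5,
                        rho_zx = 0.9, rho_zy = -0.9),
    class = "validmi_infeasible"
  )
})

test_that("mixture generator hits its implied point-biserial correlation", {
  set.seed(304)
  pop <- simulate_population(1e6, "DRR", "natural", rho_xy = 0.6, br = 0.5)
  expect_equal(point_biserial(pop$x, pop$y), 0.6, tolerance = 0.005)
  pop0 <- simulate_population(1e5, "DRR", "natural", rho_xy = 1e-9, br = 0.5)
  expect_equal(cor(pop0$x, pop0$y), 0, tolerance = 0.02)
})

test_that("mixture generator reproduces the marginal Z-X correlation under IRR", {
  set.seed(305)
  pop <- simulate_population(1e6, "IRR", "natural", rho_xy = 0.6, br = 0.5,
                             rho_zx = 0.36, rho_zy = 0.6)
  expect_equal(cor(pop$z, pop$x), 0.36, tolerance = 0.01)
  expect_equal(point_biserial(pop$z, pop$y), 0.6, tolerance = 0.005)
})

test_that("sample truth matches counting and errors on a constant criterion", {
  d <- tibble::tibble(x = c(1.2, -0.5, 0.3, 2), y = c(1L, 0L, 0L, 1L))
  tp <- true_params(d, kind = "natural", scenario = "DRR")
  expect_identical(tp$br, 0.5)
  expect_equal(tp$r_pb, cor(d$x, d$y), tolerance = 1e-12)
  expect_error(true_params(tibble::tibble(x = 1:4, y = rep(1L, 4)),
                           kind = "natural", scenario = "DRR"),
               class = "validmi_degenerate")
})
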