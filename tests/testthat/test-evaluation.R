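test_that("trueness and precision summaries match hand computations", {
  expect_identical(mean_error(c(0.1, -0.1)), 0)
  expect_identical(mean_error(c(0.07, 0.07)), 0.07)
  expect_equal(rmse(c(0.1, -0.1)), 0.1, tolerance = 1e-12)
  expect_identical(rmse(c(0, 0, 0)), 0)
  expect_equal(rmse(c(3, 4)), sqrt(12.5), tolerance = 1e-12)
  expect_error(mean_error(numeric(0)), "No residuals")
  expect_error(rmse(numeric(0)), "No residuals")
})

test_that("squared precision decomposes into bias and variance", {
  set.seed(701)
  for (i in 1:20) {
    e <- rnorm(sample(5:50, 1), mean = runif(1, -1, 1))
    pop_var <- mean((e - mean(e))^2)
    expect_equal(rmse(e)^2, mean_error(e)^2 + pop_var, tolerance = 1e-12)
  }
})

test_that("the precision F-ratio behaves as an MSE ratio", {
  e <- c(0.1, -0.2, 0.05, 0.3)
  same <- f_ratio_test(e, e)
  expect_identical(same$f, 1)
  scaled <- f_ratio_test(2 * e, e)
  expect_equal(scaled$f, 4, tolerance = 1e-12)
  expect_lt(scaled$p, same$p) # larger F, smaller upper-tail p
  inf <- f_ratio_test(e, rep(0, 4))
  expect_identical(inf$f, Inf)
  expect_identical(inf$p, 0)
  expect_identical(same$df1, 4L)
})

test_that("correlation strength partitions use half-open bins", {
  expect_identical(as.character(partition_by_strength(0.39)), "weak")
  expect_identical(as.character(partition_by_strength(0.40)), "moderate")
  expect_identical(as.character(partition_by_strength(0.69)), "moderate")
  expect_identical(as.character(partition_by_strength(0.70)), "strong")
  expect_identical(as.character(partition_by_strength(0.90)), "strong")
  expect_identical(as.character(partition_by_strength(0.10)), "weak")
  expect_error(partition_by_strength(0.95), "\\[.1, .9\\]")
  expect_error(partition_by_strength(0.05), "\\[.1, .9\\]")
})

test_that("accuracy aggregation counts exclusions without averaging them", {
  rec <- tibble::tibble(
    scenario = "DRR", kind = "natural",
    sr = c(0.5, 0.5, 0.5, 0.9),
    method = c("mice", "mice", "mice", "mice"),
    estimator = "r_pb",
    residual = c(0.1, -0.1, NA, 0.05),
    excluded = c(FALSE, FALSE, TRUE, FALSE),
    true_value = 0.5
  )
  acc <- accuracy_summary(rec, min_stable = 2)
  half <- dplyr::filter(acc, sr == 0.5)
  expect_identical(half$n_used, 2L)
  expect_identical(half$n_excluded, 1L)
  expect_equal(half$me, 0, tolerance = 1e-12)
  expect_equal(half$rmse, 0.1, tolerance = 1e-12)
  expect_false(half$unstable)
  single <- dplyr::filter(acc, sr == 0.9)
  expect_equal(single$me, 0.05, tolerance = 1e-12)
  expect_equal(single$rmse, 0.05, tolerance = 1e-12)
  expect_true(single$unstable)
  # a cell with nothing usable is still emitted, with blank statistics
  rec_empty <- dplyr::mutate(rec, excluded = TRUE, residual = NA_real_)
  acc_empty <- accuracy_summary(rec_empty)
  expect_identical(acc_empty$n_used, c(0L, 0L))
  expect_true(all(is.na(acc_empty$me)))
})

test_that("strength partitioning drops truths outside the design range", {
  rec <- tibble::tibble(
    sr = 0.5, method = "mice", estimator = "r_pb",
    residual = c(0.1, 0.2, 0.3), excluded = FALSE,
    true_value = c(0.05, 0.45, 0.85)
  )
  acc <- accuracy_summary(rec, partition = "true_value")
  expect_identical(nrow(acc), 2L)
  expect_setequal(as.character(acc$strength), c("moderate", "strong"))
})
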