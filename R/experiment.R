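# Monte Carlo orchestration: one condition = (scenario x criterion kind),
# iterated over a grid of selection ratios with paired application of both
# correction methods to the same restricted samples.

child_seed <- function(seed, i) {
  as.integer((as.double(seed) + 104729 * as.double(i)) %% 2147483647)
}

#' Run one Monte Carlo condition
#'
#' For each iteration: draw a feasible factor combination (correlations and
#' base rate uniform on `factor_range`), simulate an unrestricted applicant
#' population of size `n`, record its sample statistics as the truth, then
#' for every selection ratio apply top-down selection, check the
#' minimum-observations rule, and run both corrections (Thorndike and
#' multiple imputation) on the same restricted sample. Residuals
#' (estimate minus unrestricted-sample truth) are recorded per estimator:
#' the biserial `r_b` for an artificial dichotomy, the point-biserial
#' `r_pb` for a natural one, plus the base rate `br` for the imputation
#' route. Exclusions (marginal-condition failures, non-convergence,
#' degenerate draws) are applied to both methods pairwise, so precision
#' F-ratios compare identical samples. The run is a pure function of its
#' arguments: each iteration reseeds from a child seed derived from
#' `seed`.
#'
#' @inheritParams draw_factors
#' @param n Applicant population size per iteration (default 500).
#' @param iterations Number of Monte Carlo iterations (default 5000; scale
#'   down for quick runs).
#' @param sr_grid Selection ratios to evaluate (default .1 to .9 by .1).
#' @param m Number of imputations (default 20).
#' @param factor_range Bounds of the uniform factor distribution.
#' @param seed Master seed; the run is reproducible from it.
#' @param ridge Ridge penalty of the imputation model.
#' @param min_per_category Minimum observed count per criterion category.
#' @param stabilize Use the separation-guarding pseudo-observations in the
#'   imputation fit (see [multiple_impute()]).
#' @return An object of class `rr_condition`: a list with `residuals` (one
#'   record per iteration x sr x method x estimator), `accuracy` (the
#'   aggregated cell table), `f_ratios`, and `config`.
#' @export
run_condition <- function(scenario = c("DRR", "IRR"),
                          kind = c("artificial", "natural"),
                          n = 500L, iterations = 5000L,
                          sr_grid = seq(0.1, 0.9, by = 0.1),
                          m = 20L, factor_range = c(0.1, 0.9),
                          seed = 1L, ridge = 1e-5, min_per_category = 5L,
                          stabilize = TRUE) {
  scenario <- match.arg(scenario)
  kind <- match.arg(kind)
  if (any(sr_grid <= 0) || any(sr_grid > 1)) abort("`sr_grid` must lie in (0, 1].")
  est_corr <- if (kind == "artificial") "r_b" else "r_pb"
  n_sr <- length(sr_grid)
  rows_per_iter <- 3L * n_sr # thorndike corr, mice corr, mice br
  total <- iterations * rows_per_iter

  # flat preallocated record columns (assembled into a tibble at the end)
  c_iter <- integer(total); c_sr <- numeric(total)
  c_method <- character(total); c_estimator <- character(total)
  c_estimate <- rep(NA_real_, total); c_true <- rep(NA_real_, total)
  c_resid <- rep(NA_real_, total); c_excl <- logical(total)
  c_reason <- rep(NA_character_, total); c_rzx <- rep(NA_real_, total)

  k <- 0L
  put <- function(i, sr, method, estimator, estimate, true_value, excluded,
                  reason, rzx) {
    k <<- k + 1L
    c_iter[k] <<- i; c_sr[k] <<- sr
    c_method[k] <<- method; c_estimator[k] <<- estimator
    c_estimate[k] <<- estimate; c_true[k] <<- true_value
    c_resid[k] <<- if (excluded) NA_real_ else estimate - true_value
    c_excl[k] <<- excluded; c_reason[k] <<- reason; c_rzx[k] <<- rzx
  }

  for (i in seq_len(iterations)) {
    set.seed(child_seed(seed, i))
    iter_ok <- TRUE
    pop <- NULL; tp <- NULL
    tryCatch({
      f <- draw_factors(scenario, kind, factor_range[1], factor_range[2])
      pop <- simulate_population(n, scenario, kind,
                                 rho_xy = f$rho_xy, br = f$br,
                                 rho_zx = f[["rho_zx"]], rho_zy = f[["rho_zy"]])
      tp <- true_params(pop, kind, scenario)
    }, error = function(e) iter_ok <<- FALSE)
    if (!iter_ok) {
      for (sr in sr_grid) {
        put(i, sr, "thorndike", est_corr, NA_real_, NA_real_, TRUE, "degenerate", NA_real_)
        put(i, sr, "mice", est_corr, NA_real_, NA_real_, TRUE, "degenerate", NA_real_)
        put(i, sr, "mice", "br", NA_real_, NA_real_, TRUE, "degenerate", NA_real_)
      }
      next
    }
    true_corr <- if (kind == "artificial") tp$r_b else tp$r_pb
    rzx <- if (scenario == "IRR") tp$r_zx else NA_real_
    for (sr in sr_grid) {
      res <- restrict_sample(pop, sr, scenario)
      reason <- NULL
      th <- mi <- NULL
      if (!passes_marginal_condition(res, min_per_category)) {
        reason <- "marginal_condition"
      } else {
        th <- tryCatch(thorndike_estimate(res, kind, scenario),
                       error = function(e) NULL)
        mi <- mice_estimate(res, kind, scenario, m = m, ridge = ridge,
                            stabilize = stabilize)
        if (is.null(th) || is.null(mi)) reason <- "nonconvergence"
      }
      if (!is.null(reason)) {
        put(i, sr, "thorndike", est_corr, NA_real_, true_corr, TRUE, reason, rzx)
        put(i, sr, "mice", est_corr, NA_real_, true_corr, TRUE, reason, rzx)
        put(i, sr, "mice", "br", NA_real_, tp$br, TRUE, reason, rzx)
      } else {
        th_est <- if (kind == "artificial") th$r_b else th$r_pb
        mi_est <- if (kind == "artificial") mi$r_b else mi$r_pb
        put(i, sr, "thorndike", est_corr, th_est, true_corr, FALSE, NA_character_, rzx)
        put(i, sr, "mice", est_corr, mi_est, true_corr, FALSE, NA_character_, rzx)
        put(i, sr, "mice", "br", mi$br, tp$br, FALSE, NA_character_, rzx)
      }
    }
  }

  residuals <- tibble(
    scenario = scenario, kind = kind,
    iteration = c_iter[seq_len(k)], sr = c_sr[seq_len(k)],
    method = c_method[seq_len(k)], estimator = c_estimator[seq_len(k)],
    estimate = c_estimate[seq_len(k)], true_value = c_true[seq_len(k)],
    residual = c_resid[seq_len(k)], excluded = c_excl[seq_len(k)],
    reason = c_reason[seq_len(k)], r_zx_true = c_rzx[seq_len(k)]
  )
  config <- list(scenario = scenario, kind = kind, n = n,
                 iterations = iterations, sr_grid = sr_grid, m = m,
                 factor_range = factor_range, seed = seed, ridge = ridge,
                 min_per_category = min_per_category, stabilize = stabilize)
  structure(
    list(residuals = residuals,
         accuracy = accuracy_summary(residuals),
         f_ratios = f_ratio_summary(residuals),
         config = config),
    class = "rr_condition"
  )
}

#' @export
print.rr_condition <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Monte Carlo condition: %s, %s criterion\n", cfg$scenario, cfg$kind))
  cat(sprintf("  N = %d, iterations = %d, m = %d, seed = %d\n",
              cfg$n, cfg$iterations, cfg$m, cfg$seed))
  cat("Accuracy by selection ratio:\n")
  print(x$accuracy, n = Inf)
  invisible(x)
}

#' @method tidy rr_condition
#' @export
tidy.rr_condition <- function(x, ...) x$accuracy

#' @method glance rr_condition
#' @export
glance.rr_condition <- function(x, ...) {
  tibble(
    scenario = x$config$scenario, kind = x$config$kind,
    n = x$config$n, iterations = x$config$iterations, m = x$config$m,
    n_cells = nrow(x$accuracy),
    exclusion_rate = sum(x$residuals$excluded) / nrow(x$residuals)
  )
}

#' Preliminary study of the number of imputations
#'
#' Investigates how the number of imputations `m` affects the accuracy of
#' the pooled correlation estimate at different rates of missing criterion
#' values, under direct selection. Per iteration the imputation model is
#' fitted once and `max(m_values)` completed datasets are drawn; the pooled
#' estimate for each `m` uses the first `m` draws, so the comparison across
#' `m` is paired within iterations. The reported estimator is the biserial
#' correlation for an artificial dichotomy and the point-biserial for a
#' natural one.
#'
#' @inheritParams run_condition
#' @param kind Criterion kind (single value).
#' @param missing_rates Rates of missing criterion values; the selection
#'   ratio is one minus the rate.
#' @param m_values Numbers of imputations to compare.
#' @return A tibble with one row per (kind, missing_rate, m): `estimator`,
#'   `rmse`, `me`, `n_used`, `n_excluded`, and `delta_rmse` (change versus
#'   the previous smaller `m`).
#' @export
preliminary_m_study <- function(kind = c("natural", "artificial"),
                                missing_rates = c(0.7, 0.5, 0.3),
                                m_values = c(5L, 20L, 50L),
                                n = 500L, iterations = 1000L,
                                factor_range = c(0.1, 0.9), seed = 1L,
                                ridge = 1e-5, min_per_category = 5L,
                                stabilize = TRUE) {
  kind <- match.arg(kind)
  m_values <- sort(as.integer(m_values))
  max_m <- max(m_values)
  estimator <- if (kind == "artificial") "r_b" else "r_pb"
  out <- list()
  for (rate in missing_rates) {
    sr <- 1 - rate
    resid <- matrix(NA_real_, iterations, length(m_values))
    excluded <- logical(iterations)
    for (i in seq_len(iterations)) {
      set.seed(child_seed(seed, i))
      vals <- tryCatch({
        f <- draw_factors("DRR", kind, factor_range[1], factor_range[2])
        pop <- simulate_population(n, "DRR", kind, rho_xy = f$rho_xy, br = f$br)
        tp <- true_params(pop, kind, "DRR")
        res <- restrict_sample(pop, sr, "DRR")
        if (!passes_marginal_condition(res, min_per_category)) NULL else {
          draws <- impute_y_draws(res, max_m, "DRR", ridge, stabilize)
          if (is.null(draws)) NULL else {
            truth <- if (kind == "artificial") tp$r_b else tp$r_pb
            per <- vapply(draws, function(yj) {
              r <- point_biserial(pop$x, yj)
              if (kind == "artificial") as.numeric(biserial(r, mean(yj))) else r
            }, numeric(1))
            cumsum(per)[m_values] / m_values - truth
          }
        }
      }, error = function(e) NULL)
      if (is.null(vals)) excluded[i] <- TRUE else resid[i, ] <- vals
    }
    for (j in seq_along(m_values)) {
      r <- resid[!excluded, j]
      out[[length(out) + 1L]] <- tibble(
        kind = kind, missing_rate = rate, sr = sr, m = m_values[j],
        estimator = estimator,
        rmse = rmse(r), me = mean_error(r),
        n_used = sum(!excluded), n_excluded = sum(excluded)
      )
    }
  }
  dplyr::bind_rows(out) |>
    dplyr::group_by(.data$kind, .data$missing_rate) |>
    dplyr::arrange(.data$m, .by_group = TRUE) |>
    dplyr::mutate(delta_rmse = .data$rmse - dplyr::lag(.data$rmse)) |>
    dplyr::ungroup()
}
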