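#' Mean error (trueness) of a set of residuals
#'
#' The arithmetic mean of residuals (estimate minus truth). A positive value
#' means the estimator overestimates the true parameter on average.
#'
#' @param residuals Non-empty numeric vector of residuals.
#' @return The mean error.
#' @export
mean_error <- function(residuals) {
  if (length(residuals) == 0L) abort("No residuals supplied.")
  mean(residuals)
}

#' Root mean square error (precision) of a set of residuals
#'
#' `sqrt(mean(residuals^2))`; small values mean small random error.
#'
#' @inheritParams mean_error
#' @return The RMSE, non-negative.
#' @export
rmse <- function(residuals) {
  if (length(residuals) == 0L) abort("No residuals supplied.")
  sqrt(mean(residuals^2))
}

#' F-ratio comparison of two methods' precision
#'
#' Compares the mean squared errors of residuals from two correction methods
#' on paired samples: `F = MSE(first) / MSE(second)`. An F of 1 means equal
#' precision; an F of 2 means the second method is twice as precise. The
#' reported p-value is the one-sided upper tail of an F distribution with
#' the two usable sample sizes as degrees of freedom.
#'
#' @param res_thorndike,res_mice Residual vectors from the two methods,
#'   computed on identical iterations.
#' @return A one-row tibble with `f`, `p`, `df1`, `df2`, `mse_thorndike`,
#'   `mse_mice`.
#' @export
f_ratio_test <- function(res_thorndike, res_mice) {
  if (length(res_thorndike) == 0L || length(res_mice) == 0L) {
    abort("Both residual sets must be non-empty.")
  }
  mse_t <- mean(res_thorndike^2)
  mse_m <- mean(res_mice^2)
  f <- if (mse_m == 0) Inf else mse_t / mse_m
  n1 <- length(res_thorndike)
  n2 <- length(res_mice)
  p <- if (is.finite(f)) pf(f, n1, n2, lower.tail = FALSE) else 0
  tibble(f = f, p = p, df1 = n1, df2 = n2,
         mse_thorndike = mse_t, mse_mice = mse_m)
}

#' Partition a true correlation into strength levels
#'
#' Bins a true correlation from the unrestricted dataset into a weak
#' (`[.10, .40)`), moderate (`[.40, .70)`) or strong (`[.70, .90]`)
#' relationship.
#'
#' @param true_r True correlation value(s) in `[.1, .9]`.
#' @return A factor with levels `weak`, `moderate`, `strong`.
#' @export
partition_by_strength <- function(true_r) {
  if (any(!is.finite(true_r)) || any(true_r < 0.1) || any(true_r > 0.9)) {
    abort("`true_r` must lie in [.1, .9].")
  }
  cut(true_r, breaks = c(0.1, 0.4, 0.7, 0.9),
      labels = c("weak", "moderate", "strong"),
      right = FALSE, include.lowest = TRUE)
}

# strength with NA (instead of an error) outside [.1, .9]; sample true
# correlations can drift slightly outside the design range
strength_or_na <- function(true_r) {
  out <- factor(rep(NA_character_, length(true_r)),
                levels = c("weak", "moderate", "strong"))
  ok <- is.finite(true_r) & true_r >= 0.1 & true_r <= 0.9
  out[ok] <- partition_by_strength(true_r[ok])
  out
}

#' Aggregate residual records into an accuracy table
#'
#' Summarizes a tibble of residual records (one row per iteration, selection
#' ratio, method and estimator, as produced by [run_condition()]) into
#' accuracy cells: mean error, RMSE, usable and excluded counts. Excluded
#' records are counted but never averaged. Optionally facets each cell by
#' the strength of a true correlation (`partition = "true_value"` uses the
#' record's own truth, `partition = "r_zx"` the unrestricted Z-X
#' correlation); records whose truth falls outside `[.1, .9]` are dropped
#' from partitioned summaries.
#'
#' @param records Residual records with columns `sr`, `method`, `estimator`,
#'   `residual`, `excluded` (and optionally `scenario`, `kind`,
#'   `true_value`, `r_zx_true`).
#' @param partition `"none"` (default), `"true_value"`, or `"r_zx"`.
#' @param min_stable Cells with fewer usable iterations are flagged
#'   `unstable` (default 100).
#' @return A tibble with one row per cell.
#' @export
accuracy_summary <- function(records, partition = c("none", "true_value", "r_zx"),
                             min_stable = 100L) {
  partition <- match.arg(partition)
  by <- intersect(c("scenario", "kind", "sr", "method", "estimator"),
                  names(records))
  if (partition != "none") {
    src <- if (partition == "r_zx") records$r_zx_true else records$true_value
    records$strength <- strength_or_na(src)
    records <- dplyr::filter(records, !is.na(.data$strength))
    by <- c(by, "strength")
  }
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_used = sum(!.data$excluded),
      n_excluded = sum(.data$excluded),
      me = if (n_used > 0) mean_error(.data$residual[!.data$excluded]) else NA_real_,
      rmse = if (n_used > 0) rmse(.data$residual[!.data$excluded]) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(unstable = .data$n_used < min_stable)
}

#' F-ratio table comparing the two correction methods per cell
#'
#' Pairs the Thorndike and imputation residuals of the correlation
#' estimator within each (scenario, kind, sr) cell -- exclusions are applied
#' pairwise upstream, so both methods' residuals come from identical
#' iterations -- and reports the precision F-ratio ([f_ratio_test()]).
#'
#' @param records Residual records as in [accuracy_summary()].
#' @param estimator Which estimator to compare (default: the correlation
#'   estimators `r_b`/`r_pb`, excluding `br`).
#' @return A tibble with one row per cell and columns `f`, `p`, `df1`,
#'   `df2`.
#' @export
f_ratio_summary <- function(records, estimator = c("r_b", "r_pb")) {
  by <- intersect(c("scenario", "kind", "sr", "estimator"), names(records))
  records |>
    dplyr::filter(.data$estimator %in% !!estimator, !.data$excluded) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(d, key) {
      f_ratio_test(d$residual[d$method == "thorndike"],
                   d$residual[d$method == "mice"])
    }) |>
    dplyr::ungroup()
}
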