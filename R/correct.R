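#' Correct the predictive validity of a selected sample
#'
#' Applies both correction routes to one dataset in which the dichotomous
#' criterion is observed for selected cases only: Thorndike's sd-ratio
#' correction ([thorndike_estimate()]) and the missing-data correction that
#' multiply imputes the criterion and pools point estimates
#' ([mice_estimate()]). The input needs a continuous predictor `x`, a 0/1
#' criterion `y` with `NA` for non-selected cases, and, under indirect
#' selection, the selection variable `z` observed for everyone.
#'
#' @param data A data frame with columns `x`, `y` (`NA` where unselected)
#'   and optionally `z`.
#' @param scenario `"DRR"` or `"IRR"` (default guessed from the presence of
#'   `z`).
#' @param kind `"artificial"` if the dichotomy is a split of an underlying
#'   continuous trait (a biserial estimate is then reported), `"natural"`
#'   otherwise.
#' @param m Number of imputations.
#' @param ridge Ridge penalty of the imputation model.
#' @param seed Optional seed for the imputation draws.
#' @param min_per_category Minimum observed count per criterion category.
#' @param stabilize Use the separation-guarding pseudo-observations in the
#'   imputation fit (see [multiple_impute()]).
#' @return An object of class `validity_correction` with [tidy()] and
#'   [glance()] methods; `tidy()` returns one row per method with `r_pb`,
#'   `r_b` and `br` estimates.
#'
#' @examples
#' pop <- simulate_population(500, "DRR", "natural", rho_xy = 0.5, br = 0.6)
#' sel <- restrict_sample(pop, sr = 0.4)
#' fit <- correct_validity(sel, kind = "natural", seed = 1)
#' tidy(fit)
#' @export
correct_validity <- function(data, scenario = NULL,
                             kind = c("natural", "artificial"),
                             m = 20L, ridge = 1e-5, seed = NULL,
                             min_per_category = 5L, stabilize = TRUE) {
  kind <- match.arg(kind)
  if (!all(c("x", "y") %in% names(data))) {
    abort("`data` must contain columns `x` and `y`.")
  }
  scenario <- scenario %||% attr(data, "scenario") %||%
    if ("z" %in% names(data)) "IRR" else "DRR"
  if (identical(scenario, "IRR") && !"z" %in% names(data)) {
    abort("IRR correction requires a selection variable `z`.")
  }
  restricted <- as_tibble(data[intersect(c("x", "z", "y"), names(data))])
  if (anyNA(restricted$x) || (identical(scenario, "IRR") && anyNA(restricted$z))) {
    abort("Predictor and selection variables must be observed for all cases.")
  }
  restricted$y <- as.integer(restricted$y)
  restricted$selected <- !is.na(restricted$y)
  attr(restricted, "scenario") <- scenario
  attr(restricted, "kind") <- kind
  if (!passes_marginal_condition(restricted, min_per_category)) {
    abort(sprintf(
      "Fewer than %d observed cases in one criterion category; no valid correction.",
      min_per_category))
  }
  if (!is.null(seed)) set.seed(seed)
  th <- thorndike_estimate(restricted, kind, scenario)
  mi <- mice_estimate(restricted, kind, scenario, m = m, ridge = ridge,
                      stabilize = stabilize)
  if (is.null(mi)) abort("Imputation model did not converge.",
                         class = "validmi_nonconvergence")
  sel <- restricted$selected
  sel_var <- if (identical(scenario, "IRR")) restricted$z else restricted$x
  structure(
    list(
      estimates = dplyr::bind_rows(th, mi),
      per_imputation = attr(mi, "per_imputation"),
      scenario = scenario, kind = kind, m = m,
      n = nrow(restricted), n_selected = sum(sel),
      success_rate = mean(restricted$y[sel]),
      sd_unrestricted = sd(sel_var), sd_restricted = sd(sel_var[sel])
    ),
    class = "validity_correction"
  )
}

#' @export
print.validity_correction <- function(x, ...) {
  cat(sprintf("Range restriction correction (%s, %s dichotomy)\n",
              x$scenario, x$kind))
  cat(sprintf("  applicants: %d, selected: %d (SR = %.2f)\n",
              x$n, x$n_selected, x$n_selected / x$n))
  cat(sprintf("  selected-sample success rate: %.3f\n", x$success_rate))
  cat(sprintf("  sd of selection variable: %.3f (all) / %.3f (selected)\n",
              x$sd_unrestricted, x$sd_restricted))
  cat("\nEstimates:\n")
  print(x$estimates)
  invisible(x)
}

#' @method tidy validity_correction
#' @export
tidy.validity_correction <- function(x, ...) x$estimates

#' @method glance validity_correction
#' @export
glance.validity_correction <- function(x, ...) {
  tibble(
    scenario = x$scenario, kind = x$kind, m = x$m,
    n = x$n, n_selected = x$n_selected,
    sr = x$n_selected / x$n,
    success_rate = x$success_rate,
    sd_ratio = x$sd_unrestricted / x$sd_restricted
  )
}

#' Correct a user-supplied dataset stored as delimited text
#'
#' Reads a CSV file with columns `x`, `y` (blank where the criterion is
#' unobserved) and optionally `z`, and runs [correct_validity()] on it.
#'
#' @param path Path to the CSV file.
#' @inheritParams correct_validity
#' @return A `validity_correction` object.
#' @export
correct_user_dataset <- function(path, scenario = NULL,
                                 kind = c("natural", "artificial"),
                                 m = 20L, seed = NULL, ridge = 1e-5,
                                 min_per_category = 5L) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  names(data) <- tolower(names(data))
  if (!all(c("x", "y") %in% names(data))) {
    abort(sprintf("`%s` must contain columns `x` and `y` (got: %s).",
                  path, paste(names(data), collapse = ", ")))
  }
  bad <- !data$y %in% c(0, 1) & !is.na(data$y)
  if (any(bad)) abort("`y` must contain only 0, 1 or blank values.")
  correct_validity(data, scenario = scenario, kind = kind, m = m,
                   ridge = ridge, seed = seed,
                   min_per_category = min_per_category)
}
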