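#' Apply top-down selection to an applicant population
#'
#' Sorts the population in descending order of the selection variable (X
#' under direct selection, Z under indirect selection), keeps the criterion
#' value for the top `round(n * sr)` cases, and deletes it (sets `NA`) for
#' everyone else. The predictor and selection variables remain observed for
#' all applicants, which is what makes the missingness pattern missing at
#' random and the classical sd-ratio corrections computable. Rounding is
#' half-away-from-zero; ties in the selection variable are broken by row
#' order (they have probability zero under continuous draws).
#'
#' @param data An unrestricted population (columns `x`, `y`, optionally `z`).
#' @param sr Selection ratio in (0, 1]: proportion of applicants selected.
#' @param scenario `"DRR"` (select on `x`) or `"IRR"` (select on `z`);
#'   defaults to the attribute set by [simulate_population()].
#' @return A tibble like `data` but with `y` missing for non-selected rows
#'   and a logical `selected` column; the selection ratio is stored in the
#'   `sr` attribute.
#' @export
restrict_sample <- function(data, sr, scenario = attr(data, "scenario")) {
  if (!is.numeric(sr) || length(sr) != 1L || sr <= 0 || sr > 1) {
    abort("`sr` must be a single selection ratio in (0, 1].")
  }
  scenario <- scenario %||% if ("z" %in% names(data)) "IRR" else "DRR"
  sel_var <- if (identical(scenario, "IRR")) data$z else data$x
  if (is.null(sel_var)) abort("Selection variable not found in `data`.")
  n <- nrow(data)
  n_sel <- as.integer(floor(n * sr + 0.5))
  ord <- order(-sel_var) # stable: ties broken by original row index
  selected <- logical(n)
  selected[ord[seq_len(n_sel)]] <- TRUE
  out <- as_tibble(data)
  out$y <- as.integer(out$y)
  out$y[!selected] <- NA_integer_
  out$selected <- selected
  attr(out, "sr") <- sr
  attr(out, "scenario") <- scenario
  attr(out, "kind") <- attr(data, "kind")
  out
}

#' Check the minimum-observations rule for a restricted sample
#'
#' A restricted sample supports a valid correction only if the observed
#' criterion contains enough cases in both categories; the rule used here
#' (and throughout the Monte Carlo evaluation) requires at least five
#' observed "successful" and five observed "not successful" cases, following
#' the contingency-table rule of thumb. Samples failing the rule are
#' excluded from accuracy aggregation for both correction methods.
#'
#' @param data A restricted sample (column `y` with `NA` for non-selected).
#' @param min_per_category Minimum observed count per category (default 5).
#' @return `TRUE` or `FALSE`.
#' @export
passes_marginal_condition <- function(data, min_per_category = 5L) {
  y <- data$y
  sum(y == 0L, na.rm = TRUE) >= min_per_category &&
    sum(y == 1L, na.rm = TRUE) >= min_per_category
}
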