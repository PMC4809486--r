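#' Thorndike's Case-2 correction for direct range restriction
#'
#' Corrects a correlation observed in a directly restricted sample using the
#' ratio `k = S/s` of the unrestricted to the restricted standard deviation
#' of the selection variable:
#' `rho = k * r / sqrt(1 + r^2 * (k^2 - 1))`.
#' With `k = 1` the input is returned unchanged; for `|r| <= 1` the result
#' always lies in `[-1, 1]`.
#'
#' @param r Restricted-sample correlation between predictor and criterion.
#' @param k Ratio of unrestricted to restricted sd of the predictor
#'   (`S_X / s_X`), positive.
#' @return The corrected correlation (vectorized over `r` and `k`).
#'
#' @examples
#' correct_drr(0.5, 2)
#' @export
correct_drr <- function(r, k) {
  if (any(!is.finite(k)) || any(k <= 0)) {
    abort("`k` must be positive and finite (degenerate restricted sd?).",
          class = "validmi_degenerate")
  }
  (k * r) / sqrt(1 + r^2 * (k^2 - 1))
}

#' Thorndike's Case-3 correction for indirect range restriction
#'
#' Corrects the predictor-criterion correlation when selection was top-down
#' on a third variable Z. All three restricted-sample correlations and the
#' sd ratio `k = S_Z / s_Z` enter:
#' `rho = (r_xy + r_zx * r_zy * (k^2 - 1)) /
#'   (sqrt(1 + r_zx^2 * (k^2 - 1)) * sqrt(1 + r_zy^2 * (k^2 - 1)))`.
#' Finite samples can push the value outside `[-1, 1]`; it is then clipped
#' and flagged via the `"clipped"` attribute.
#'
#' @param r_xy,r_zx,r_zy Correlations obtained from the restricted sample.
#' @param k Ratio of unrestricted to restricted sd of Z.
#' @return The corrected correlation with a logical `"clipped"` attribute.
#'
#' @examples
#' correct_irr(0.3, 0.5, 0.4, 2)
#' @export
correct_irr <- function(r_xy, r_zx, r_zy, k) {
  if (any(!is.finite(k)) || any(k <= 0)) {
    abort("`k` must be positive and finite (degenerate restricted sd?).",
          class = "validmi_degenerate")
  }
  u <- k^2 - 1
  rho <- (r_xy + r_zx * r_zy * u) /
    (sqrt(1 + r_zx^2 * u) * sqrt(1 + r_zy^2 * u))
  clipped <- any(is.finite(rho) & abs(rho) > 1)
  rho <- pmin(pmax(rho, -1), 1)
  structure(rho, clipped = clipped)
}

#' Thorndike correction applied to a restricted sample
#'
#' Computes the restricted-sample correlations on the selected cases only
#' (where the criterion is observed), the sd ratio of the selection variable
#' from all applicants versus selected applicants, and applies
#' [correct_drr()] or [correct_irr()]. For a naturally dichotomous criterion
#' the corrected coefficient is the point-biserial correlation. For an
#' artificially dichotomous criterion the restricted correlations with the
#' criterion are first converted to biserial coefficients via [biserial()]
#' -- necessarily with the selected sample's success proportion, the only
#' success proportion this approach can see, which is what ties its biserial
#' estimate to the biased success rate -- and the sd-ratio correction is
#' applied to those. Thorndike's approach yields no estimate of the base
#' rate.
#'
#' @param restricted A restricted sample from [restrict_sample()] (or any
#'   tibble with `x`, `y` containing `NA`, optional `z`, and `selected`).
#' @param kind,scenario Design labels; default to the attributes of
#'   `restricted`.
#' @return A one-row tibble with columns `method` (`"thorndike"`), `r_pb`
#'   (corrected point-biserial), `r_b` (corrected biserial, `NA` for a
#'   natural dichotomy), `br` (always `NA`), and `clipped`.
#' @export
thorndike_estimate <- function(restricted, kind = attr(restricted, "kind"),
                               scenario = attr(restricted, "scenario")) {
  sel <- restricted$selected %||% !is.na(restricted$y)
  x <- restricted$x
  y <- restricted$y
  scenario <- scenario %||% if ("z" %in% names(restricted)) "IRR" else "DRR"
  r_xy <- point_biserial(x[sel], y[sel])
  q_sel <- mean(y[sel])
  artificial <- identical(kind, "artificial")
  clipped <- FALSE
  correct <- if (identical(scenario, "IRR")) {
    z <- restricted$z
    s <- sd(z[sel])
    if (s == 0) abort("Degenerate restriction: restricted sd of Z is zero.",
                      class = "validmi_degenerate")
    k <- sd(z) / s
    r_zx <- cor(z[sel], x[sel])
    r_zy <- point_biserial(z[sel], y[sel])
    function(r, r_cr_z) correct_irr(r, r_zx, r_cr_z, k)
  } else {
    s <- sd(x[sel])
    if (s == 0) abort("Degenerate restriction: restricted sd of X is zero.",
                      class = "validmi_degenerate")
    k <- sd(x) / s
    function(r, r_cr_z) correct_drr(r, k)
  }
  rho_pb <- correct(r_xy, if (identical(scenario, "IRR")) r_zy else NULL)
  clipped <- isTRUE(attr(rho_pb, "clipped"))
  r_b <- NA_real_
  if (artificial) {
    # convert the restricted criterion correlations to biserial form first,
    # then apply the sd-ratio correction to them
    rb_res <- biserial(r_xy, q_sel)
    clipped <- clipped || isTRUE(attr(rb_res, "clipped"))
    rzy_b <- if (identical(scenario, "IRR")) {
      zb <- biserial(r_zy, q_sel)
      clipped <- clipped || isTRUE(attr(zb, "clipped"))
      as.numeric(zb)
    } else NULL
    rb_cor <- correct(as.numeric(rb_res), rzy_b)
    clipped <- clipped || isTRUE(attr(rb_cor, "clipped"))
    r_b <- min(1, max(-1, as.numeric(rb_cor)))
  }
  tibble(method = "thorndike", r_pb = as.numeric(rho_pb), r_b = r_b,
         br = NA_real_, clipped = clipped)
}
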