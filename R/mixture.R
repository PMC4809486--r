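#' Standard deviation of a two-component normal mixture
#'
#' For a naturally dichotomous criterion the continuous predictor is modelled
#' as a mixture of two unit-variance normal distributions, one per criterion
#' group, whose means differ by `d`. The marginal standard deviation of the
#' mixture is `sqrt(1 + br * (1 - br) * d^2)`, where `br` is the base rate of
#' success (the proportion in the "successful" group).
#'
#' @param d Non-negative group mean difference (M1 - M0) on the predictor.
#' @param br Base rate of success, strictly inside (0, 1).
#'
#' @return The mixture standard deviation, a numeric value `>= 1`.
#'
#' @examples
#' mixture_sd(1.5, 0.5) # 1.25
#' @export
mixture_sd <- function(d, br) {
  check_prob_open(br, "br")
  if (!is.numeric(d) || any(!is.finite(d)) || any(d < 0)) {
    abort("`d` must be a finite non-negative mean difference.")
  }
  sqrt(1 + br * (1 - br) * d^2)
}

#' Point-biserial correlation implied by a two-group normal mixture
#'
#' With unit within-group standard deviations, group mean difference `d`, and
#' success proportion `br`, the population point-biserial correlation between
#' the mixture variable and the 0/1 group indicator is
#' `d * sqrt(br * (1 - br)) / mixture_sd(d, br)`.
#'
#' @inheritParams mixture_sd
#' @return The implied point-biserial correlation in `[0, 1)`.
#'
#' @examples
#' pb_from_mixture(1.5, 0.5) # 0.60
#' @export
pb_from_mixture <- function(d, br) {
  d * sqrt(br * (1 - br)) / mixture_sd(d, br)
}

#' Group mean difference needed for a target point-biserial correlation
#'
#' Inverts [pb_from_mixture()]: given a target point-biserial correlation and
#' a base rate, returns the mean difference `d` between the two unit-variance
#' criterion groups that produces it.
#'
#' @param rho_pb Target point-biserial correlation, strictly in (0, 1).
#' @param br Base rate of success, strictly inside (0, 1).
#' @return The group mean difference `d > 0`.
#'
#' @examples
#' d_from_pb(0.60, 0.5) # 1.5
#' @export
d_from_pb <- function(rho_pb, br) {
  check_prob_open(br, "br")
  if (!is.numeric(rho_pb) || any(rho_pb <= 0) || any(rho_pb >= 1)) {
    abort("`rho_pb` must lie strictly in (0, 1): no finite mean difference otherwise.")
  }
  sqrt(rho_pb^2 / (br * (1 - br) * (1 - rho_pb^2)))
}

#' Within-group correlation required for a target marginal Z-X correlation
#'
#' In the indirect-selection mixture design both the predictor X and the
#' selection variable Z shift between criterion groups (by `d_x` and `d_z`).
#' Their marginal covariance decomposes as
#' `cov(Z, X) = rho_w + br * (1 - br) * d_x * d_z`, with `rho_w` the common
#' within-group correlation. Solving for `rho_w` given a target marginal
#' correlation yields
#' `rho_w = rho_zx_target * sigma_X * sigma_Z - br * (1 - br) * d_x * d_z`.
#' Some target combinations are infeasible (`|rho_w| >= 1`); these raise an
#' error so that callers can reject and redraw the factor combination.
#'
#' @param rho_zx_target Target marginal correlation between Z and X.
#' @param d_x,d_z Group mean differences of X and Z.
#' @param br Base rate of success in (0, 1).
#' @return The within-group correlation `rho_w` in (-1, 1).
#' @export
solve_within_corr <- function(rho_zx_target, d_x, d_z, br) {
  check_prob_open(br, "br")
  rho_w <- rho_zx_target * mixture_sd(d_x, br) * mixture_sd(d_z, br) -
    br * (1 - br) * d_x * d_z
  if (!is.finite(rho_w) || abs(rho_w) >= 1) {
    abort(
      sprintf("Infeasible within-group correlation (rho_w = %.4f).", rho_w),
      class = "validmi_infeasible"
    )
  }
  rho_w
}

check_prob_open <- function(p, name) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort(sprintf("`%s` must lie strictly inside (0, 1).", name))
  }
  invisible(p)
}
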