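#' Point-biserial correlation between a continuous and a 0/1 variable
#'
#' Computes `(M1 - M0) * sqrt(p * q) / sigma_x`, where `M1` and `M0` are the
#' group means of `x` for `y = 1` and `y = 0`, `q` and `p` the group
#' proportions, and `sigma_x` the population-denominator (divide-by-n)
#' standard deviation of `x`. With that denominator the value is numerically
#' identical to the product-moment correlation of `x` with the 0/1 coding.
#'
#' @param x Numeric vector (continuous variable).
#' @param y Vector of 0/1 values, same length as `x`; both categories must be
#'   present.
#' @return The point-biserial correlation, a numeric scalar in `[-1, 1]`.
#'
#' @examples
#' point_biserial(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
point_biserial <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have the same length.")
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort("`y` must contain only 0/1 values.")
  ones <- y == 1
  q <- mean(ones)
  if (q == 0 || q == 1) {
    abort("`y` is constant: the point-biserial correlation is undefined.",
          class = "validmi_degenerate")
  }
  sigma_x <- sqrt(mean((x - mean(x))^2))
  if (sigma_x == 0) {
    abort("`x` is constant: the point-biserial correlation is undefined.",
          class = "validmi_degenerate")
  }
  (mean(x[ones]) - mean(x[!ones])) * sqrt(q * (1 - q)) / sigma_x
}

#' Standard normal ordinate at a dichotomization split
#'
#' Returns `dnorm(qnorm(1 - q))`, the height of the standard normal density
#' at the cut-off that leaves upper-tail mass `q`. This is the `h` term of
#' the biserial correlation and is symmetric in `q` and `1 - q`.
#'
#' @param q Upper-tail proportion (proportion coded 1), in (0, 1).
#' @return The density value, a positive scalar.
#' @export
normal_ordinate_at_split <- function(q) {
  check_prob_open(q, "q")
  dnorm(qnorm(1 - q))
}

#' Biserial correlation from a point-biserial correlation
#'
#' When a dichotomy is an artificial split of an underlying normal variable,
#' the biserial coefficient `r_b = r_pb * sqrt(p * q) / h` estimates the
#' latent Pearson correlation, with `h` the normal ordinate at the split
#' ([normal_ordinate_at_split()]). In finite samples the value can exceed 1
#' in magnitude; it is then clipped to +/-1 and flagged via the `"clipped"`
#' attribute.
#'
#' @param r_pb Point-biserial correlation.
#' @param q Proportion of cases coded 1, in (0, 1).
#' @return The biserial correlation (numeric scalar) with a logical
#'   `"clipped"` attribute.
#'
#' @examples
#' biserial(0.3, 0.5)
#' @export
biserial <- function(r_pb, q) {
  h <- normal_ordinate_at_split(q)
  r_b <- r_pb * sqrt(q * (1 - q)) / h
  clipped <- is.finite(r_b) && abs(r_b) > 1
  if (clipped) r_b <- sign(r_b)
  structure(r_b, clipped = clipped)
}
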