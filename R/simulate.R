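#' Draw a feasible factor combination for a simulated applicant population
#'
#' Draws the predictor-criterion correlation, the base rate of success, and
#' (for indirect selection) the Z-X and Z-Y correlations independently from a
#' uniform distribution, redrawing until the combination is feasible: for the
#' latent-normal design the implied correlation matrix must be positive
#' definite, for the mixture design the implied within-group correlation must
#' lie inside (-1, 1). The number of rejected draws is recorded in the
#' `rejections` column.
#'
#' @param scenario `"DRR"` (selection on the predictor X) or `"IRR"`
#'   (selection on a third variable Z).
#' @param kind `"artificial"` (criterion is a dichotomized latent normal) or
#'   `"natural"` (criterion groups are genuinely distinct, mixture design).
#' @param lower,upper Bounds of the uniform factor distribution (defaults
#'   0.1 and 0.9, the ranges of the study design).
#' @param max_tries Abort after this many infeasible draws.
#' @return A one-row tibble with columns `rho_xy`, `br`, for IRR also
#'   `rho_zx`, `rho_zy`, and the rejection count.
#' @export
draw_factors <- function(scenario = c("DRR", "IRR"),
                         kind = c("artificial", "natural"),
                         lower = 0.1, upper = 0.9, max_tries = 1000L) {
  scenario <- match.arg(scenario)
  kind <- match.arg(kind)
  for (try in seq_len(max_tries)) {
    f <- list(rho_xy = runif(1, lower, upper), br = runif(1, lower, upper))
    if (scenario == "IRR") {
      f$rho_zx <- runif(1, lower, upper)
      f$rho_zy <- runif(1, lower, upper)
    }
    if (factors_feasible(f, scenario, kind)) {
      f$rejections <- try - 1L
      return(as_tibble(f))
    }
  }
  abort("No feasible factor combination found.", class = "validmi_infeasible")
}

factors_feasible <- function(f, scenario, kind) {
  if (scenario == "DRR") return(TRUE)
  if (kind == "artificial") {
    sigma <- latent_corr_matrix(f$rho_xy, f$rho_zx, f$rho_zy)
    ok <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
    return(ok)
  }
  # mixture design: within-group correlation must be a valid correlation
  d_x <- d_from_pb(f$rho_xy, f$br)
  d_z <- d_from_pb(f$rho_zy, f$br)
  tryCatch({ solve_within_corr(f$rho_zx, d_x, d_z, f$br); TRUE },
           error = function(e) FALSE)
}

latent_corr_matrix <- function(rho_xy, rho_zx = NULL, rho_zy = NULL) {
  if (is.null(rho_zx)) {
    matrix(c(1, rho_xy, rho_xy, 1), 2, 2,
           dimnames = list(c("x", "ylat"), c("x", "ylat")))
  } else {
    m <- diag(3)
    m[1, 2] <- m[2, 1] <- rho_xy
    m[1, 3] <- m[3, 1] <- rho_zx
    m[2, 3] <- m[3, 2] <- rho_zy
    dimnames(m) <- list(c("x", "ylat", "z"), c("x", "ylat", "z"))
    m
  }
}

#' Simulate an unrestricted applicant population
#'
#' Generates the complete (pre-selection) population for one Monte Carlo
#' iteration. Two designs are available:
#'
#' * `kind = "artificial"`: draws a bivariate (DRR) or trivariate (IRR)
#'   standard normal with the target correlations and dichotomizes the
#'   latent criterion at the cut-off `qnorm(1 - br)`, so values above the
#'   cut are coded 1 ("successful") and the expected success proportion is
#'   `br`.
#' * `kind = "natural"`: draws the 0/1 criterion directly as
#'   i.i.d. Bernoulli(`br`) and gives each criterion group its own
#'   unit-variance normal distribution for X (and Z under IRR), with group
#'   mean differences chosen via [d_from_pb()] so the marginal
#'   point-biserial correlations hit their targets; the within-group Z-X
#'   correlation comes from [solve_within_corr()].
#'
#' @param n Number of applicants.
#' @inheritParams draw_factors
#' @param rho_xy Target predictor-criterion correlation (latent Pearson for
#'   the artificial design, point-biserial for the natural design).
#' @param br Base rate of success in (0, 1).
#' @param rho_zx,rho_zy Target Z-X and Z-Y correlations (IRR only).
#' @return A tibble with columns `x`, `y` (integer 0/1) and, under IRR, `z`,
#'   carrying `scenario`, `kind` and `factors` attributes.
#' @export
simulate_population <- function(n, scenario = c("DRR", "IRR"),
                                kind = c("artificial", "natural"),
                                rho_xy, br, rho_zx = NULL, rho_zy = NULL) {
  scenario <- match.arg(scenario)
  kind <- match.arg(kind)
  if (!is.numeric(n) || n < 2) abort("`n` must be at least 2.")
  check_prob_open(br, "br")
  if (scenario == "IRR" && (is.null(rho_zx) || is.null(rho_zy))) {
    abort("IRR requires `rho_zx` and `rho_zy`.")
  }
  out <- if (kind == "artificial") {
    gen_artificial(n, scenario, rho_xy, br, rho_zx, rho_zy)
  } else {
    gen_natural(n, scenario, rho_xy, br, rho_zx, rho_zy)
  }
  attr(out, "scenario") <- scenario
  attr(out, "kind") <- kind
  attr(out, "factors") <- list(rho_xy = rho_xy, br = br,
                               rho_zx = rho_zx, rho_zy = rho_zy)
  out
}

gen_artificial <- function(n, scenario, rho_xy, br, rho_zx, rho_zy) {
  sigma <- if (scenario == "IRR") {
    latent_corr_matrix(rho_xy, rho_zx, rho_zy)
  } else {
    latent_corr_matrix(rho_xy)
  }
  ok <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
  if (!ok) {
    abort("Target correlation matrix is not positive definite.",
          class = "validmi_infeasible")
  }
  lat <- MASS::mvrnorm(n, mu = rep(0, ncol(sigma)), Sigma = sigma)
  cut <- qnorm(1 - br)
  y <- as.integer(lat[, 2] > cut)
  if (scenario == "IRR") {
    tibble(x = lat[, 1], z = lat[, 3], y = y)
  } else {
    tibble(x = lat[, 1], y = y)
  }
}

gen_natural <- function(n, scenario, rho_xy, br, rho_zx, rho_zy) {
  d_x <- d_from_pb(rho_xy, br)
  y <- rbinom(n, 1L, br)
  if (scenario == "DRR") {
    x <- d_x * y + rnorm(n)
    return(tibble(x = x, y = y))
  }
  d_z <- d_from_pb(rho_zy, br)
  rho_w <- solve_within_corr(rho_zx, d_x, d_z, br) # errors if infeasible
  e_x <- rnorm(n)
  e_z <- rho_w * e_x + sqrt(1 - rho_w^2) * rnorm(n)
  tibble(x = d_x * y + e_x, z = d_z * y + e_z, y = y)
}

#' Sample "true" parameters of an unrestricted population
#'
#' Computes the sample statistics of the complete applicant population that
#' serve as ground truth for the accuracy analysis of the corrections: the
#' point-biserial correlation (product-moment r of x and the 0/1 criterion),
#' the base rate (proportion of successes), for an artificial dichotomy the
#' biserial correlation (via the sample success proportion), and under IRR
#' the Z-X and Z-Y sample correlations.
#'
#' @param data An unrestricted population, e.g. from [simulate_population()].
#' @param kind,scenario Design labels; default to the attributes set by
#'   [simulate_population()].
#' @return A one-row tibble with columns `r_pb`, `br`, and where applicable
#'   `r_b`, `r_zx`, `r_zy`.
#' @export
true_params <- function(data, kind = attr(data, "kind"),
                        scenario = attr(data, "scenario")) {
  y <- data$y
  if (anyNA(y) || anyNA(data$x)) abort("`data` must be complete.")
  if (length(unique(y)) < 2L) {
    abort("Constant criterion: correlations are undefined.",
          class = "validmi_degenerate")
  }
  out <- tibble(r_pb = point_biserial(data$x, y), br = mean(y))
  if (identical(kind, "artificial")) {
    out$r_b <- as.numeric(biserial(out$r_pb, out$br))
  }
  if (identical(scenario, "IRR")) {
    out$r_zx <- cor(data$z, data$x)
    out$r_zy <- point_biserial(data$z, y)
  }
  out
}
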