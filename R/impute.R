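#' Ridge-penalized Bayesian logistic regression fit
#'
#' Fits the logistic model `Pr(y = 1 | x) = plogis(x' beta)` on the observed
#' rows by maximizing a ridge-penalized log-likelihood with Newton steps
#' (iteratively reweighted least squares, with step-halving to keep the
#' penalized likelihood monotone). The small default ridge keeps the
#' optimum finite under (quasi-)separation, which does occur in heavily
#' restricted samples. The returned approximate posterior is multivariate
#' normal around the penalized MLE with the inverse penalized observed
#' information as covariance; [draw_beta()] samples from it.
#'
#' @param predictors Numeric matrix (or vector) of predictor values for the
#'   observed rows, without an intercept column.
#' @param y_obs 0/1 criterion values for the observed rows; both categories
#'   must be present.
#' @param weights Optional non-negative case weights (used by the
#'   stabilizing pseudo-observations of [multiple_impute()]).
#' @param ridge Ridge penalty (default `1e-5`).
#' @param max_iter,tol Iteration cap and relative coefficient-change
#'   tolerance for convergence.
#' @return An object of class `bayes_logreg`: a list with `beta` (intercept
#'   first), `cov`, `converged`, `n_obs`.
#' @export
fit_bayes_logistic <- function(predictors, y_obs, weights = NULL,
                               ridge = 1e-5, max_iter = 150L, tol = 1e-6) {
  X <- cbind(`(Intercept)` = 1, as.matrix(predictors))
  y <- as.numeric(y_obs)
  if (!all(y %in% c(0, 1))) abort("`y_obs` must contain only 0/1 values.")
  if (all(y == 0) || all(y == 1)) {
    abort("`y_obs` is constant: the logistic fit is undefined.",
          class = "validmi_degenerate")
  }
  if (nrow(X) != length(y)) abort("Dimension mismatch.")
  wt <- weights %||% rep(1, length(y))
  if (length(wt) != length(y) || any(wt < 0)) abort("Invalid `weights`.")
  p <- ncol(X)
  beta <- numeric(p)

  pen_ll <- function(b) {
    eta <- drop(X %*% b)
    # numerically stable log(1 + exp(eta))
    log1pe <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
    sum(wt * (y * eta - log1pe)) - ridge / 2 * sum(b^2)
  }

  ll <- pen_ll(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(wt * mu * (1 - mu), 1e-12)
    H <- crossprod(X, X * w)
    diag(H) <- diag(H) + ridge
    g <- drop(crossprod(X, wt * (y - mu))) - ridge * beta
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    new_beta <- beta + step
    new_ll <- pen_ll(new_beta)
    halvings <- 0L
    while ((!is.finite(new_ll) || new_ll < ll - 1e-12) && halvings < 30L) {
      step <- step / 2
      new_beta <- beta + step
      new_ll <- pen_ll(new_beta)
      halvings <- halvings + 1L
    }
    if (!is.finite(new_ll) || new_ll < ll - 1e-12) break
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    ll <- new_ll
    if (delta < tol * (1 + max(abs(beta)))) {
      converged <- TRUE
      break
    }
  }

  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(wt * mu * (1 - mu), 1e-12)
  H <- crossprod(X, X * w)
  diag(H) <- diag(H) + ridge
  cov <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
  if (is.null(cov)) {
    converged <- FALSE
    cov <- matrix(NA_real_, p, p)
  } else {
    cov <- (cov + t(cov)) / 2
  }
  dimnames(cov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  structure(list(beta = beta, cov = cov, converged = converged,
                 n_obs = nrow(X), ridge = ridge),
            class = "bayes_logreg")
}

#' Draw one coefficient vector from the approximate posterior
#'
#' Samples `beta* ~ N(beta_hat, cov_hat)` from the large-sample posterior
#' approximation of a [fit_bayes_logistic()] fit. Each imputation uses an
#' independent draw, so the parameter uncertainty of the imputation model
#' propagates into the imputed values. A covariance that fails its Cholesky
#' factorization is repaired by flooring negative eigenvalues at zero (with
#' a warning); a zero covariance therefore returns `beta_hat` exactly.
#'
#' @param fit A `bayes_logreg` object with `converged = TRUE`.
#' @return A numeric coefficient vector (intercept first).
#' @export
draw_beta <- function(fit) {
  if (!isTRUE(fit$converged)) abort("Fit did not converge; no posterior draw.")
  cv <- fit$cov
  R <- tryCatch(chol(cv), error = function(e) NULL)
  z <- rnorm(length(fit$beta))
  if (is.null(R)) {
    warn("Posterior covariance not positive definite; eigenvalues floored at zero.")
    e <- eigen(cv, symmetric = TRUE)
    L <- e$vectors %*% (t(e$vectors) * sqrt(pmax(e$values, 0)))
    return(fit$beta + drop(L %*% z))
  }
  fit$beta + drop(crossprod(R, z))
}

#' Impute the missing criterion values once
#'
#' For every missing row computes the fitted success probability
#' `p_i = plogis(eta_i)` under the supplied coefficient vector and draws
#' `y_i ~ Bernoulli(p_i)`. Observed values are returned unchanged.
#'
#' @param restricted A restricted sample (columns `x`, optional `z`, `y`
#'   with `NA` for non-selected rows).
#' @param beta_star Coefficient vector: intercept, slope of `x`, and (IRR)
#'   slope of `z`.
#' @param scenario `"DRR"` or `"IRR"`; decides whether `z` enters the
#'   linear predictor. Defaults to the sample's attribute.
#' @return The completed integer 0/1 criterion vector.
#' @export
impute_once <- function(restricted, beta_star,
                        scenario = attr(restricted, "scenario")) {
  scenario <- scenario %||% if ("z" %in% names(restricted)) "IRR" else "DRR"
  y <- as.integer(restricted$y)
  miss <- is.na(y)
  if (!any(miss)) return(y)
  X <- imputation_predictors(restricted, scenario)
  if (length(beta_star) != ncol(X) + 1L) {
    abort("`beta_star` does not match the scenario's predictor set.")
  }
  eta <- beta_star[1L] + drop(X[miss, , drop = FALSE] %*% beta_star[-1L])
  y[miss] <- rbinom(sum(miss), 1L, plogis(eta))
  y
}

imputation_predictors <- function(restricted, scenario) {
  if (identical(scenario, "IRR")) {
    cbind(x = restricted$x, z = restricted$z)
  } else {
    cbind(x = restricted$x)
  }
}

# Stabilizing pseudo-observations against (quasi-)separation: for each
# predictor, one pseudo success and one pseudo failure at its mean +/- half
# an sd (computed over ALL applicants, where the predictors are fully
# observed, and clipped to the observed range), with total pseudo-weight
# p + 1. This is the weighted-augmentation device of White, Daniel &
# Royston that standard multiple-imputation software applies by default to
# its logistic imputation method; it keeps heavily restricted fits finite
# and shrinks extreme slopes slightly.
stabilizing_pseudo_obs <- function(X) {
  p <- ncol(X)
  k <- 2L
  nr <- 2L * p * k
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  mn <- apply(X, 2, min)
  mx <- apply(X, 2, max)
  a <- matrix(mu, nr, p, byrow = TRUE)
  b <- matrix(0, nr, p)
  for (j in seq_len(p)) {
    b[(j - 1L) * 2L * k + seq_len(2L * k), j] <- c(0.5, -0.5)
  }
  d <- a + b * matrix(s, nr, p, byrow = TRUE)
  d <- pmin(pmax(d, matrix(mn, nr, p, byrow = TRUE)),
            matrix(mx, nr, p, byrow = TRUE))
  colnames(d) <- colnames(X)
  list(x = d, y = rep(c(0L, 1L), each = 2L * p), w = rep((p + 1) / nr, nr))
}

# Fast path shared by multiple_impute() and mice_estimate(): returns a list
# of m completed 0/1 vectors, or NULL if the logistic fit failed. The
# imputation model always contains the cause of missingness (X for DRR,
# X and Z for IRR), which the MAR mechanism requires.
impute_y_draws <- function(restricted, m, scenario, ridge = 1e-5,
                           stabilize = TRUE) {
  y <- as.integer(restricted$y)
  miss <- is.na(y)
  if (!any(miss)) return(rep(list(y), m))
  X <- imputation_predictors(restricted, scenario)
  x_fit <- X[!miss, , drop = FALSE]
  y_fit <- y[!miss]
  w_fit <- NULL
  if (stabilize) {
    ps <- stabilizing_pseudo_obs(X)
    x_fit <- rbind(x_fit, ps$x)
    y_fit <- c(y_fit, ps$y)
    w_fit <- c(rep(1, sum(!miss)), ps$w)
  }
  fit <- tryCatch(
    fit_bayes_logistic(x_fit, y_fit, weights = w_fit, ridge = ridge),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged) return(NULL)
  Xmis <- X[miss, , drop = FALSE]
  n_mis <- sum(miss)
  out <- vector("list", m)
  for (j in seq_len(m)) {
    b <- draw_beta(fit)
    eta <- b[1L] + drop(Xmis %*% b[-1L])
    yj <- y
    yj[miss] <- rbinom(n_mis, 1L, plogis(eta))
    out[[j]] <- yj
  }
  out
}

#' Multiple imputation of the binary criterion
#'
#' Fits the Bayesian logistic imputation model once on the observed rows
#' (predictor X under direct selection; X and Z under indirect selection)
#' and produces `m` completed datasets, each built from an independent
#' posterior coefficient draw. Because the criterion is the only incomplete
#' variable, the chained-equations cycle reduces to this single conditional
#' model; no between-variable iteration is required. With no missing values
#' the input is replicated unchanged.
#'
#' @inheritParams impute_once
#' @param m Number of imputations (default 20).
#' @param ridge Ridge penalty passed to [fit_bayes_logistic()].
#' @param stabilize Add the weighted pseudo-observations guarding against
#'   separation (default `TRUE`, the reference default of the logistic
#'   imputation method).
#' @return A list of `m` completed tibbles.
#' @export
multiple_impute <- function(restricted, m = 20L,
                            scenario = attr(restricted, "scenario"),
                            ridge = 1e-5, stabilize = TRUE) {
  if (!is.numeric(m) || m < 1) abort("`m` must be a positive integer.")
  scenario <- scenario %||% if ("z" %in% names(restricted)) "IRR" else "DRR"
  draws <- impute_y_draws(restricted, m, scenario, ridge, stabilize)
  if (is.null(draws)) {
    abort("Imputation model did not converge.", class = "validmi_nonconvergence")
  }
  lapply(draws, function(yj) {
    out <- as_tibble(restricted)
    out$y <- yj
    out
  })
}

#' Pool per-imputation estimates into point estimates
#'
#' For each completed dataset computes the point-biserial correlation of x
#' with the completed criterion, the completed-data success proportion, and
#' for an artificial dichotomy the biserial correlation using that dataset's
#' own success proportion (this is how the imputation route corrects the
#' base-rate distortion that the classical correction cannot). Pooled values
#' are the arithmetic means of the per-imputation estimates; a set of
#' identical values pools to that value exactly.
#'
#' @param completed A list of completed datasets (tibbles with `x` and
#'   complete `y`), e.g. from [multiple_impute()].
#' @param kind `"artificial"` or `"natural"`.
#' @return A one-row tibble with `r_pb`, `r_b` (`NA` for natural), `br`,
#'   `m`, and the per-imputation estimates in the `per_imputation`
#'   attribute.
#' @export
pool_estimates <- function(completed, kind = c("artificial", "natural")) {
  kind <- match.arg(kind)
  pool_y_draws(completed[[1L]]$x, lapply(completed, `[[`, "y"), kind)
}

pool_y_draws <- function(x, y_draws, kind) {
  m <- length(y_draws)
  r_pb <- numeric(m)
  br <- numeric(m)
  r_b <- rep(NA_real_, m)
  ok <- logical(m)
  for (j in seq_len(m)) {
    yj <- y_draws[[j]]
    brj <- mean(yj)
    if (brj == 0 || brj == 1) next # constant completed criterion: drop draw
    r_pb[j] <- point_biserial(x, yj)
    br[j] <- brj
    if (identical(kind, "artificial")) {
      r_b[j] <- as.numeric(biserial(r_pb[j], brj))
    }
    ok[j] <- TRUE
  }
  if (!any(ok)) return(NULL)
  per <- tibble(imputation = which(ok), r_pb = r_pb[ok], br = br[ok],
                r_b = r_b[ok])
  out <- tibble(
    r_pb = pool_mean(per$r_pb),
    r_b = if (identical(kind, "artificial")) pool_mean(per$r_b) else NA_real_,
    br = pool_mean(per$br),
    m = m
  )
  attr(out, "per_imputation") <- per
  out
}

# mean() that returns the common value exactly when all inputs are equal,
# so that pooling is a bit-for-bit no-op when nothing was imputed
pool_mean <- function(v) {
  if (all(v == v[[1L]])) v[[1L]] else mean(v)
}

#' Multiple-imputation correction of a restricted sample
#'
#' Runs the full imputation route on one restricted sample: fit the
#' Bayesian logistic model on the observed rows, draw `m` completed
#' criterion vectors, estimate the predictive validity and base rate on
#' each, and pool by the arithmetic mean.
#'
#' @inheritParams multiple_impute
#' @param kind `"artificial"` or `"natural"`; decides whether a biserial
#'   estimate is produced.
#' @return A one-row tibble with `method` (`"mice"`), `r_pb`, `r_b`, `br`,
#'   `m`; per-imputation estimates in the `per_imputation` attribute.
#'   Returns `NULL` (with no error) if the imputation model fails to
#'   converge, so Monte Carlo callers can exclude the sample.
#' @export
mice_estimate <- function(restricted, kind = attr(restricted, "kind"),
                          scenario = attr(restricted, "scenario"),
                          m = 20L, ridge = 1e-5, stabilize = TRUE) {
  kind <- kind %||% "natural"
  scenario <- scenario %||% if ("z" %in% names(restricted)) "IRR" else "DRR"
  draws <- impute_y_draws(restricted, m, scenario, ridge, stabilize)
  if (is.null(draws)) return(NULL)
  pooled <- pool_y_draws(restricted$x, draws, kind)
  if (is.null(pooled)) return(NULL)
  out <- dplyr::bind_cols(tibble(method = "mice"), pooled)
  attr(out, "per_imputation") <- attr(pooled, "per_imputation")
  out
}
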