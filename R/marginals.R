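#' Specify the marginal response distribution
#'
#' The copula model couples arbitrary GLM marginals through a latent
#' Gaussian field; this object fixes the response family, link, and any
#' family-specific constants. Canonical links are used throughout: log for
#' counts, logit for binomial, identity for Gaussian.
#'
#' The negative binomial uses the mean/dispersion parameterization with
#' variance \code{v(mu) = mu + mu^2 / theta}; \code{theta} near 0 means
#' severe overdispersion and the Poisson arises as \code{theta} tends to
#' infinity. \code{"bernoulli"} is binomial with \code{size = 1}, kept as a
#' separate tag because ungrouped binary data behave very differently in
#' stage 2.
#'
#' @param family one of \code{"poisson"}, \code{"negative_binomial"},
#'   \code{"binomial"}, \code{"bernoulli"}, \code{"gaussian"}.
#' @param size binomial subsample size N (integer, at least 1).
#' @param theta negative binomial dispersion; \code{NULL} means estimate it
#'   by maximum likelihood in \code{\link{fit_margin}}.
#' @param offset optional per-observation additive term on the link scale
#'   (e.g. \code{log} of expected counts in disease mapping).
#' @return An object of class \code{marginal_spec}.
#' @export
marginal_spec <- function(family, size = 1L, theta = NULL, offset = NULL) {
  family <- match.arg(family, c("poisson", "negative_binomial", "binomial",
                                "bernoulli", "gaussian"))
  size <- as.integer(size)
  if (family == "bernoulli") size <- 1L
  if (family %in% c("binomial", "bernoulli")) {
    if (is.na(size) || size < 1L) stop("'size' must be an integer >= 1")
  }
  if (!is.null(theta) && theta <= 0) stop("'theta' must be positive")
  structure(
    list(family = family,
         link = switch(family, gaussian = "identity",
                       binomial = , bernoulli = "logit", "log"),
         size = size, theta = theta, offset = offset),
    class = "marginal_spec"
  )
}

#' @export
print.marginal_spec <- function(x, ...) {
  cat("Marginal family:", x$family, "(", x$link, "link )\n")
  if (x$family == "binomial") cat("  subsample size N =", x$size, "\n")
  if (x$family == "negative_binomial" && !is.null(x$theta)) {
    cat("  dispersion theta =", x$theta, "\n")
  }
  invisible(x)
}

margin_linkinv <- function(spec) {
  switch(spec$link,
    log = exp,
    logit = stats::plogis,
    identity = identity
  )
}

# stats family object used for IRLS; NB with fixed theta is an ordinary
# GLM family via MASS
stats_family <- function(spec, theta = NULL) {
  switch(spec$family,
    poisson = stats::poisson(),
    binomial = , bernoulli = stats::binomial(),
    gaussian = stats::gaussian(),
    negative_binomial = MASS::negative.binomial(theta)
  )
}

#' Fit the stage-1 marginal GLM
#'
#' Ordinary maximum-likelihood GLM fit of the marginal mean model
#' \code{g(E(Y_i)) = x_i' beta + offset_i}, ignoring spatial dependence.
#' For the negative binomial, \code{beta} and the dispersion \code{theta}
#' are estimated jointly by alternating IRLS for \code{beta} given
#' \code{theta} with one-dimensional ML for \code{theta} given \code{beta}.
#' Leverages come from the weighted hat matrix of the final IRLS step,
#' \code{H = W^{1/2} X (X'WX)^{-1} X' W^{1/2}}.
#'
#' Binomial responses are passed as success counts out of \code{spec$size}
#' trials; internally the fit uses the proportion with prior weight N, so
#' residuals and leverages match a \code{cbind(successes, failures)} fit.
#'
#' @param X design matrix (n x p), full column rank. No intercept is added
#'   implicitly; include a column of ones if one is wanted.
#' @param y response vector in the family's support.
#' @param spec a \code{\link{marginal_spec}}.
#' @param start optional starting coefficients for IRLS.
#' @return An object of class \code{margin_fit} with coefficients,
#'   coefficient covariance, leverages, Pearson and deviance residuals,
#'   fitted means, log-likelihood, AIC, and (negative binomial) the
#'   dispersion estimate.
#' @export
fit_margin <- function(X, y, spec, start = NULL) {
  stopifnot(inherits(spec, "marginal_spec"))
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length of 'y' must match nrow(X)")
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  offset <- if (is.null(spec$offset)) rep(0, n) else spec$offset
  check_support(spec, y)

  if (spec$family %in% c("binomial", "bernoulli")) {
    yy <- y / spec$size
    wts <- rep(spec$size, n)
  } else {
    yy <- y
    wts <- rep(1, n)
  }

  if (spec$family == "negative_binomial" && is.null(spec$theta)) {
    fit <- fit_nb_ml(X, yy, offset, start)
    theta_hat <- fit$theta
    fam <- MASS::negative.binomial(theta_hat)
    n_extra <- 1L          # theta counts as an estimated marginal parameter
  } else {
    theta_hat <- spec$theta
    fam <- stats_family(spec, theta_hat)
    fit <- stats::glm.fit(X, yy, weights = wts, offset = offset,
                          family = fam, start = start)
    if (!fit$converged) stop("IRLS did not converge after ", fit$iter, " iterations")
    n_extra <- if (spec$family == "gaussian") 1L else 0L  # sigma^2 for gaussian
  }

  mu <- fit$fitted.values
  w <- fit$weights                     # IRLS working weights at convergence
  pearson <- (yy - mu) * sqrt(wts) / sqrt(fam$variance(mu))
  dev_i <- fam$dev.resids(yy, mu, wts)
  deviance <- sign(yy - mu) * sqrt(pmax(dev_i, 0))
  h <- leverages_from_wls(X, w)

  ll <- margin_loglik(spec, y, mu, theta_hat, wts)
  n_par <- p + n_extra
  dispersion <- if (spec$family == "gaussian") sum((yy - mu)^2) / (n - p) else 1
  XtWX_inv <- chol2inv(chol(crossprod(X, X * w)))

  structure(
    list(coefficients = stats::setNames(fit$coefficients, colnames(X)),
         coef_cov = dispersion * XtWX_inv,
         leverages = h,
         pearson_residuals = pearson,
         deviance_residuals = deviance,
         fitted_means = if (spec$family %in% c("binomial", "bernoulli"))
           mu * spec$size else mu,
         fitted_prob = if (spec$family %in% c("binomial", "bernoulli")) mu else NULL,
         theta = theta_hat,
         loglik = ll, n_par = n_par, aic = 2 * n_par - 2 * ll,
         spec = spec, X = X, y = y, n = n),
    class = "margin_fit"
  )
}

check_support <- function(spec, y) {
  bad <- switch(spec$family,
    poisson = , negative_binomial = any(y < 0 | y != floor(y)),
    binomial = , bernoulli = any(y < 0 | y > spec$size | y != floor(y)),
    gaussian = any(!is.finite(y))
  )
  if (isTRUE(bad)) stop("response outside the support of family '", spec$family, "'")
  invisible(y)
}

leverages_from_wls <- function(X, w) {
  qrW <- qr(X * sqrt(w))
  h <- rowSums(qr.Q(qrW)[, seq_len(qrW$rank), drop = FALSE]^2)
  pmin(h, 1)
}

# alternating ML for the negative binomial: IRLS for beta given theta,
# then MASS::theta.ml for theta given the fitted means
fit_nb_ml <- function(X, y, offset, start = NULL, tol = 1e-8, max_it = 50L) {
  mu0 <- pmax(y, 0.5)
  theta <- max(0.1, mean(mu0)^2 / max(stats::var(y) - mean(mu0), 0.1))
  fit <- NULL
  ll_old <- -Inf
  for (it in seq_len(max_it)) {
    fit <- stats::glm.fit(X, y, offset = offset,
                          family = MASS::negative.binomial(theta),
                          start = if (is.null(fit)) start else fit$coefficients)
    theta <- as.numeric(suppressWarnings(
      MASS::theta.ml(y, fit$fitted.values, limit = 25)
    ))
    ll <- sum(stats::dnbinom(y, size = theta, mu = fit$fitted.values, log = TRUE))
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  fit$theta <- theta
  fit
}

margin_loglik <- function(spec, y, mu, theta, wts) {
  switch(spec$family,
    poisson = sum(stats::dpois(y, mu, log = TRUE)),
    negative_binomial = sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE)),
    binomial = , bernoulli =
      sum(stats::dbinom(y, size = spec$size, prob = mu, log = TRUE)),
    gaussian = {
      n <- length(y)
      s2 <- sum((y - mu)^2) / n          # ML variance
      -n / 2 * (log(2 * pi * s2) + 1)
    }
  )
}

#' @export
print.margin_fit <- function(x, ...) {
  cat("Marginal GLM fit (", x$spec$family, ")\n", sep = "")
  print(round(x$coefficients, 4))
  if (x$spec$family == "negative_binomial") {
    cat("theta =", format(x$theta, digits = 4), "\n")
  }
  cat("log-likelihood:", format(x$loglik, digits = 6),
      " AIC:", format(x$aic, digits = 6), "\n")
  invisible(x)
}

#' Standardized residuals
#'
#' Pearson or deviance residuals divided by \code{sqrt(1 - h_i)}, where
#' \code{h_i} is the leverage. These are the stage-2 inputs: approximately
#' standard normal for most GLMs, they are treated as a realization of the
#' latent Gaussian field when estimating the copula parameters.
#'
#' @param fit a \code{\link{fit_margin}} result.
#' @param type \code{"deviance"} (default; closer to normal for discrete
#'   families) or \code{"pearson"}.
#' @return Numeric residual vector.
#' @export
standardized_residuals <- function(fit, type = c("deviance", "pearson")) {
  type <- match.arg(type)
  h <- fit$leverages
  if (any(h >= 1 - 1e-10)) {
    stop("leverage of observation ", which.max(h), " is numerically 1")
  }
  e <- switch(type, pearson = fit$pearson_residuals,
              deviance = fit$deviance_residuals)
  e / sqrt(1 - h)
}

#' Randomized quantile residuals
#'
#' For a discrete response, draws \code{u_i} uniformly on the cdf jump
#' interval \code{(F_i(y_i - 1), F_i(y_i)]} and returns \code{qnorm(u_i)};
#' for a continuous response this reduces to \code{qnorm(F_i(y_i))} with no
#' randomization. Exactly standard normal under a correctly specified
#' model, which makes them the recommended residual for model assessment
#' with discrete data (standardized residuals band badly). They are not a
#' substitute for standardized residuals in stage 2: the randomization
#' obscures the dependence structure.
#'
#' @param fit a \code{\link{fit_margin}} result.
#' @param seed optional integer seed for the uniform draws.
#' @return Numeric residual vector.
#' @export
randomized_quantile_residuals <- function(fit, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- fit$spec
  mu <- fit$fitted_means
  y <- fit$y
  if (spec$family == "gaussian") {
    sd <- sqrt(sum((y - mu)^2) / length(y))
    return(stats::qnorm(stats::pnorm(y, mu, sd)))
  }
  hi <- marginal_cdf(spec, mu, y, theta = fit$theta)
  lo <- ifelse(y > 0, marginal_cdf(spec, mu, y - 1, theta = fit$theta), 0)
  u <- stats::runif(length(y), lo, hi)
  stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
}

#' Marginal cdf and quantile function
#'
#' \code{marginal_cdf} evaluates \code{F(y | mu)}; \code{marginal_quantile}
#' is its generalized inverse, i.e. for discrete families the smallest
#' support value whose cdf reaches \code{u}. These are the two halves of
#' the probability integral transform that couples the marginals to the
#' latent Gaussian field.
#'
#' @param spec a \code{\link{marginal_spec}}.
#' @param mu mean vector (on the response scale; for binomial families the
#'   expected count out of \code{size} trials).
#' @param y value(s) at which to evaluate the cdf.
#' @param theta negative binomial dispersion (overrides \code{spec$theta}).
#' @param sd Gaussian standard deviation (default 1).
#' @return Probabilities (\code{marginal_cdf}) or support values
#'   (\code{marginal_quantile}).
#' @export
marginal_cdf <- function(spec, mu, y, theta = spec$theta, sd = 1) {
  switch(spec$family,
    poisson = stats::ppois(y, mu),
    negative_binomial = stats::pnbinom(y, size = theta, mu = mu),
    binomial = , bernoulli = stats::pbinom(y, size = spec$size, prob = mu / spec$size),
    gaussian = stats::pnorm(y, mu, sd)
  )
}

#' @rdname marginal_cdf
#' @param u probabilities strictly inside (0, 1).
#' @export
marginal_quantile <- function(spec, mu, u, theta = spec$theta, sd = 1) {
  if (any(u <= 0 | u >= 1)) stop("'u' must lie strictly inside (0, 1)")
  switch(spec$family,
    poisson = stats::qpois(u, mu),
    negative_binomial = stats::qnbinom(u, size = theta, mu = mu),
    binomial = , bernoulli = stats::qbinom(u, size = spec$size, prob = mu / spec$size),
    gaussian = stats::qnorm(u, mu, sd)
  )
}

#' AIC of the marginal fit
#'
#' \code{2p - 2 loglik}, where \code{p} counts every estimated marginal
#' parameter (regression coefficients, plus the dispersion for the negative
#' binomial and the variance for the Gaussian). Useful for choosing the
#' response family even under dependence.
#'
#' @param fit a \code{\link{fit_margin}} result.
#' @return A number.
#' @export
aic_glm <- function(fit) 2 * fit$n_par - 2 * fit$loglik
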