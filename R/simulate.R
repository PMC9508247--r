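#' Simulate responses from a spatial Gaussian copula regression model
#'
#' Generates data by the model's own chain: draw the latent field
#' \code{Z ~ N(0, Omega)}, map to uniforms \code{U = pnorm(Z)} (probability
#' integral transform), and push each \code{U_i} through the marginal
#' quantile function at mean \code{g^{-1}(x_i' beta + offset_i)} (inverse
#' probability integral transform). The marginals are exact whatever the
#' dependence; only the joint law changes with \code{Omega}.
#'
#' @param structure a \code{corr_structure} (or a fully specified
#'   \code{copula_spec}, which is resolved internally).
#' @param mspec a \code{\link{marginal_spec}}.
#' @param X design matrix.
#' @param beta regression coefficients.
#' @param nsim number of independent response vectors.
#' @param seed optional integer seed.
#' @param Z optional pre-drawn latent matrix (n x nsim); a test hook, e.g.
#'   a zero matrix forces every response to its marginal median.
#' @return Numeric vector (\code{nsim = 1}) or n x nsim matrix.
#' @export
simulate_sgcrm <- function(structure, mspec, X, beta, nsim = 1L,
                           seed = NULL, Z = NULL) {
  if (inherits(structure, "copula_spec")) structure <- copula_structure(structure)
  stopifnot(inherits(structure, "corr_structure"))
  X <- as.matrix(X)
  if (structure$n != nrow(X)) stop("'X' rows must match the copula dimension")
  if (!is.null(seed)) set.seed(seed)
  eta <- drop(X %*% beta)
  if (!is.null(mspec$offset)) eta <- eta + mspec$offset
  mu <- margin_linkinv(mspec)(eta)
  if (mspec$family %in% c("binomial", "bernoulli")) mu <- mu * mspec$size
  if (is.null(Z)) Z <- sample_latent(structure, nsim)
  U <- pmin(pmax(stats::pnorm(Z), 1e-12), 1 - 1e-12)
  Y <- matrix(marginal_quantile(mspec, rep(mu, ncol(U)), as.vector(U)),
              structure$n, ncol(U))
  if (ncol(Y) == 1L) drop(Y) else Y
}

#' Simulation scenario presets
#'
#' Returns the complete generating configuration for one of six study
#' scenarios spanning both spatial-domain notions, the common discrete
#' response families, and strong versus weaker dependence:
#'
#' \tabular{llllll}{
#'  \strong{id} \tab \strong{response} \tab \strong{copula} \tab
#'    \strong{grid} \tab \strong{dependence} \tab \strong{beta} \cr
#'  1 \tab Poisson \tab proper CAR \tab 30x30 \tab rho = 0.99 \tab (3, 1) \cr
#'  2 \tab Poisson \tab proper CAR \tab 30x30 \tab rho = 0.8 \tab (3, 1) \cr
#'  3 \tab binomial N = 20 \tab Leroux \tab 40x40 \tab lambda = 0.95 \tab (2, 0.5) \cr
#'  4 \tab Bernoulli \tab exponential \tab 30x30 \tab phi = 0.3 \tab (2, 0.5) \cr
#'  5 \tab neg. binomial theta = 3 \tab Matern \tab 20x20 \tab phi = 0.1, nu = 1 \tab (3, 1) \cr
#'  6 \tab neg. binomial theta = 3 \tab Matern \tab 20x20 \tab phi = 0.03, nu = 1 \tab (3, 1)
#' }
#'
#' Areal scenarios (1-3) use the rook-adjacency lattice graph as the
#' spatial domain; point-level scenarios (4-6) use the matching grid of
#' locations in the unit square centered at the origin. In every scenario
#' the covariates are the grid coordinates themselves -- an east-west
#' coordinate \code{x} and a north-south coordinate \code{y}, each spanning
#' \code{[-0.5, 0.5]} -- with no intercept, so the mean surface is
#' \code{g^{-1}(beta1 * x + beta2 * y)} with a log link for counts and a
#' logit link for (grouped or ungrouped) binomial responses.
#'
#' @param scenario_id integer 1 to 6.
#' @return A list of class \code{scenario_config} with the domain objects,
#'   design matrix, true coefficients, marginal spec, fully parameterized
#'   generating \code{copula_spec}, and a free-parameter copy
#'   (\code{fit_copula}) for stage-2 estimation.
#' @export
scenario_config <- function(scenario_id) {
  id <- as.integer(scenario_id)
  if (is.na(id) || id < 1L || id > 6L) stop("'scenario_id' must be 1..6")
  dims <- switch(id, c(30L, 30L), c(30L, 30L), c(40L, 40L),
                 c(30L, 30L), c(20L, 20L), c(20L, 20L))
  X <- lattice_coordinates(dims[1L], dims[2L])
  mspec <- switch(id,
    marginal_spec("poisson"), marginal_spec("poisson"),
    marginal_spec("binomial", size = 20L),
    marginal_spec("bernoulli"),
    marginal_spec("negative_binomial", theta = 3),
    marginal_spec("negative_binomial", theta = 3)
  )
  beta <- switch(id, c(3, 1), c(3, 1), c(2, 0.5), c(2, 0.5), c(3, 1), c(3, 1))
  if (id <= 3L) {
    domain <- square_lattice(dims[1L], dims[2L])
    gen <- switch(id,
      copula_spec("car", domain, list(rho = 0.99)),
      copula_spec("car", domain, list(rho = 0.8)),
      copula_spec("leroux", domain, list(lambda = 0.95))
    )
    fit_cop <- copula_spec(gen$family, domain)
  } else {
    domain <- unit_square_grid(dims[1L], dims[2L])
    gen <- switch(id - 3L,
      copula_spec("exponential", domain, list(phi = 0.3)),
      copula_spec("matern", domain, list(phi = 0.1, nu = 1)),
      copula_spec("matern", domain, list(phi = 0.03, nu = 1))
    )
    fit_cop <- copula_spec(gen$family, domain)
  }
  # the fit side estimates nuisance marginal parameters that the generator
  # fixes (the negative binomial dispersion)
  fit_mspec <- if (mspec$family == "negative_binomial") {
    marginal_spec("negative_binomial")
  } else {
    mspec
  }
  structure(
    list(scenario_id = id, dims = dims, domain = domain, X = X,
         beta = beta, mspec = mspec, fit_mspec = fit_mspec,
         copula = gen, fit_copula = fit_cop),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario", x$scenario_id, ":", x$mspec$family, "response,",
      x$copula$family, "copula,", paste(x$dims, collapse = "x"), "grid\n")
  cat("  beta = (", paste(x$beta, collapse = ", "), "), ",
      paste(names(x$copula$params), unlist(x$copula$params),
            sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-site mean vector of a scenario
#'
#' Evaluates the generating mean surface \code{g^{-1}(beta1 x + beta2 y)}
#' at every grid location (count rates for log-link families, success
#' probabilities for binomial families).
#'
#' @param config a \code{\link{scenario_config}}.
#' @return Numeric vector of means (probabilities for binomial families,
#'   not expected counts).
#' @export
scenario_mean_structure <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  margin_linkinv(config$mspec)(drop(config$X %*% config$beta))
}

#' Simulate replicate datasets from a scenario
#'
#' @param config a \code{\link{scenario_config}}.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @return n x nsim matrix of responses.
#' @export
simulate_scenario <- function(config, nsim = 1L, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  cop <- config$copula
  Z <- if (cop$family %in% c("car", "leroux")) {
    areal_sample_latent(cop$domain, cop$family, cop$params[[1L]], nsim)
  } else {
    sample_latent(copula_structure(cop), nsim)
  }
  Y <- simulate_sgcrm(scenario_structure(config), config$mspec, config$X,
                      config$beta, nsim = nsim, Z = Z)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L)
  Y
}

# resolve (and cache) the generating correlation structure of a scenario
scenario_structure <- function(config) {
  key <- "gen_structure"
  env <- if (inherits(config$domain, "areal_graph")) config$domain$cache else NULL
  if (!is.null(env)) {
    st <- get0(key, envir = env)
    if (!is.null(st)) return(st)
  }
  st <- copula_structure(config$copula)
  if (!is.null(env)) assign(key, st, envir = env)
  st
}
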