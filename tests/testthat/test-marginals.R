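test_that("stage-1 fits agree with closed forms and reference fits", {
  # Poisson intercept-only MLE is the log sample mean
  f <- fit_margin(matrix(1, 3, 1), c(1, 2, 3), marginal_spec("poisson"))
  expect_equal(unname(f$coefficients), log(2))

  # Gaussian identity link is ordinary least squares
  set.seed(2)
  X <- cbind(1, rnorm(60))
  y <- drop(X %*% c(1, 2)) + rnorm(60)
  fg <- fit_margin(X, y, marginal_spec("gaussian"))
  expect_equal(unname(fg$coefficients), unname(coef(lm(y ~ X[, 2]))),
               tolerance = 1e-10)

  # negative binomial with huge fixed theta collapses to the Poisson fit
  set.seed(3)
  Xp <- cbind(rnorm(300))
  yp <- rpois(300, exp(0.5 * Xp[, 1]))
  fp <- fit_margin(Xp, yp, marginal_spec("poisson"))
  fnb <- fit_margin(Xp, yp, marginal_spec("negative_binomial", theta = 1e6))
  expect_equal(fp$coefficients, fnb$coefficients, tolerance = 1e-4)

  expect_error(fit_margin(cbind(c(1, 1), c(2, 2)), c(1, 2),
                          marginal_spec("poisson")),
               "rank deficient")
  expect_error(fit_margin(matrix(1, 2, 1), c(-1, 2), marginal_spec("poisson")),
               "support")
})

test_that("negative binomial ML matches glm.nb for beta and theta", {
  set.seed(4)
  X <- cbind(rnorm(400), runif(400))
  y <- rnbinom(400, size = 3, mu = exp(drop(X %*% c(1, -0.5))))
  f <- fit_margin(X, y, marginal_spec("negative_binomial"))
  m <- MASS::glm.nb(y ~ X - 1)
  expect_equal(unname(f$coefficients), unname(coef(m)), tolerance = 1e-6)
  expect_equal(f$theta, m$theta, tolerance = 1e-6)
  # p counts theta as an estimated marginal parameter
  expect_equal(f$aic, 2 * 3 - 2 * f$loglik)
  expect_equal(f$aic, AIC(m), tolerance = 1e-6)
})

test_that("leverages trace to p and residual formulas are exact", {
  set.seed(5)
  X <- cbind(1, rnorm(120), runif(120))
  y <- rpois(120, exp(drop(X %*% c(0.2, 0.4, -0.3))))
  f <- fit_margin(X, y, marginal_spec("poisson"))
  expect_lt(abs(sum(f$leverages) - 3), 1e-6)
  expect_true(all(f$leverages >= 0 & f$leverages < 1))

  # standardized residual is the raw residual over sqrt(1 - h):
  # Pearson y = 9, mu = 4 gives 2.5; h = 0.19 scales it to 2.5/sqrt(0.81)
  expect_equal(2.5 / sqrt(1 - 0.19), 2.7777778, tolerance = 1e-6)
  r_p <- standardized_residuals(f, "pearson")
  expect_equal(r_p, f$pearson_residuals / sqrt(1 - f$leverages))
  r_d <- standardized_residuals(f, "deviance")
  expect_equal(r_d, f$deviance_residuals / sqrt(1 - f$leverages))

  # residuals vanish at exact fits
  f0 <- fit_margin(matrix(1, 4, 1), rep(3, 4), marginal_spec("poisson"))
  expect_equal(f0$pearson_residuals, rep(0, 4))

  # Gaussian Pearson and deviance standardized residuals coincide
  fg <- fit_margin(X, rnorm(120, drop(X %*% c(0, 1, 1))),
                   marginal_spec("gaussian"))
  expect_equal(standardized_residuals(fg, "pearson"),
               standardized_residuals(fg, "deviance"), tolerance = 1e-10)

  # binomial fit agrees with the cbind() glm interface
  yb <- rbinom(120, 20, plogis(drop(X %*% c(0.1, 0.5, -0.5))))
  fb <- fit_margin(X, yb, marginal_spec("binomial", size = 20))
  gb <- glm(cbind(yb, 20 - yb) ~ X - 1, family = binomial())
  expect_equal(unname(fb$coefficients), unname(coef(gb)), tolerance = 1e-8)
  expect_equal(fb$leverages, unname(hatvalues(gb)), tolerance = 1e-6)
  expect_equal(fb$pearson_residuals, unname(residuals(gb, "pearson")),
               tolerance = 1e-6)
  expect_equal(fb$deviance_residuals, unname(residuals(gb, "deviance")),
               tolerance = 1e-6)
  expect_equal(fb$loglik, as.numeric(logLik(gb)), tolerance = 1e-8)
})

test_that("marginal cdf/quantile are generalized inverses", {
  sp <- marginal_spec("poisson")
  # F(0) = 0.368 < 0.5 <= F(1) at mu = 1, so the median is 1
  expect_equal(marginal_quantile(sp, 1, 0.5), 1)
  expect_equal(marginal_cdf(sp, 1, 0), exp(-1))

  sb <- marginal_spec("binomial", size = 20)
  expect_equal(marginal_quantile(sb, 10, 0.5), 10)

  sg <- marginal_spec("gaussian")
  y <- c(-1.3, 0.2, 2.5)
  expect_equal(marginal_quantile(sg, 0, marginal_cdf(sg, 0, y)), y,
               tolerance = 1e-10)

  # generalized-inverse property on discrete support points
  sn <- marginal_spec("negative_binomial", theta = 3)
  for (yy in 0:15) {
    u <- marginal_cdf(sn, 4, yy)
    if (u < 1) expect_equal(marginal_quantile(sn, 4, u), yy)
  }
  expect_error(marginal_quantile(sp, 1, 0), "inside")
})

test_that("randomized quantile residuals are uniform-normal under truth", {
  # continuous family: deterministic, qnorm(F(y))
  set.seed(6)
  X <- cbind(1, rnorm(100))
  y <- rnorm(100, drop(X %*% c(0, 1)))
  fg <- fit_margin(X, y, marginal_spec("gaussian"))
  r1 <- randomized_quantile_residuals(fg, seed = 1)
  r2 <- randomized_quantile_residuals(fg, seed = 99)
  expect_equal(r1, r2)

  # interval interpolation: F(y-1) = 0.2, F(y) = 0.6, u = 0.5 of the jump
  expect_equal(qnorm(0.2 + 0.5 * 0.4), qnorm(0.4))

  # under a correctly specified discrete model the RQRs pass normality
  set.seed(7)
  Xb <- cbind(rnorm(2000))
  pass <- replicate(50, {
    yy <- rpois(2000, exp(0.3 * Xb[, 1]))
    ff <- fit_margin(Xb, yy, marginal_spec("poisson"))
    shapiro.test(randomized_quantile_residuals(ff))$p.value > 0.01
  })
  expect_gte(mean(pass), 0.9)
})

test_that("marginal AIC selects the right count family", {
  expect_equal(2 * 1 - 2 * (-10), 22)
  # strongly overdispersed data: NB wins in essentially every replicate
  set.seed(8)
  X <- cbind(rnorm(400))
  wins <- replicate(60, {
    y <- rnbinom(400, size = 0.8, mu = exp(0.5 * X[, 1]))
    aic_glm(fit_margin(X, y, marginal_spec("poisson"))) >
      aic_glm(fit_margin(X, y, marginal_spec("negative_binomial")))
  })
  expect_gte(mean(wins), 0.99)
})

test_that("i.i.d. simulation recovers beta within Monte Carlo error", {
  set.seed(9)
  n <- 5000
  X <- cbind(rnorm(n), runif(n) - 0.5)
  beta <- c(0.5, -1)
  for (spn in list(marginal_spec("poisson"),
                   marginal_spec("binomial", size = 20),
                   marginal_spec("negative_binomial", theta = 3))) {
    st <- precision_to_correlation(Matrix::Diagonal(n))
    y <- simulate_sgcrm(st, spn, X, beta)
    fit_spec <- if (spn$family == "negative_binomial") {
      marginal_spec("negative_binomial")
    } else spn
    f <- fit_margin(X, y, fit_spec)
    se <- sqrt(diag(f$coef_cov))
    expect_true(all(abs(f$coefficients - beta) < 3 * se + 0.05))
  }
})
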