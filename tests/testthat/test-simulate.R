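test_that("scenario presets encode the study design", {
  c3 <- scenario_config(3)
  expect_equal(c3$mspec$family, "binomial")
  expect_equal(c3$mspec$size, 20L)
  expect_equal(c3$copula$family, "leroux")
  expect_equal(c3$copula$params$lambda, 0.95)
  expect_equal(c3$dims, c(40L, 40L))
  expect_equal(c3$beta, c(2, 0.5))

  c4 <- scenario_config(4)
  expect_equal(c4$mspec$family, "bernoulli")
  expect_equal(c4$copula$family, "exponential")
  expect_equal(c4$copula$params$phi, 0.3)
  expect_s3_class(c4$domain, "point_set")
  expect_equal(c4$domain$n, 900L)

  c6 <- scenario_config(6)
  expect_equal(c6$mspec$family, "negative_binomial")
  expect_equal(c6$mspec$theta, 3)
  expect_equal(c6$copula$params, list(phi = 0.03, nu = 1))
  expect_equal(c6$dims, c(20L, 20L))
  expect_equal(c6$beta, c(3, 1))
  # fit side leaves the dispersion free
  expect_null(c6$fit_mspec$theta)
  expect_error(scenario_config(7), "1..6")
})

test_that("scenario mean structures follow the stated link and surface", {
  c3 <- scenario_config(3)
  mu3 <- scenario_mean_structure(c3)
  corner <- which(c3$X[, 1] == 0.5 & c3$X[, 2] == 0.5)
  expect_equal(mu3[corner], exp(1.25) / (1 + exp(1.25)), tolerance = 1e-12)
  expect_true(all(mu3 > 0.15 & mu3 < 0.85))   # range roughly 0.2 to 0.8

  c1 <- scenario_config(1)
  mu1 <- scenario_mean_structure(c1)
  expect_equal(mu1, exp(drop(c1$X %*% c(3, 1))))  # log link, rate 1 at (0,0)
  expect_equal(which.max(mu1), which(c1$X[, 1] == 0.5 & c1$X[, 2] == 0.5))
  expect_equal(which.min(mu1), which(c1$X[, 1] == -0.5 & c1$X[, 2] == -0.5))
})

test_that("degenerate latent field gives the marginal medians", {
  c1 <- scenario_config(1)
  st <- copula_structure(c1$copula)
  y <- simulate_sgcrm(st, c1$mspec, c1$X, c1$beta, Z = matrix(0, 900, 1))
  expect_equal(y, qpois(0.5, scenario_mean_structure(c1)))
})

test_that("simulation preserves the marginal laws under dependence", {
  # i.i.d. limit: sample mean of strong-rate Poisson draws
  n <- 10000
  st <- precision_to_correlation(Matrix::Diagonal(n))
  set.seed(41)
  y <- simulate_sgcrm(st, marginal_spec("poisson"), matrix(1, n, 1), log(5))
  expect_lt(abs(mean(y) - 5), 3 * sqrt(5 / n))

  # per-site chi-square goodness of fit under the Scenario 1 copula
  c1 <- scenario_config(1)
  mu <- scenario_mean_structure(c1)
  set.seed(42)
  Z <- sgcreg:::areal_sample_latent(c1$domain, "car", 0.99, 2000)
  sites <- round(seq(1, 900, length.out = 20))
  pvals <- vapply(sites, function(i) {
    yi <- qpois(pnorm(Z[i, ]), mu[i])
    brk <- qpois(seq(0, 1, by = 0.1), mu[i])
    brk <- unique(c(-1, brk[is.finite(brk)], Inf))
    obs <- table(cut(yi, brk))
    expp <- diff(ppois(head(brk, -1), mu[i]))
    expp <- c(expp, 1 - sum(expp))
    keep <- expp > 1e-12
    suppressWarnings(chisq.test(as.numeric(obs)[keep],
                                p = expp[keep] / sum(expp[keep]))$p.value)
  }, 0)
  expect_true(all(pvals > 0.01 / 20))
})

test_that("latent correlation survives the discrete transform approximately", {
  c1 <- scenario_config(1)
  st <- copula_structure(c1$copula)
  om <- correlation_matrix(st)
  set.seed(43)
  Z <- sgcreg:::areal_sample_latent(c1$domain, "car", 0.99, 5000)
  U <- pnorm(Z)                 # the copula uniforms of the generating chain
  pairs <- cbind(round(seq(1, 880, length.out = 10)),
                 round(seq(1, 880, length.out = 10)) + 1L)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    # normal scores of the empirical cdf transform of the uniforms
    zi <- qnorm((rank(U[i, ]) - 0.5) / ncol(U))
    zj <- qnorm((rank(U[j, ]) - 0.5) / ncol(U))
    expect_lt(abs(cor(zi, zj) - om[i, j]), 0.05)
  }
})

test_that("positive dependence deflates across-site variance of NB draws", {
  c5 <- scenario_config(5)
  st <- copula_structure(c5$copula)
  id <- precision_to_correlation(Matrix::Diagonal(400))
  set.seed(44)
  v_dep <- mean(apply(simulate_sgcrm(st, c5$mspec, c5$X, c5$beta,
                                     nsim = 100), 2, var))
  v_ind <- mean(apply(simulate_sgcrm(id, c5$mspec, c5$X, c5$beta,
                                     nsim = 100), 2, var))
  expect_lt(v_dep, v_ind)
})

test_that("scenario draws carry positive neighbour autocorrelation", {
  c1 <- scenario_config(1)
  edges <- c1$domain$edges
  mu <- scenario_mean_structure(c1)
  set.seed(45)
  Y <- simulate_scenario(c1, nsim = 50)
  # Moran-style cross product of mean-centered responses over lattice edges
  moran <- apply(Y, 2, function(y) {
    e <- y - mu
    sum(e[edges[, 1]] * e[edges[, 2]]) / sum(e^2)
  })
  expect_true(all(moran > 0))
})

test_that("scenario simulation is reproducible from its seed", {
  c2 <- scenario_config(2)
  y1 <- simulate_scenario(c2, nsim = 3, seed = 9)
  y2 <- simulate_scenario(c2, nsim = 3, seed = 9)
  expect_identical(y1, y2)
})
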