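test_that("CAR and Leroux precisions match closed forms", {
  g <- path_graph(3)
  expect_equal(as.matrix(car_precision(g, 0.5)),
               matrix(c(1, -0.5, 0, -0.5, 2, -0.5, 0, -0.5, 1), 3))
  expect_equal(as.matrix(car_precision(g, 0)), diag(c(1, 2, 1)))
  expect_equal(as.matrix(leroux_precision(g, 0.5)),
               matrix(c(1, -0.5, 0, -0.5, 1.5, -0.5, 0, -0.5, 1), 3))
  expect_equal(as.matrix(leroux_precision(g, 0)), diag(3))
  # intrinsic limit: D - A singular (constant null vector)
  expect_equal(unname(rowSums(as.matrix(car_precision(g, 1 - 1e-12)))),
               rep(0, 3), tolerance = 1e-9)
  expect_error(car_precision(g, 1), "singular")
  expect_error(leroux_precision(g, 1.2), "\\[0, 1\\)")
})

test_that("Leroux smallest eigenvalue is bounded below by 1 - lambda", {
  g <- square_lattice(5, 7)
  for (lam in c(0.2, 0.8, 0.99)) {
    ev <- eigen(as.matrix(leroux_precision(g, lam)), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), 1 - lam - 1e-10)
  }
})

test_that("precision rescaling yields unit-diagonal correlation", {
  Q <- Matrix::Matrix(matrix(c(2, -1, -1, 2), 2), sparse = TRUE)
  st <- precision_to_correlation(Q)
  expect_equal(correlation_matrix(st), matrix(c(1, 0.5, 0.5, 1), 2),
               tolerance = 1e-10)
  expect_equal(diag_of_inverse(Q), c(2 / 3, 2 / 3), tolerance = 1e-12)
  expect_equal(diag_of_inverse(diag(c(2, 4, 8))), c(0.5, 0.25, 0.125))

  # strong-dependence CAR at full scenario size against the dense oracle
  g <- square_lattice(30, 30)
  Qc <- car_precision(g, 0.99)
  st <- precision_to_correlation(Qc)
  expect_lt(max(abs(diag(correlation_matrix(st)) - 1)), 1e-8)
  expect_equal(st$v, diag(solve(as.matrix(Qc))), tolerance = 1e-8)
})

test_that("diag_of_inverse matches dense inversion on random sparse SPD", {
  set.seed(7)
  n <- 200
  B <- Matrix::rsparsematrix(n, n, density = 0.02)
  Q <- Matrix::crossprod(B) + Matrix::Diagonal(n, runif(n, 1, 2))
  expect_equal(diag_of_inverse(Q), diag(solve(as.matrix(Q))),
               tolerance = 1e-10)
})

test_that("kernel correlations obey their closed forms and nesting", {
  d <- matrix(c(0, 0.3, 0.3, 0), 2)
  expect_equal(exponential_correlation(d, 0.3)[1, 2], exp(-3))
  expect_lt(abs(exponential_correlation(d, 0.3)[1, 2] - 0.05), 0.001)
  expect_equal(exponential_correlation(d, 0.9)[1, 2], exp(-1))
  expect_equal(diag(exponential_correlation(d, 0.5)), c(1, 1))

  expect_equal(powered_exponential_correlation(d, 0.3, 1)[1, 2], exp(-1))
  expect_equal(powered_exponential_correlation(d, 0.3, 2)[1, 2], exp(-1))
  expect_equal(powered_exponential_correlation(d, 0.6, 2)[1, 2],
               exp(-(0.3 / 0.6)^2))
  expect_error(powered_exponential_correlation(d, 0.3, 2.5), "\\(0, 2]")

  expect_equal(matern_correlation(d, 0.3, 0.5)[1, 2], exp(-1),
               tolerance = 1e-10)
  expect_equal(matern_correlation(d, 0.3, 1)[1, 2], besselK(1, 1),
               tolerance = 1e-10)
  expect_equal(diag(matern_correlation(d, 0.3, 1.7)), c(1, 1))

  # Matern nu = 0.5 is the powered exponential with smoothness 1, entrywise
  set.seed(1)
  dd <- pairwise_distances(matrix(runif(30), 15, 2))
  expect_equal(matern_correlation(dd, 0.2, 0.5),
               powered_exponential_correlation(dd, 0.2, 1),
               tolerance = 1e-12)
})

test_that("kernel matrices are positive definite on grids", {
  ps <- unit_square_grid(5, 5)
  for (om in list(powered_exponential_correlation(ps$dists, 0.2, 1.5),
                  matern_correlation(ps$dists, 0.2, 1),
                  exponential_correlation(ps$dists, 0.3))) {
    ev <- eigen(om, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("spherical taper has compact support and exact closed forms", {
  d <- matrix(c(0, 0.5, 1.2, 0.5, 0, 2, 1.2, 2, 0), 3)
  T <- spherical_taper(d, 1)
  T <- as.matrix(T)
  expect_equal(diag(T), rep(1, 3))
  expect_equal(T[2, 3], 0)            # d >= t truncated to zero
  expect_equal(T[1, 2], 0.5^2 * 1.25) # d = t/2
  expect_equal(T[1, 3], 0)
  expect_error(spherical_taper(d, -1), "positive")
})

test_that("tapering keeps a valid, sparse correlation structure", {
  ps <- unit_square_grid(20, 20)
  om <- exponential_correlation(ps$dists, 0.3)
  st <- taper_correlation(om, spherical_taper(ps$dists, 0.15))
  expect_equal(st$rep, "sparse")
  omt <- as.matrix(st$omega)
  expect_equal(diag(omt), rep(1, 400))
  expect_gt(min(eigen(omt, symmetric = TRUE, only.values = TRUE)$values), 0)
  # taper wider than the domain leaves the correlation essentially intact
  # (T -> all-ones as t -> infinity; deviation is O(d/t))
  wide <- taper_correlation(om, spherical_taper(ps$dists, 1e8))
  expect_equal(as.matrix(correlation_matrix(wide)), om, tolerance = 1e-6)
  # taper below the minimum spacing gives the identity copula
  tiny <- taper_correlation(om, spherical_taper(ps$dists, 1e-4))
  expect_equal(as.matrix(correlation_matrix(tiny)), diag(400))
})

test_that("sparse half log-determinant matches the dense oracle", {
  expect_equal(sparse_half_logdet(diag(2)), 0)
  expect_equal(sparse_half_logdet(diag(c(4, 4))), log(4))
  g <- square_lattice(30, 30)
  Q <- car_precision(g, 0.8)
  dense <- 0.5 * determinant(as.matrix(Q), logarithm = TRUE)$modulus[1]
  expect_equal(sparse_half_logdet(Q), unname(dense), tolerance = 1e-8)
  expect_error(suppressWarnings(sparse_half_logdet(diag(c(1, -1)))),
               "positive definite")
})

test_that("copula log-likelihood: sparse precision path equals dense path", {
  expect_equal(copula_loglik(correlation_structure(diag(3)), c(1, 2, 3)),
               -0.5 * 14)
  om2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(copula_loglik(correlation_structure(om2), c(0, 0)),
               -0.5 * log(0.75))

  g <- square_lattice(30, 30)
  st <- precision_to_correlation(car_precision(g, 0.8))
  set.seed(3)
  r <- rnorm(900)
  dense <- loglik_dense_oracle(correlation_matrix(st), r)
  expect_equal(copula_loglik(st, r), unname(dense), tolerance = 1e-8)
  expect_error(copula_loglik(st, r[1:10]), "length")
})

test_that("CAR correlation is entrywise non-decreasing in rho", {
  g <- square_lattice(6, 6)
  rhos <- c(0, 0.4, 0.8, 0.99)
  oms <- lapply(rhos, function(rho) {
    correlation_matrix(precision_to_correlation(car_precision(g, rho)))
  })
  for (k in 2:length(oms)) {
    expect_true(all(oms[[k]] - oms[[k - 1]] > -1e-10))
  }
})

test_that("copula families are valid correlation models at scenario sizes", {
  g <- square_lattice(10, 10)
  ps <- unit_square_grid(8, 8)
  specs <- list(
    copula_spec("car", g, list(rho = 0.9)),
    copula_spec("leroux", g, list(lambda = 0.95)),
    copula_spec("exponential", ps, list(phi = 0.3)),
    copula_spec("powered_exponential", ps, list(phi = 0.2, nu = 1.5)),
    copula_spec("matern", ps, list(phi = 0.1, nu = 1))
  )
  for (sp in specs) {
    om <- correlation_matrix(copula_structure(sp))
    expect_true(isSymmetric(unname(om), tol = 1e-10))
    expect_lt(max(abs(diag(om) - 1)), 1e-8)
    expect_gt(min(eigen(om, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("family/domain mismatches and bad parameters are rejected", {
  g <- path_graph(3)
  ps <- unit_square_grid(2, 2)
  expect_error(copula_spec("car", ps), "areal_graph")
  expect_error(copula_spec("matern", g), "point_set")
  expect_error(copula_spec("car", g, list(rho = 1)), "singular")
  expect_error(copula_spec("matern", ps, list(phi = -1)), "positive")
  expect_error(copula_spec("car", g, taper_length = 0.5), "kernel")
})

test_that("gauss transform is the normal quantile with exact round trip", {
  expect_equal(gauss_transform(0.5), 0)
  expect_equal(gauss_transform(0.975), qnorm(0.975))
  x <- seq(0.01, 0.99, by = 0.01)
  expect_equal(gauss_transform_inverse(gauss_transform(x)), x)
  expect_error(gauss_transform(1), "inside")
})

test_that("areal spectral likelihood equals the generic sparse path", {
  g <- square_lattice(7, 9)
  set.seed(9)
  r <- rnorm(g$n)
  for (theta in c(0.05, 0.5, 0.9, 0.999)) {
    st_car <- precision_to_correlation(car_precision(g, theta))
    expect_equal(sgcreg:::areal_loglik(g, "car", theta, r),
                 copula_loglik(st_car, r), tolerance = 1e-10)
    st_ler <- precision_to_correlation(leroux_precision(g, theta))
    expect_equal(sgcreg:::areal_loglik(g, "leroux", theta, r),
                 copula_loglik(st_ler, r), tolerance = 1e-10)
  }
})

test_that("copula estimation recovers the generating dependence", {
  # latent fields simulated directly from the copula; CAR on a small lattice
  g <- square_lattice(15, 15)
  st <- copula_structure(copula_spec("car", g, list(rho = 0.8)))
  set.seed(21)
  Z <- sample_latent(st, 60)
  est <- apply(Z, 2, function(z) {
    estimate_copula_params(z, copula_spec("car", g))$params$rho
  })
  expect_lt(abs(median(est) - 0.8), 0.15)

  # independence at the scenario lattice size: estimates concentrate near 0
  g30 <- square_lattice(30, 30)
  set.seed(22)
  est0 <- replicate(40, {
    estimate_copula_params(rnorm(g30$n), copula_spec("car", g30))$params$rho
  })
  expect_gte(mean(est0 < 0.2), 0.95)
})
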