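# small fixtures shared across test files; everything is built in code

path_graph <- function(n = 3L) {
  areal_graph(cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L))
}

# brute-force O(n^2) distance oracle
dist_loop <- function(coords) {
  n <- nrow(coords)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    }
  }
  d
}

# dense-oracle copula log-likelihood: -0.5 log|Omega| - 0.5 r' Omega^{-1} r
loglik_dense_oracle <- function(omega, r) {
  omega <- as.matrix(omega)
  -0.5 * determinant(omega, logarithm = TRUE)$modulus[1] -
    0.5 * drop(crossprod(r, solve(omega, r)))
}

# dense correlation from a precision matrix, by direct inversion
corr_dense_oracle <- function(Q) {
  Qinv <- solve(as.matrix(Q))
  s <- 1 / sqrt(diag(Qinv))
  sweep(sweep(Qinv, 1L, s, `*`), 2L, s, `*`)
}
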