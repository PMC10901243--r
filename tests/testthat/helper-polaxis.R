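# shared fixtures: random physical Mueller factor triples and axial samples

# draw angles from a wrapped normal on the axial domain
rwnorm_axial <- function(n, mu, sigma) (mu + rnorm(n, 0, sigma)) %% 180

# random Lu-Chipman factor triple (depolarizer diag, retarder, diattenuator)
# with parameters kept away from the degenerate boundaries
random_factors <- function(Dmax = 0.9, dmin = 0.1) {
  list(delta = runif(1, 5, 175),
       theta = runif(1, 0, 180),
       d = runif(3, dmin, 1),
       D = runif(1, 0, Dmax),
       aD = runif(1, 0, 180))
}

compose_from_factors <- function(f) {
  depolarizer_diag(f$d) %*% linear_retarder(f$delta, f$theta) %*%
    linear_diattenuator(f$D, f$aD)
}

expect_matrix_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a - b)), tol)
}
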