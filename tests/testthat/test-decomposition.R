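test_that("polar decomposition has the expected fixed points", {
  f <- lu_chipman(diag(4))
  expect_matrix_equal(f$M_delta, diag(4), 1e-12)
  expect_matrix_equal(f$M_R, diag(4), 1e-12)
  expect_matrix_equal(f$M_D, diag(4), 1e-12)
  # a pure retarder is its own retarder factor
  R <- linear_retarder(90, 37)
  f <- lu_chipman(R)
  expect_matrix_equal(f$M_delta, diag(4), 1e-9)
  expect_matrix_equal(f$M_D, diag(4), 1e-9)
  expect_matrix_equal(f$M_R, R, 1e-9)
  expect_error(lu_chipman(linear_diattenuator(1, 10)), "degenerate")
})

test_that("forward-composed factors are recovered by decomposition", {
  M <- depolarizer_diag(0.7, 0.7, 0.5) %*% linear_retarder(40, 15) %*%
    linear_diattenuator(0.2, 100)
  f <- lu_chipman(M)
  expect_matrix_equal(f$M_delta %*% f$M_R %*% f$M_D, M, 1e-8)
  expect_matrix_equal(f$M_delta, depolarizer_diag(0.7, 0.7, 0.5), 1e-8)
  expect_matrix_equal(f$M_R, linear_retarder(40, 15), 1e-8)
  expect_matrix_equal(f$M_D, linear_diattenuator(0.2, 100), 1e-8)
  # parameter recovery on random triples, including retarder orthogonality
  set.seed(31)
  for (k in 1:200) {
    fac <- random_factors()
    M <- compose_from_factors(fac)
    f <- lu_chipman(M)
    expect_matrix_equal(f$M_delta %*% f$M_R %*% f$M_D, M, 1e-9)
    mr <- f$M_R[2:4, 2:4]
    expect_matrix_equal(mr %*% t(mr), diag(3), 1e-9)
    expect_equal(f$D, fac$D, tolerance = 1e-6)
    expect_equal(linear_retardance(f$M_R), fac$delta, tolerance = 1e-6)
    expect_lt(axial_distance(retardance_theta(f$M_R), fac$theta), 1e-6)
    expect_equal(depolarization_power(f$M_delta), 1 - sum(fac$d) / 3,
                 tolerance = 1e-6)
  }
})

test_that("fast-axis orientation inverts the constructor and bisects stacks", {
  expect_equal(retardance_theta(linear_retarder(60, 20)), 20,
               tolerance = 1e-9)
  expect_equal(retardance_theta(linear_retarder(90, 155)), 155,
               tolerance = 1e-9)
  # two equal-retardance layers: equivalent fast axis is the bisector
  M <- compose_layers(list(linear_retarder(20, 0), linear_retarder(20, 60)))
  expect_equal(retardance_theta(lu_chipman(M)$M_R), 30, tolerance = 1e-9)
  # orientation undefined at zero and half-wave total retardance
  expect_true(is.na(retardance_theta(diag(4))))
  expect_true(is.na(retardance_theta(linear_retarder(180, 40))))
})

test_that("linear retardance inverts the constructor over a grid", {
  expect_equal(linear_retardance(linear_retarder(90, 10)), 90,
               tolerance = 1e-9)
  expect_equal(linear_retardance(diag(4)), 0, tolerance = 1e-9)
  for (delta in c(5, 73, 120, 179)) for (axis in c(0, 48, 91, 140))
    expect_equal(linear_retardance(linear_retarder(delta, axis)), delta,
                 tolerance = 1e-9)
})

test_that("element-ratio azimuths follow their defining conventions", {
  # alphaP: first-column convention, verified against the Stokes oracle
  for (ax in c(0, 25, 60, 130)) {
    Md <- linear_diattenuator(0.3, ax)
    expect_equal(alpha_p(Md), ax, tolerance = 1e-9)
    out <- drop(Md %*% c(1, 0, 0, 0))
    expect_equal(alpha_p(Md),
                 wrap_axial(0.5 * atan2(out[3], out[2]) * 180 / pi),
                 tolerance = 1e-9)
  }
  expect_true(is.na(alpha_p(depolarizer_diag(0, 0, 0))))
  # alphaQ equals theta for a quarter-wave plate
  for (th in c(0, 10, 45, 155)) {
    expect_equal(alpha_q(linear_retarder(90, th)), th, tolerance = 1e-9)
  }
  expect_true(is.na(alpha_q(linear_retarder(0, 30))))
})

test_that("anisotropic depolarization corrupts alphaQ but not theta", {
  # depolarizer encountered before the retarder: m42/m43 are scaled by
  # different diagonal coefficients, so the element-ratio angle is biased,
  # while the decomposition still isolates the true retarder
  M <- linear_retarder(40, 70) %*% depolarizer_diag(0.9, 0.3, 0.9)
  th <- retardance_theta(lu_chipman(M)$M_R)
  expect_lt(axial_distance(th, 70), 1e-6)
  expect_gt(axial_distance(alpha_q(M), 70), 5)
})

test_that("near-zero m43 inflates alphaQ noise while alphaP stays stable", {
  # fast axis at 45 deg puts m43 ~ 0 with small retardance: the alphaQ
  # ratio divides two near-zero elements, while m21 stays well away from 0
  M0 <- linear_retarder(4, 45) %*% linear_diattenuator(0.3, 0)
  set.seed(52)
  aq <- ap <- numeric(400)
  for (k in 1:400) {
    M <- M0 + matrix(rnorm(16, sd = 0.005), 4, 4)
    aq[k] <- alpha_q(M)
    ap[k] <- alpha_p(M)
  }
  spread <- function(x, ref) mean(axial_distance(x, ref)^2)
  expect_gt(spread(aq, 45) / spread(ap, 0), 5)
})

test_that("decomposition angles are rotationally equivariant", {
  set.seed(41)
  for (k in 1:20) {
    fac <- random_factors()
    M <- compose_from_factors(fac)
    phi <- runif(1, 0, 180)
    Mr <- rotation_matrix(phi) %*% M %*% rotation_matrix(-phi)
    expect_lt(axial_distance(retardance_theta(lu_chipman(Mr)$M_R),
                             fac$theta + phi), 1e-6)
    expect_lt(axial_distance(alpha_p(Mr), alpha_p(M) + phi), 1e-6)
    expect_lt(axial_distance(alpha_q(Mr), alpha_q(M) + phi), 1e-6)
  }
})

test_that("image decomposition produces consistent maps and masks", {
  img <- mueller_image(linear_retarder(90, 30), shape = c(6, 6))
  maps <- decompose_image(img)
  expect_true(all(abs(maps$theta - 30) < 1e-9))
  expect_true(all(maps$Delta < 1e-9))
  expect_true(all(maps$D < 1e-12))
  expect_true(all(abs(maps$delta_lr - 90) < 1e-9))
  # alphaQ tracks theta for the pure retarder image
  expect_true(all(abs(maps$alphaQ - 30) < 1e-9))

  # identity pixels: theta and both azimuths are undefined, flagged not NaN
  maps0 <- decompose_image(mueller_image(diag(4), shape = c(2, 2)))
  expect_true(all(is.na(maps0$theta)))
  expect_true(all(is.na(maps0$alphaP)))
  expect_true(all(bitwAnd(maps0$mask, 1L) != 0L))
  expect_true(all(bitwAnd(maps0$mask, 2L) != 0L))
  expect_false(any(is.nan(unlist(maps0[c("theta", "alphaP", "alphaQ")]))))

  # random physical image: factors recompose below 1e-8 everywhere
  set.seed(61)
  arr <- array(0, c(5, 5, 4, 4))
  for (h in 1:5) for (w in 1:5)
    arr[h, w, , ] <- compose_from_factors(random_factors())
  img <- mueller_image(arr)
  for (h in 1:5) for (w in 1:5) {
    M <- pixel_matrix(img, h, w)
    f <- lu_chipman(M)
    expect_matrix_equal(f$M_delta %*% f$M_R %*% f$M_D, normalize_mueller(M),
                        1e-8)
  }
})
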