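test_that("active deformation gradient has the prescribed structure", {
  expect_equal(active_deformation(0, c(1, 0, 0)), diag(3))
  expect_equal(active_deformation(-0.1, c(1, 0, 0)), diag(c(0.9, 1, 1)))
  # eigenvalues {1+gamma, 1, 1} for arbitrary unit fibres
  set.seed(11)
  for (i in 1:5) {
    f <- stats::rnorm(3); f <- f / sqrt(sum(f^2))
    g <- stats::runif(1, -0.3, 0.3)
    F0 <- active_deformation(g, f)
    ev <- sort(eigen(F0, only.values = TRUE)$values)
    expect_equal(ev, sort(c(1 + g, 1, 1)), tolerance = 1e-10)
    expect_equal(det(F0), 1 + g, tolerance = 1e-10)
  }
  expect_error(active_deformation(-1, c(1, 0, 0)), "invertible")
  expect_error(active_deformation(0, c(1, 1, 0)), "unit")
})

test_that("elastic strains follow the multiplicative decomposition", {
  F0 <- active_deformation(-0.1, c(1, 0, 0))
  es <- elastic_strains(F0, F0)
  expect_equal(es$Fe, diag(3), tolerance = 1e-12)
  expect_equal(es$Ee, matrix(0, 3, 3), tolerance = 1e-12)
  es <- elastic_strains(diag(3), F0)
  expect_equal(es$Fe, diag(c(1 / 0.9, 1, 1)), tolerance = 1e-12)
  expect_error(elastic_strains(diag(3), matrix(0, 3, 3)), "singular")
  # objectivity: Ce invariant under F -> R F for rotations R
  set.seed(21)
  Fm <- diag(3) + 0.1 * matrix(stats::rnorm(9), 3)
  if (det(Fm) <= 0) Fm <- diag(3) + 0.01 * matrix(stats::rnorm(9), 3)
  base <- elastic_strains(Fm, F0)$Ce
  for (i in 1:4) {
    R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    expect_equal(elastic_strains(R %*% Fm, F0)$Ce, base,
                 tolerance = 1e-10)
  }
})

test_that("Guccione energy reproduces the printed constants and symmetry", {
  expect_equal(guccione_energy(matrix(0, 3, 3)), 0.831)
  E <- matrix(0, 3, 3); E[1, 1] <- 0.1
  expect_equal(guccione_energy(E), 0.831 * exp(14.31 * 0.01))
  # transverse isotropy: swapping axes 2 and 3 leaves W unchanged
  set.seed(5)
  for (i in 1:5) {
    A <- matrix(stats::rnorm(9, sd = 0.1), 3); E <- (A + t(A)) / 2
    P <- diag(3)[, c(1, 3, 2)]
    expect_equal(guccione_energy(E), guccione_energy(t(P) %*% E %*% P),
                 tolerance = 1e-12)
    expect_gt(guccione_energy(E), 0)
  }
  expect_error(guccione_parameters(C1 = -1), "positive")
})

test_that("energy is frame-indifferent and minimised at zero strain", {
  set.seed(7)
  F0 <- active_deformation(-0.05, c(1, 0, 0))
  Fm <- diag(3) + 0.05 * matrix(stats::rnorm(9), 3)
  for (i in 1:4) {
    R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    expect_equal(guccione_energy(elastic_strains(R %*% Fm, F0)$Ee),
                 guccione_energy(elastic_strains(Fm, F0)$Ee),
                 tolerance = 1e-10)
  }
  w0 <- guccione_energy(matrix(0, 3, 3))
  for (i in 1:20) {
    A <- matrix(stats::rnorm(9, sd = 0.05), 3); E <- (A + t(A)) / 2
    expect_gte(guccione_energy(E), w0)
  }
})

test_that("analytic stress matches central finite differences of W", {
  set.seed(13)
  pars <- guccione_parameters()
  h <- 1e-6
  for (rep in 1:5) {
    A <- matrix(stats::rnorm(9, sd = 0.08), 3); E <- (A + t(A)) / 2
    S <- second_pk_stress(E, pars)
    for (i in 1:3) for (j in 1:3) {
      dE <- matrix(0, 3, 3)
      if (i == j) dE[i, j] <- 1 else dE[i, j] <- dE[j, i] <- 0.5
      fd <- (guccione_energy(E + h * dE, pars) -
               guccione_energy(E - h * dE, pars)) / (2 * h)
      expect_equal(S[i, j], fd, tolerance = 1e-6,
                   label = sprintf("S[%d,%d]", i, j))
    }
  }
  # zero strain, zero pressure: stress-free energy minimum
  expect_equal(second_pk_stress(matrix(0, 3, 3), pars), matrix(0, 3, 3))
  # linearity in C1
  E <- diag(c(0.05, -0.02, 0.01))
  p2 <- guccione_parameters(C1 = 2 * 0.831)
  expect_equal(second_pk_stress(E, p2), 2 * second_pk_stress(E, pars),
               tolerance = 1e-12)
})

test_that("homogeneous active contraction shortens along the fibre and
           matches a dense grid search", {
  out0 <- uniaxial_active_contraction(0)
  expect_equal(out0$lambda_f, 1, tolerance = 1e-5)
  out <- uniaxial_active_contraction(-0.1)
  expect_lt(out$lambda_f, 1)
  expect_gt(out$lambda_t, 1)
  expect_equal(out$lambda_f * out$lambda_t^2, 1, tolerance = 1e-10)
  # grid-search oracle
  grid <- seq(0.7, 1.3, by = 1e-4)
  F0 <- active_deformation(-0.1, c(1, 0, 0))
  w <- vapply(grid, function(lf) {
    Fm <- diag(c(lf, 1 / sqrt(lf), 1 / sqrt(lf)))
    guccione_energy(elastic_strains(Fm, F0)$Ee)
  }, numeric(1))
  expect_equal(out$lambda_f, grid[which.min(w)], tolerance = 2e-4)
  # shortening magnitude monotone in |gamma|
  lf <- vapply(c(-0.05, -0.1, -0.2), function(g)
    uniaxial_active_contraction(g)$lambda_f, numeric(1))
  expect_true(all(diff(lf) < 0))
  expect_error(uniaxial_active_contraction(0.6), "gamma")
})
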