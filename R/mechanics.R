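#' Active part of the deformation gradient
#'
#' `F0 = I + gamma f x f`: fibre-aligned contraction/elongation prescribed
#' by the active strain. `det F0 = 1 + gamma`.
#'
#' @param gamma Active strain, > -1.
#' @param f Fibre direction (length-3 unit vector).
#' @return 3x3 matrix `F0`.
#' @export
#' @examples
#' active_deformation(-0.1, c(1, 0, 0))
active_deformation <- function(gamma, f) {
  if (gamma <= -1) stop("gamma must exceed -1 (F0 must stay invertible)")
  f <- as.numeric(f)
  if (length(f) != 3 || abs(sqrt(sum(f^2)) - 1) > 1e-8)
    stop("f must be a unit 3-vector")
  diag(3) + gamma * tcrossprod(f)
}

#' Elastic strain measures of the multiplicative decomposition
#'
#' `Fe = F F0^-1`, `Ce = Fe^T Fe`, `Ee = (Ce - I)/2`.
#'
#' @param F Total deformation gradient (3x3, det > 0).
#' @param F0 Active deformation gradient (3x3, invertible).
#' @return List with `Fe`, `Ce`, `Ee`.
#' @export
elastic_strains <- function(F, F0) {
  F <- as.matrix(F); F0 <- as.matrix(F0)
  if (!all(dim(F) == 3) || !all(dim(F0) == 3)) stop("F and F0 must be 3x3")
  d0 <- det(F0)
  if (abs(d0) < 1e-12) stop("F0 is singular")
  if (det(F) <= 0) stop("det F must be positive")
  Fe <- F %*% solve(F0)
  Ce <- crossprod(Fe)
  list(Fe = Fe, Ce = Ce, Ee = (Ce - diag(3)) / 2)
}

#' Guccione material parameters
#'
#' Transversely isotropic exponential strain energy with the printed atrial
#' values: `C1 = 0.831` kPa, `C2 = 14.31`, `C3 = 4.49`, `C4 = 10`
#' (dimensionless).
#'
#' @param C1,C2,C3,C4 Material constants, all positive.
#' @return A named list of class `guccione_parameters`.
#' @export
guccione_parameters <- function(C1 = 0.831, C2 = 14.31, C3 = 4.49,
                                C4 = 10) {
  if (any(c(C1, C2, C3, C4) <= 0)) stop("all constants must be positive")
  structure(list(C1 = C1, C2 = C2, C3 = C3, C4 = C4),
            class = "guccione_parameters")
}

# Orthonormal fibre frame with axis 1 = f; the second axis is the smallest-
# index coordinate axis projected orthogonal to f (deterministic tie-break).
fibre_frame <- function(f) {
  f <- f / sqrt(sum(f^2))
  k <- which.min(abs(f))
  e <- c(0, 0, 0); e[k] <- 1
  s <- e - sum(e * f) * f
  s <- s / sqrt(sum(s^2))
  n <- c(f[2] * s[3] - f[3] * s[2],
         f[3] * s[1] - f[1] * s[3],
         f[1] * s[2] - f[2] * s[1])
  cbind(f, s, n)
}

#' Guccione strain energy
#'
#' `W = C1 exp(Q)` with `Q = C2 E11^2 + C3 (E22^2 + E33^2 + E23^2 + E32^2)/1
#' + 2 C4 (E12 E21 + E13 E31)` evaluated in an orthonormal frame whose first
#' axis is the fibre direction. For symmetric `E` the cross terms equal the
#' squared forms.
#'
#' @param Ee Elastic Green-Lagrange strain (3x3 symmetric), expressed in the
#'   reference coordinates.
#' @param params [guccione_parameters()].
#' @param f Fibre direction (unit 3-vector); axis 1 of the material frame.
#' @return Energy density W (kPa).
#' @export
#' @examples
#' guccione_energy(matrix(0, 3, 3)) # = C1
guccione_energy <- function(Ee, params = guccione_parameters(),
                            f = c(1, 0, 0)) {
  Ee <- as.matrix(Ee)
  if (max(abs(Ee - t(Ee))) > 1e-8) stop("Ee must be symmetric")
  Q <- fibre_frame(f)
  E <- t(Q) %*% Ee %*% Q
  q <- params$C2 * E[1, 1]^2 +
    params$C3 * (E[2, 2]^2 + E[3, 3]^2 + E[2, 3]^2) +
    2 * params$C4 * (E[1, 2] * E[2, 1] + E[1, 3] * E[3, 1])
  params$C1 * exp(q)
}

#' Second Piola-Kirchhoff stress of the Guccione law
#'
#' `S = dW/dEe - p Ce^-1` (the second term enforces incompressibility via
#' the hydrostatic pressure). The elastic part is the analytic derivative of
#' the exponential quadratic form; it is verified against central
#' finite differences of [guccione_energy()] in the test suite.
#'
#' @inheritParams guccione_energy
#' @param p Hydrostatic pressure (kPa).
#' @param Ce Elastic right Cauchy-Green tensor (needed when `p != 0`).
#' @return 3x3 stress tensor (kPa).
#' @export
second_pk_stress <- function(Ee, params = guccione_parameters(), p = 0,
                             f = c(1, 0, 0), Ce = NULL) {
  Ee <- as.matrix(Ee)
  if (max(abs(Ee - t(Ee))) > 1e-8) stop("Ee must be symmetric")
  Q <- fibre_frame(f)
  E <- t(Q) %*% Ee %*% Q
  q <- params$C2 * E[1, 1]^2 +
    params$C3 * (E[2, 2]^2 + E[3, 3]^2 + E[2, 3]^2) +
    2 * params$C4 * (E[1, 2] * E[2, 1] + E[1, 3] * E[3, 1])
  dQdE <- matrix(0, 3, 3)
  dQdE[1, 1] <- 2 * params$C2 * E[1, 1]
  dQdE[2, 2] <- 2 * params$C3 * E[2, 2]
  dQdE[3, 3] <- 2 * params$C3 * E[3, 3]
  # the transverse shear enters Q as a single E23^2 term; its symmetric
  # gradient therefore carries no factor 2
  dQdE[2, 3] <- dQdE[3, 2] <- params$C3 * E[2, 3]
  dQdE[1, 2] <- dQdE[2, 1] <- 2 * params$C4 * E[2, 1]
  dQdE[1, 3] <- dQdE[3, 1] <- 2 * params$C4 * E[3, 1]
  S <- params$C1 * exp(q) * (Q %*% dQdE %*% t(Q))
  if (p != 0) {
    if (is.null(Ce)) Ce <- 2 * Ee + diag(3)
    S <- S - p * solve(Ce)
  }
  S
}

#' Traction-free homogeneous active contraction
#'
#' Equilibrium of an incompressible homogeneous block with fibre along
#' axis 1 under active strain `gamma`: `F = diag(lambda_f, lambda_t,
#' lambda_t)` with `lambda_f lambda_t^2 = 1`, minimising the Guccione
#' energy of the elastic part `Fe = F F0(gamma)^-1` by bounded scalar
#' minimisation.
#'
#' @param gamma Active strain in (-0.5, 0.5).
#' @param params [guccione_parameters()].
#' @param interval Search interval for `lambda_f`.
#' @param tol Convergence tolerance on `lambda_f`.
#' @return A list with `lambda_f`, `lambda_t`, `energy`.
#' @export
#' @examples
#' uniaxial_active_contraction(-0.1)$lambda_f
uniaxial_active_contraction <- function(gamma,
                                        params = guccione_parameters(),
                                        interval = c(0.6, 1.4),
                                        tol = 1e-9) {
  if (abs(gamma) >= 0.5) stop("gamma must lie in (-0.5, 0.5)")
  f <- c(1, 0, 0)
  F0 <- active_deformation(gamma, f)
  energy <- function(lf) {
    Fm <- diag(c(lf, 1 / sqrt(lf), 1 / sqrt(lf)))
    guccione_energy(elastic_strains(Fm, F0)$Ee, params, f)
  }
  opt <- optimize(energy, interval, tol = tol)
  lf <- opt$minimum
  if (min(lf - interval[1], interval[2] - lf) < 1e-4 && abs(gamma) > 1e-8)
    stop("minimiser hit the search bracket [", interval[1], ", ",
         interval[2], "]; widen `interval`")
  list(lambda_f = lf, lambda_t = 1 / sqrt(lf), energy = opt$objective)
}
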