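#' Subject material parameters
#'
#' Bundles one virtual subject's constitutive parameters: shear modulus
#' \code{mu} (MPa), first Lame parameter \code{lam} (MPa, always `40 * mu`
#' for the nearly incompressible skin model), areal growth rate \code{k}
#' (1/day), natural pre-stretch \code{theta_nat} (areal, dimensionless) and
#' mass density \code{rho} (kg/m^3).
#'
#' @param mu Shear modulus in MPa; must be positive.
#' @param k Growth rate in 1/day; must be non-negative.
#' @param theta_nat Natural areal pre-stretch; must be >= 1.
#' @param rho Density in kg/m^3; must be positive.
#'
#' @return An object of class `material_params`.
#' @examples
#' p <- material_params(mu = 0.06, k = 1.2, theta_nat = 1.125, rho = 1116)
#' p$lam  # 40 * mu
#' @export
material_params <- function(mu, k = 1.2, theta_nat = 1.125, rho = 1116) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(k), length(k) == 1L, is.finite(k),
            is.numeric(theta_nat), length(theta_nat) == 1L, is.finite(theta_nat),
            is.numeric(rho), length(rho) == 1L, is.finite(rho))
  if (mu <= 0) stop("mu must be positive")
  if (k < 0) stop("k must be non-negative")
  if (theta_nat < 1) stop("theta_nat must be >= 1")
  if (rho <= 0) stop("rho must be positive")
  structure(
    list(mu = mu, lam = 40 * mu, k = k, theta_nat = theta_nat, rho = rho),
    class = "material_params"
  )
}

#' @export
print.material_params <- function(x, ...) {
  cat("Skin material parameters\n")
  cat(sprintf("  mu        = %.5g MPa (lam = 40*mu = %.5g MPa)\n", x$mu, x$lam))
  cat(sprintf("  k         = %.5g /day\n", x$k))
  cat(sprintf("  theta_nat = %.5g (areal)\n", x$theta_nat))
  cat(sprintf("  rho       = %.5g kg/m^3\n", x$rho))
  invisible(x)
}

.check_unit_normal <- function(N) {
  if (!is.numeric(N) || length(N) != 3L || abs(sqrt(sum(N^2)) - 1) > 1e-8)
    stop("N must be a unit 3-vector")
  N
}

#' Growth part of the deformation gradient
#'
#' Transversely isotropic in-plane areal growth: area grows by a factor
#' `theta_g` in the plane orthogonal to the reference skin normal `N`, with
#' no growth through the thickness, giving
#' `Fg = sqrt(theta_g) (I - N o N) + N o N`.
#'
#' @param theta_g Areal growth factor, >= 1.
#' @param N Reference unit surface normal.
#' @return A 3x3 growth tensor.
#' @examples
#' growth_tensor(1.21, c(0, 0, 1))  # diag(1.1, 1.1, 1)
#' @export
growth_tensor <- function(theta_g, N = c(0, 0, 1)) {
  stopifnot(is.numeric(theta_g), length(theta_g) == 1L, is.finite(theta_g))
  if (theta_g < 1) stop("theta_g must be >= 1 (growth is irreversible)")
  N <- .check_unit_normal(N)
  s <- sqrt(theta_g)
  s * (diag(3) - tcrossprod(N)) + tcrossprod(N)
}

#' Elastic part of the deformation gradient
#'
#' Inverts the multiplicative split `F = Fe Fg`: `Fe = F Fg^-1` with `Fg`
#' the in-plane growth tensor for areal growth `theta_g` about normal `N`.
#'
#' @param F Total 3x3 deformation gradient with positive determinant.
#' @param theta_g Areal growth factor, >= 1.
#' @param N Reference unit surface normal.
#' @return The elastic 3x3 deformation gradient `Fe`.
#' @export
elastic_part <- function(F, theta_g, N = c(0, 0, 1)) {
  stopifnot(is.matrix(F), all(dim(F) == c(3L, 3L)))
  if (det(F) <= 0) stop("F must have positive determinant")
  N <- .check_unit_normal(N)
  s <- sqrt(theta_g)
  if (theta_g < 1) stop("theta_g must be >= 1")
  Fg_inv <- (1 / s) * (diag(3) - tcrossprod(N)) + tcrossprod(N)
  F %*% Fg_inv
}

#' Areal stretch of a surface element
#'
#' Nanson's relation: a reference area element with unit normal `N` is mapped
#' by `A` to a current area element `cof(A) N`; its magnitude is the areal
#' stretch `||cof(A) N||` with `cof(A) = det(A) A^-T`.
#'
#' @param A A non-singular 3x3 tensor.
#' @param N Reference unit surface normal.
#' @return The (positive) areal stretch.
#' @examples
#' areal_stretch(diag(c(1.2, 1.3, 1)), c(0, 0, 1))  # 1.56
#' @export
areal_stretch <- function(A, N = c(0, 0, 1)) {
  stopifnot(is.matrix(A), all(dim(A) == c(3L, 3L)))
  dA <- det(A)
  if (dA == 0) stop("A must be non-singular")
  N <- .check_unit_normal(N)
  cofA <- dA * t(solve(A))
  sqrt(sum((cofA %*% N)^2))
}

#' Compressible neo-Hookean strain-energy density
#'
#' `Psi = mu/2 (I1e - 3) - mu ln(Je) + lam/2 ln(Je)^2` with
#' `I1e = tr(Fe^T Fe)` and `Je = det(Fe)`, evaluated on the elastic part of
#' the deformation. The `-mu ln(Je)` term makes the reference state
#' stress-free (the standard compressible neo-Hookean; it is exactly the
#' energy whose push-forward is the Cauchy stress in [cauchy_stress()]).
#' Zero exactly when `Fe` is a rotation.
#'
#' @param Fe Elastic 3x3 deformation gradient, positive determinant.
#' @param params A [material_params()] object.
#' @return Strain-energy density in MPa (per unit intermediate volume).
#' @export
strain_energy_density <- function(Fe, params) {
  stopifnot(is.matrix(Fe), all(dim(Fe) == c(3L, 3L)),
            inherits(params, "material_params"))
  Je <- det(Fe)
  if (Je <= 0) stop("Fe must have positive determinant")
  I1e <- sum(Fe^2)
  params$mu / 2 * (I1e - 3) - params$mu * log(Je) +
    params$lam / 2 * log(Je)^2
}

#' Cauchy stress of the compressible neo-Hookean model
#'
#' Standard push-forward of the energy in [strain_energy_density()]:
#' `sigma = (1/Je) (mu (Fe Fe^T - I) + lam ln(Je) I)`. Also reports the Von
#' Mises equivalent stress and the energy density.
#'
#' @inheritParams strain_energy_density
#' @return An object of class `stress_measures`: list with `cauchy` (3x3,
#'   MPa), `von_mises` (MPa) and `energy` (MPa).
#' @export
cauchy_stress <- function(Fe, params) {
  stopifnot(is.matrix(Fe), all(dim(Fe) == c(3L, 3L)),
            inherits(params, "material_params"))
  Je <- det(Fe)
  if (Je <= 0) stop("Fe must have positive determinant")
  b <- tcrossprod(Fe)   # Fe Fe^T
  sig <- (params$mu * (b - diag(3)) + params$lam * log(Je) * diag(3)) / Je
  dev <- sig - mean(diag(sig)) * diag(3)
  vm <- sqrt(3 / 2 * sum(dev^2))
  structure(list(cauchy = sig, von_mises = vm,
                 energy = strain_energy_density(Fe, params)),
            class = "stress_measures")
}

#' Areal growth rate law
#'
#' The rate of irreversible areal growth is proportional to the elastic areal
#' stretch in excess of the natural pre-stretch,
#' `theta_g_dot = k (theta_elastic - theta_nat)`, clamped at zero so that
#' growth never reverses when the skin is slack.
#'
#' @param theta_elastic Elastic areal stretch (positive).
#' @param params A [material_params()] object.
#' @return Growth rate in 1/day (non-negative).
#' @export
growth_rate <- function(theta_elastic, params) {
  stopifnot(is.numeric(theta_elastic), all(theta_elastic > 0),
            inherits(params, "material_params"))
  pmax(0, params$k * (theta_elastic - params$theta_nat))
}

#' Material-point growth relaxation under a held total stretch
#'
#' Integrates the local growth law at a single material point held at a fixed
#' total areal stretch `theta_total`: since `theta_total = theta_elastic *
#' theta_g`, the growth ODE is `d theta_g / dt = k (theta_total / theta_g -
#' theta_nat)` from `theta_g(0) = 1`. Integrated by Heun's method (explicit
#' trapezoid) with automatic substepping capped at a per-substep growth
#' increment of 0.01; the ODE is smooth and contracts towards the
#' equilibrium `theta_total / theta_nat`. The same integrator advances the
#' per-Gauss-point growth field in [grow()].
#'
#' @param theta_total Held total areal stretch, >= `theta_nat`.
#' @param params A [material_params()] object.
#' @param t_end Final time in days.
#' @param dt Output time step in days.
#' @return A data frame with columns `time` (days) and `theta_g`.
#' @export
point_driver <- function(theta_total, params, t_end, dt = 0.05) {
  stopifnot(inherits(params, "material_params"),
            is.numeric(theta_total), length(theta_total) == 1L,
            t_end >= 0, dt > 0)
  if (theta_total < params$theta_nat)
    stop("theta_total must be >= theta_nat")
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  tg <- numeric(length(times))
  tg[1] <- 1
  cur <- 1
  for (i in seq_along(times)[-1]) {
    cur <- .grow_interval(cur, theta_total, params, times[i] - times[i - 1])
    tg[i] <- cur
  }
  data.frame(time = times, theta_g = tg)
}
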