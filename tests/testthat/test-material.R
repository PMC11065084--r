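# Constitutive core: growth kinematics, energy, stress, growth law.

test_that("material_params enforces the constitutive invariants", {
  p <- material_params(mu = 0.06, k = 1.2, theta_nat = 1.125, rho = 1116)
  expect_equal(p$lam, 40 * p$mu)
  expect_error(material_params(mu = -1), "mu")
  expect_error(material_params(mu = 0.06, k = -0.1), "k")
  expect_error(material_params(mu = 0.06, theta_nat = 0.9), "theta_nat")
  expect_error(material_params(mu = 0.06, rho = 0), "rho")
})

test_that("growth tensor realises in-plane areal growth about the normal", {
  expect_equal(growth_tensor(1, c(0, 0, 1)), diag(3))
  Fg <- growth_tensor(1.21, c(0, 0, 1))
  expect_equal(Fg, diag(c(1.1, 1.1, 1)))
  # cofactor maps the normal area element by exactly theta_g
  cof <- det(Fg) * t(solve(Fg))
  expect_equal(sqrt(sum((cof %*% c(0, 0, 1))^2)), 1.21, tolerance = 1e-12)
  # no growth through the thickness, any normal
  set.seed(1)
  for (i in 1:10) {
    N <- random_unit()
    tg <- runif(1, 1, 2)
    expect_equal(as.vector(growth_tensor(tg, N) %*% N), N, tolerance = 1e-12)
    expect_equal(areal_stretch(growth_tensor(tg, N), N), tg,
                 tolerance = 1e-12)
  }
  expect_error(growth_tensor(0.9), "irreversible")
  expect_error(growth_tensor(1.2, c(0, 0, 2)), "unit")
})

test_that("elastic part inverts the multiplicative split", {
  set.seed(2)
  for (i in 1:50) {
    F <- random_F()
    N <- random_unit()
    tg <- runif(1, 1, 1.8)
    Fe <- elastic_part(F, tg, N)
    expect_lt(max(abs(Fe %*% growth_tensor(tg, N) - F)), 1e-12)
  }
  F <- random_F()
  expect_equal(elastic_part(F, 1, c(0, 0, 1)), F)
  Fg <- growth_tensor(1.21, c(0, 0, 1))
  expect_equal(elastic_part(Fg, 1.21, c(0, 0, 1)), diag(3),
               tolerance = 1e-12)
})

test_that("areal stretch follows Nanson's relation", {
  expect_equal(areal_stretch(diag(3), c(0, 0, 1)), 1)
  expect_equal(areal_stretch(diag(c(1.2, 1.3, 1)), c(0, 0, 1)), 1.56,
               tolerance = 1e-12)
  th <- 0.3
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(areal_stretch(R, random_unit()), 1, tolerance = 1e-12)
})

test_that("areal stretch is multiplicative across the split", {
  set.seed(3)
  for (i in 1:50) {
    N <- random_unit()
    tg <- runif(1, 1, 1.9)
    Fe <- random_F()
    F <- Fe %*% growth_tensor(tg, N)
    expect_equal(areal_stretch(F, N), areal_stretch(Fe, N) * tg,
                 tolerance = 1e-12)
  }
})

test_that("strain energy density matches the closed form and vanishes on rotations", {
  p <- material_params(mu = 0.06, k = 1, theta_nat = 1.1, rho = 1116)
  expect_equal(strain_energy_density(diag(3), p), 0)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_lt(abs(strain_energy_density(R, p)), 1e-12)
  # worked value: I1e = 3.42, Je = 1.21
  Fe <- diag(c(1.1, 1.1, 1))
  expect_equal(strain_energy_density(Fe, p),
               0.06 / 2 * 0.42 - 0.06 * log(1.21) + 2.4 / 2 * log(1.21)^2,
               tolerance = 1e-12)
  expect_equal(strain_energy_density(Fe, p), 0.04477, tolerance = 1e-3)
  expect_error(strain_energy_density(diag(c(1, 1, -1)), p), "determinant")
})

test_that("Cauchy stress is symmetric, zero at rest, and energy-consistent", {
  p <- ref_params()
  s0 <- cauchy_stress(diag(3), p)
  expect_equal(s0$cauchy, matrix(0, 3, 3))
  expect_equal(s0$von_mises, 0)
  set.seed(4)
  for (i in 1:20) {
    Fe <- random_F()
    sm <- cauchy_stress(Fe, p)
    expect_lt(max(abs(sm$cauchy - t(sm$cauchy))) /
                max(abs(sm$cauchy)), 1e-12)
    expect_gte(sm$von_mises, 0)
    P_fd <- fd_piola(Fe, p)
    P_cs <- piola_from_cauchy(Fe, p)
    expect_lt(max(abs(P_cs - P_fd)) / max(abs(P_fd)), 1e-6)
  }
})

test_that("small-strain uniaxial response recovers the linear Young modulus", {
  p <- ref_params()
  eps <- 1e-6
  sxx <- function(elat) {
    Fe <- diag(c(1 + eps, 1 + elat, 1 + elat))
    cauchy_stress(Fe, p)$cauchy[1, 1]
  }
  slat <- function(elat) {
    Fe <- diag(c(1 + eps, 1 + elat, 1 + elat))
    cauchy_stress(Fe, p)$cauchy[2, 2]
  }
  elat <- uniroot(slat, c(-1e-5, 1e-5), tol = 1e-16)$root
  E_num <- sxx(elat) / eps
  E_lin <- p$mu * (3 * p$lam + 2 * p$mu) / (p$lam + p$mu)
  expect_equal(E_num, E_lin, tolerance = 1e-3)
})

test_that("growth rate law is proportional above homeostasis and clamped below", {
  p <- material_params(mu = 0.06, k = 1.2, theta_nat = 1.125, rho = 1116)
  expect_equal(growth_rate(p$theta_nat, p), 0)
  expect_equal(growth_rate(1.3, p), 1.2 * (1.3 - 1.125))
  expect_equal(growth_rate(1.3, p), 0.21)
  expect_equal(growth_rate(1.05, p), 0)
})

test_that("point driver matches a high-accuracy ODE oracle and its limits", {
  p <- material_params(mu = 0.06, k = 1.2, theta_nat = 1.125, rho = 1116)
  # degenerate hold at homeostasis
  tr0 <- point_driver(p$theta_nat, p, t_end = 2, dt = 0.5)
  expect_true(all(tr0$theta_g == 1))
  tr <- point_driver(1.4, p, t_end = 3.5, dt = 0.05)
  expect_true(all(diff(tr$theta_g) >= 0))
  expect_true(all(tr$theta_g <= 1.4 / 1.125 + 1e-12))
  ref <- desolve_theta_g(1.4, p, tr$time)
  expect_lt(max(abs(tr$theta_g - ref) / ref), 1e-4)
  # long-time equilibrium across the population ranges
  for (pars in list(c(0.2, 1.05), c(0.2, 1.2), c(1.92, 1.05), c(1.92, 1.2),
                    c(1.0, 1.12))) {
    pp <- material_params(mu = 0.05, k = pars[1], theta_nat = pars[2],
                          rho = 1116)
    tt <- 1.5 * pars[2]  # held total stretch above homeostasis
    tr <- point_driver(tt, pp, t_end = 30 / pars[1], dt = 1 / pars[1])
    expect_lt(abs(tail(tr$theta_g, 1) - tt / pars[2]), 1e-6)
  }
})
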