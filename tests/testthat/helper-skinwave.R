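# Shared fixtures and small oracles for the test suite.

# mid-range reference subject (also the worked example in the documentation)
ref_params <- function() material_params(mu = 0.058335, k = 1.2,
                                         theta_nat = 1.125, rho = 1120)

# random deformation gradient with positive determinant, bounded distortion
random_F <- function() {
  repeat {
    F <- diag(3) + matrix(stats::runif(9, -0.3, 0.3), 3, 3)
    if (det(F) > 0.3) return(F)
  }
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# finite-difference first Piola-Kirchhoff stress from the energy, at Fg = I
fd_piola <- function(F, params, h = 1e-6) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fm <- F
    Fp[i, j] <- Fp[i, j] + h
    Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (strain_energy_density(Fp, params) -
                  strain_energy_density(Fm, params)) / (2 * h)
  }
  P
}

# first Piola-Kirchhoff stress implied by the closed-form Cauchy stress
piola_from_cauchy <- function(Fe, params) {
  sig <- cauchy_stress(Fe, params)$cauchy
  det(Fe) * sig %*% t(solve(Fe))
}

# homogeneous traction-free equilibrium under equi-biaxial in-plane stretch s
# at areal growth theta_g: returns the full deformation gradient (material
# point oracle for the FE patch tests)
biaxial_point_state <- function(s, theta_g, params) {
  sg <- sqrt(theta_g)
  f <- function(sz) {
    Je <- (s / sg)^2 * sz
    params$mu * (sz^2 - 1) + params$lam * log(Je)
  }
  sz <- stats::uniroot(f, c(1e-3, 2), tol = 1e-14)$root
  diag(c(s, s, sz))
}

# reference growth trajectory via deSolve at tight tolerance (independent of
# the package's Heun stepper)
desolve_theta_g <- function(theta_total, params, times) {
  rhs <- function(t, y, p)
    list(max(0, params$k * (theta_total / y - params$theta_nat)))
  deSolve::ode(y = c(tg = 1), times = times, func = rhs, parms = NULL,
               method = "lsoda", rtol = 1e-10, atol = 1e-12)[, "tg"]
}

# fabricated subject record (no FE) for design-matrix bookkeeping tests
fake_record <- function(seed = 1, n = 1001L) {
  set.seed(seed)
  mk <- function(label) structure(
    list(times = seq(0, 0.0125, length.out = n),
         normal_displacement = stats::rnorm(n), probe_offset = 5,
         label = label, resampled = TRUE), class = "waveform")
  structure(list(
    params = material_params(mu = stats::runif(1, 0.02, 0.1),
                             k = stats::runif(1, 0.2, 1.9),
                             theta_nat = stats::runif(1, 1.05, 1.2),
                             rho = stats::runif(1, 1061, 1171)),
    waveforms = list(baseline = mk("baseline"), day0 = mk("day0"),
                     day3p5 = mk("day3p5")),
    growth_grid = matrix(stats::runif(25, 1, 1.5), 5, 5),
    extra_area = stats::runif(1, 0, 400)
  ), class = "subject_record")
}

# tiny-protocol config: single-element-thick coarse mesh, cheap but complete
tiny_config <- function(...) run_config(mesh = c(8L, 6L, 1L), ...)
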