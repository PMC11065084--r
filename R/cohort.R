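# Virtual-population generation: Latin hypercube sampling over the
# population parameter ranges.

#' Density range from a reference value
#'
#' Skin density is commonly treated as a constant reference value; the
#' cohort allows it to vary by a fraction around that reference (hydration
#' and composition variability).
#'
#' @param rho_ref Reference density, kg/m^3.
#' @param fraction Half-width of the relative variation, in (0, 1).
#' @return Length-2 range `c(lower, upper)`.
#' @examples
#' density_range_from_reference(1116, 0.05)  # c(1060.2, 1171.8)
#' @export
density_range_from_reference <- function(rho_ref = 1116, fraction = 0.05) {
  stopifnot(rho_ref > 0, fraction >= 0, fraction < 1)
  c(rho_ref * (1 - fraction), rho_ref * (1 + fraction))
}

#' Population parameter ranges
#'
#' Defaults are the study input space: shear modulus 0.01667-0.1 MPa,
#' growth rate 0.2-1.92 per day, natural areal pre-stretch 1.05-1.2, and
#' density 1116 kg/m^3 plus or minus 5 percent.
#'
#' @param mu,k,theta_nat,rho Length-2 ranges (lower < upper).
#' @return An object of class `parameter_ranges`.
#' @export
parameter_ranges <- function(mu = c(0.01667, 0.1), k = c(0.2, 1.92),
                             theta_nat = c(1.05, 1.2),
                             rho = density_range_from_reference(1116, 0.05)) {
  rg <- list(mu = mu, k = k, theta_nat = theta_nat, rho = rho)
  for (nm in names(rg)) {
    r <- rg[[nm]]
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2])
      stop(sprintf("range '%s' must be c(lower, upper) with lower < upper", nm))
  }
  structure(rg, class = "parameter_ranges")
}

# one-sample-per-stratum Latin hypercube in [0,1]^d
.lhs_unit <- function(n, d) {
  m <- lhs::randomLHS(n, d)
  dim(m) <- c(n, d)
  m
}

#' Sample a virtual cohort by Latin hypercube
#'
#' Draws `n` subjects with exactly one sample in each of the `n`
#' equal-probability strata per parameter (uniform placement within each
#' stratum), scaled to the given ranges. The first Lame parameter is set to
#' 40 times the shear modulus for every subject. Deterministic given `seed`.
#'
#' @param n Number of subjects.
#' @param ranges A [parameter_ranges()] object.
#' @param seed Integer RNG seed.
#' @return A data frame of class `skin_cohort` with columns `subject_id`,
#'   `mu_MPa`, `lam_MPa`, `k_per_day`, `theta_nat`, `rho_kg_m3`, `seed`.
#' @export
sample_cohort <- function(n, ranges = parameter_ranges(), seed = 1L) {
  stopifnot(n >= 1, inherits(ranges, "parameter_ranges"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  u <- .lhs_unit(as.integer(n), 4L)
  sc <- function(col, r) r[1] + u[, col] * (r[2] - r[1])
  out <- data.frame(
    subject_id = seq_len(n),
    mu_MPa = sc(1, ranges$mu),
    lam_MPa = 40 * sc(1, ranges$mu),
    k_per_day = sc(2, ranges$k),
    theta_nat = sc(3, ranges$theta_nat),
    rho_kg_m3 = sc(4, ranges$rho),
    seed = as.integer(seed)
  )
  class(out) <- c("skin_cohort", "data.frame")
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Material parameters of one cohort row
#' @param cohort A `skin_cohort` data frame.
#' @param i Subject index (row).
#' @return A [material_params()] object.
#' @export
cohort_params <- function(cohort, i) {
  material_params(mu = cohort$mu_MPa[i], k = cohort$k_per_day[i],
                  theta_nat = cohort$theta_nat[i], rho = cohort$rho_kg_m3[i])
}

#' Write / read a cohort table as CSV
#' @param cohort A `skin_cohort`.
#' @param path CSV file path.
#' @return `path` (write) or the cohort (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- as.data.frame(cohort)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("skin_cohort", "data.frame")
  out
}
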