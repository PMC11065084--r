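# The simulated clinical protocol: baseline / day-0 / day-3.5 wave
# measurements, the day-7 growth field, waveform resampling, 5x5 grid
# coarsening and the extra-grown-area metric.

#' Resample a waveform onto the common input grid
#'
#' Cubic interpolating spline through the recorded samples, evaluated at
#' `n` equidistant times spanning `[0, t_max]`. Original sample values are
#' reproduced exactly at their own abscissae (interpolation, not smoothing).
#'
#' @param w A [excite_and_record()] waveform.
#' @param n Number of grid points (default 1001).
#' @param t_max End of the common grid in seconds (default 0.0125).
#' @return A `waveform` on the common grid with `resampled = TRUE`.
#' @export
resample_waveform <- function(w, n = 1001L, t_max = 0.0125) {
  stopifnot(inherits(w, "waveform"))
  if (min(w$times) > 0 || max(w$times) < t_max - 1e-12)
    stop("waveform does not cover the common grid [0, t_max]")
  sf <- stats::splinefun(w$times, w$normal_displacement, method = "fmm")
  tt <- seq(0, t_max, length.out = n)
  structure(list(times = tt, normal_displacement = sf(tt),
                 probe_offset = w$probe_offset, label = w$label,
                 resampled = TRUE),
            class = "waveform")
}

#' First-peak arrival time of a waveform
#'
#' Time of the first local maximum of the absolute normal displacement at or
#' above `frac` of the maximum attained inside the early window. The early
#' window keeps late, large reflections from raising the detection threshold
#' above the genuine first arrival. The peak position is refined to
#' sub-sample resolution by a parabolic fit through the three samples around
#' the discrete maximum.
#'
#' @param w A `waveform`.
#' @param frac Detection threshold as a fraction of the early-window maximum.
#' @param early Early-window length in seconds.
#' @return First-peak time in seconds.
#' @export
first_peak_time <- function(w, frac = 0.1, early = 0.003) {
  stopifnot(inherits(w, "waveform"))
  y <- abs(w$normal_displacement)
  t <- w$times
  thr <- frac * max(y[t <= early])
  n <- length(y)
  for (i in 2:(n - 1L)) {
    if (y[i] >= thr && y[i] >= y[i - 1L] && y[i] >= y[i + 1L]) {
      den <- y[i - 1L] - 2 * y[i] + y[i + 1L]
      delta <- if (den < 0) 0.5 * (y[i - 1L] - y[i + 1L]) / den else 0
      delta <- max(-0.5, min(0.5, delta))
      return(t[i] + delta * (t[i + 1L] - t[i]))
    }
  }
  NA_real_
}

#' Coarsen a per-element growth field to an n x n grid
#'
#' Partitions the quarter-model top surface into `n x n` equal regions in
#' reference coordinates and represents each region by the growth value of
#' the element containing the region's centroid.
#'
#' @param theta_elem Per-element areal growth over the whole mesh (e.g.
#'   [element_theta_g()]).
#' @param mesh The [build_quarter_mesh()] mesh.
#' @param n Grid dimension (default 5).
#' @return An `n x n` matrix; entry `[i, j]` is the region with x-index `i`
#'   (from the symmetry corner outward) and y-index `j`.
#' @export
coarsen_growth <- function(theta_elem, mesh, n = 5L) {
  stopifnot(inherits(mesh, "skin_mesh"),
            length(theta_elem) == nrow(mesh$hexes))
  te <- mesh$top_elems
  rx <- mesh$dims[1] / n
  ry <- mesh$dims[2] / n
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cx <- (i - 0.5) * rx
    cy <- (j - 0.5) * ry
    el <- te$elem[which.min((te$cx - cx)^2 + (te$cy - cy)^2)]
    out[i, j] <- theta_elem[el]
  }
  out
}

#' Extra grown skin area
#'
#' Total new reference-surface area generated by growth: the sum over
#' top-surface elements of `(theta_g - 1)` times the element's reference
#' area. Non-negative under the irreversible growth law.
#'
#' @inheritParams coarsen_growth
#' @return Extra area in mm^2 (quarter model).
#' @export
extra_area <- function(theta_elem, mesh) {
  stopifnot(inherits(mesh, "skin_mesh"),
            length(theta_elem) == nrow(mesh$hexes))
  te <- mesh$top_elems
  sum((theta_elem[te$elem] - 1) * te$area)
}

#' Extra area implied by a coarsened growth grid
#'
#' Each grid cell contributes `(theta_g - 1)` times its region's reference
#' area (quarter-model top surface split into equal cells).
#'
#' @param grid An `n x n` growth grid.
#' @param dims Quarter-model in-plane extents, mm.
#' @return Extra area in mm^2.
#' @export
grid_extra_area <- function(grid, dims = c(50, 37.5)) {
  cell <- dims[1] / nrow(grid) * dims[2] / ncol(grid)
  sum((grid - 1) * cell)
}

#' Run the full simulated expansion protocol for one subject
#'
#' Reproduces the four-phase measurement schedule on one virtual subject:
#' (1) pre-stretch to the natural in vivo state and a baseline wave
#' measurement; (2) expander inflation, held for `hold_day0` days, and the
#' day-0 measurement; (3) growth to day 3.5 and the third measurement;
#' (4) growth to day 7, storing the coarsened growth field and the
#' extra-area metric. All phases share the single inflation solution.
#'
#' @param params A [material_params()] subject.
#' @param config A [run_config()] list.
#' @param warm Optional warm-start increment from [inflation_warmstart()].
#' @param keep_states If `TRUE`, attach the final solver states (large).
#' @return An object of class `subject_record`: list with `params`,
#'   `waveforms` (named list of the three resampled waveforms), `raw_waveforms`,
#'   `growth_grid` (5 x 5), `extra_area` (mm^2), `first_peaks` (s).
#' @export
run_protocol <- function(params, config = run_config(), warm = NULL,
                         keep_states = FALSE) {
  stopifnot(inherits(params, "material_params"))
  rg <- config$ranges
  inside <- params$mu >= rg$mu[1] && params$mu <= rg$mu[2] &&
    params$k >= rg$k[1] && params$k <= rg$k[2] &&
    params$theta_nat >= rg$theta_nat[1] && params$theta_nat <= rg$theta_nat[2] &&
    params$rho >= rg$rho[1] && params$rho <= rg$rho[2]
  if (!inside)
    warning("subject parameters outside the sampling ranges; proceeding")
  mesh <- build_quarter_mesh(config$mesh[1], config$mesh[2], config$mesh[3],
                             dims = config$dims)
  # solve all measurement states first, then record the three waves with one
  # common time step so their arrival times share a time discretisation
  pre <- prestretch_state(mesh, params)
  infl <- inflate_state(pre, config$footprint, config$volume_cc, warm = warm)
  st0 <- grow(infl, config$hold_day0, dt_growth = config$dt_growth)
  st35 <- grow(st0, config$day_mid, dt_growth = config$dt_growth)
  dt <- min(vapply(list(pre, st0, st35), wave_time_step, numeric(1),
                   safety = config$cfl_safety))
  wave <- function(state, label)
    excite_and_record(state, impact_x = config$impact_x,
                      probe_offset = config$probe_offset,
                      pressure = config$pressure,
                      duration = config$pulse_s,
                      t_record = config$t_record, label = label,
                      safety = config$cfl_safety, dt = dt,
                      damping = config$wave_damping)
  w_base <- wave(pre, "baseline")
  w_day0 <- wave(st0, "day0")
  w_day35 <- wave(st35, "day3p5")
  st <- grow(st35, config$day_final, dt_growth = config$dt_growth)
  theta_el <- element_theta_g(st)
  grid <- coarsen_growth(theta_el, mesh, config$grid)
  raw <- list(baseline = w_base, day0 = w_day0, day3p5 = w_day35)
  resampled <- lapply(raw, resample_waveform, n = config$n_samples,
                      t_max = config$t_record)
  rec <- structure(list(
    params = params,
    waveforms = resampled,
    raw_waveforms = raw,
    growth_grid = grid,
    extra_area = extra_area(theta_el, mesh),
    first_peaks = vapply(raw, first_peak_time, numeric(1))
  ), class = "subject_record")
  if (keep_states) rec$final_state <- st
  rec
}

#' @export
print.subject_record <- function(x, ...) {
  cat("subject_record:\n")
  cat(sprintf("  mu = %.4g MPa, k = %.3g /day, theta_nat = %.4g, rho = %.5g kg/m^3\n",
              x$params$mu, x$params$k, x$params$theta_nat, x$params$rho))
  cat(sprintf("  first peaks (ms): baseline %.3f, day0 %.3f, day3.5 %.3f\n",
              1e3 * x$first_peaks[["baseline"]],
              1e3 * x$first_peaks[["day0"]],
              1e3 * x$first_peaks[["day3p5"]]))
  cat(sprintf("  day-7 growth grid: %.3f .. %.3f; extra area %.1f mm^2\n",
              min(x$growth_grid), max(x$growth_grid), x$extra_area))
  invisible(x)
}
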