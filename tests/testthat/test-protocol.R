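# Measurement protocol: resampling, growth-field coarsening, extra area,
# and the per-subject record.

test_that("resampling interpolates exactly and lands on the common grid", {
  mkw <- function(t, y) structure(
    list(times = t, normal_displacement = y, probe_offset = 5,
         label = "baseline"), class = "waveform")
  # constant signal
  w <- mkw(seq(0, 0.0125, length.out = 400), rep(3.25, 400))
  r <- resample_waveform(w)
  expect_equal(length(r$times), 1001)
  expect_equal(r$times[1], 0)
  expect_equal(r$times[1001], 0.0125)
  expect_true(all(r$normal_displacement == 3.25))
  # a signal already on the common grid is reproduced at the knots
  tt <- seq(0, 0.0125, length.out = 1001)
  y <- sin(2 * pi * 400 * tt)
  r2 <- resample_waveform(mkw(tt, y))
  expect_equal(r2$normal_displacement, y, tolerance = 1e-12)
  # coverage shortfall
  expect_error(resample_waveform(mkw(seq(0, 0.01, length.out = 50),
                                     rnorm(50))), "cover")
})

test_that("growth-field coarsening picks the region-centroid element", {
  mesh <- build_quarter_mesh(25, 10, 1)
  # homogeneous field
  g <- coarsen_growth(rep(1.37, nrow(mesh$hexes)), mesh)
  expect_equal(dim(g), c(5L, 5L))
  expect_true(all(g == 1.37))
  # linear-in-x field: grid entries equal centroid values within one element
  theta <- 1 + 0.001 * mesh$top_elems$cx
  full <- rep(1, nrow(mesh$hexes))
  full[mesh$top_elems$elem] <- theta
  g2 <- coarsen_growth(full, mesh)
  dx <- 50 / 25
  for (i in 1:5) {
    expected <- 1 + 0.001 * ((i - 0.5) * 10)
    expect_lt(max(abs(g2[i, ] - expected)), 0.001 * dx)
  }
})

test_that("extra area integrates (theta_g - 1) over the reference surface", {
  mesh <- build_quarter_mesh(10, 6, 2)
  expect_equal(extra_area(rep(1, nrow(mesh$hexes)), mesh), 0)
  expect_equal(extra_area(rep(1.1, nrow(mesh$hexes)), mesh), 187.5,
               tolerance = 1e-12)
  # brute-force oracle over top elements
  set.seed(11)
  th <- rep(1, nrow(mesh$hexes))
  th[mesh$top_elems$elem] <- runif(nrow(mesh$top_elems), 1, 1.6)
  brute <- 0
  for (r in seq_len(nrow(mesh$top_elems))) {
    e <- mesh$top_elems$elem[r]
    brute <- brute + (th[e] - 1) * (50 / 10) * (37.5 / 6)
  }
  expect_equal(extra_area(th, mesh), brute, tolerance = 1e-12)
  # grid form of the same metric
  expect_equal(grid_extra_area(matrix(1.1, 5, 5)), 187.5)
  expect_equal(grid_extra_area(matrix(1, 5, 5)), 0)
})

test_that("the protocol yields a complete, deterministic subject record", {
  cfg <- tiny_config()
  p <- ref_params()
  rec <- run_protocol(p, cfg)
  expect_s3_class(rec, "subject_record")
  expect_named(rec$waveforms, c("baseline", "day0", "day3p5"))
  for (w in rec$waveforms) {
    expect_equal(length(w$normal_displacement), 1001)
    expect_true(isTRUE(w$resampled))
  }
  expect_equal(dim(rec$growth_grid), c(5L, 5L))
  expect_true(all(rec$growth_grid >= 1))
  expect_gte(rec$extra_area, 0)
  # day-7 growth bounded by the point-driver ceiling at the apex
  apex_total <- max(state_fields(
    inflate_state(prestretch_state(
      build_quarter_mesh(cfg$mesh[1], cfg$mesh[2], cfg$mesh[3]), p)))$theta_F)
  expect_lt(max(rec$growth_grid), apex_total / p$theta_nat + 1e-3)
  # bit-identical reproduction
  rec2 <- run_protocol(p, cfg)
  expect_identical(rec$waveforms, rec2$waveforms)
  expect_identical(rec$growth_grid, rec2$growth_grid)
})

test_that("without growth the day-0 and day-3.5 waveforms coincide", {
  cfg <- tiny_config()
  p <- material_params(mu = 0.06, k = 0, theta_nat = 1.125, rho = 1116)
  # k = 0 sits outside the sampling ranges, which run_protocol flags
  expect_warning(rec <- run_protocol(p, cfg), "outside")
  d0 <- rec$waveforms$day0$normal_displacement
  d35 <- rec$waveforms$day3p5$normal_displacement
  expect_lt(max(abs(d0 - d35)), 1e-8 * max(abs(d0)))
})

test_that("subjects outside the sampling ranges trigger a warning, not an error", {
  cfg <- tiny_config()
  p <- material_params(mu = 0.2, k = 1, theta_nat = 1.1, rho = 1116)
  expect_warning(rec <- run_protocol(p, cfg), "outside")
  expect_s3_class(rec, "subject_record")
})
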