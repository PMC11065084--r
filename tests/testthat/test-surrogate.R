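# Inverse surrogate: design assembly, MLP training, cross-validation.

test_that("R-squared matches hand-computed values and its contracts", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  y <- c(4, 7, 1, 2)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)  # SS_res 1, SS_tot 2
  expect_lt(r_squared(c(1, 2, 3), c(3, 2, 1)), 0)
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("design matrices concatenate waveforms and stack the 28 targets", {
  recs <- lapply(1:4, fake_record)
  d <- build_design(recs)
  expect_equal(dim(d$X), c(4L, 3003L))
  expect_equal(dim(d$Y), c(4L, 28L))
  expect_equal(colnames(d$Y)[26:28], c("mu", "k", "theta_nat"))
  # slicing X recovers each waveform exactly
  r <- recs[[2]]
  expect_identical(d$X[2, 1:1001],
                   r$waveforms$baseline$normal_displacement)
  expect_identical(d$X[2, 1002:2002],
                   r$waveforms$day0$normal_displacement)
  expect_identical(d$X[2, 2003:3003],
                   r$waveforms$day3p5$normal_displacement)
  # Y row = grid (x-fastest) then parameters; rho is not a target
  expect_identical(unname(d$Y[2, 1:25]), as.vector(r$growth_grid))
  expect_identical(unname(d$Y[2, 26]), r$params$mu)
  expect_false(any(colnames(d$Y) == "rho"))
  # missing waveform is a record-level error
  bad <- recs
  bad[[3]]$waveforms$day0 <- NULL
  expect_error(build_design(bad), "missing")
})

test_that("training is deterministic given the seed", {
  set.seed(10)
  X <- matrix(rnorm(60 * 12), 60, 12)
  Y <- X %*% matrix(rnorm(12 * 4), 12, 4)
  m1 <- fit_surrogate(X, Y, hidden = c(8, 8), seed = 42, epochs = 40)
  m2 <- fit_surrogate(X, Y, hidden = c(8, 8), seed = 42, epochs = 40)
  expect_identical(predict(m1, X), predict(m2, X))
  m3 <- fit_surrogate(X, Y, hidden = c(8, 8), seed = 43, epochs = 40)
  expect_false(identical(predict(m1, X), predict(m3, X)))
})

test_that("the network learns a noiseless linear map essentially exactly", {
  set.seed(20)
  n <- 500
  X <- matrix(rnorm(n * 5), n, 5)
  W <- matrix(rnorm(5 * 3), 5, 3)
  Y <- X %*% W
  tr <- 1:400
  te <- 401:500
  m <- fit_surrogate(X[tr, ], Y[tr, ], hidden = c(32, 64, 32), seed = 1,
                     epochs = 1000, patience = 150, lr = 3e-3, batch = 32)
  pred <- predict(m, X[te, ])
  for (j in 1:3) expect_gt(r_squared(Y[te, j], pred[, j]), 0.99)
})

test_that("prediction validates input dimensionality and output width", {
  set.seed(30)
  X <- matrix(rnorm(40 * 6), 40, 6)
  Y <- matrix(rnorm(40 * 3), 40, 3)
  m <- fit_surrogate(X, Y, hidden = c(4), seed = 1, epochs = 5)
  expect_equal(dim(predict(m, X)), c(40L, 3L))
  expect_error(predict(m, X[, 1:5]), "dimensionality")
  expect_error(fit_surrogate(X * NA, Y, seed = 1), "non-finite")
})

test_that("cross-validation partitions subjects and fills the report", {
  set.seed(40)
  recs <- lapply(1:30, fake_record)
  d <- build_design(recs)
  cv <- cross_validate(d, architectures = list(c(4)), folds = 10,
                       repeats = 2, base_seed = 9, epochs = 3)
  # folds x repeats fits, (28 + growth_avg) targets per fit
  expect_equal(nrow(cv), 10 * 2 * 29)
  expect_setequal(unique(cv$fold), 1:10)
  expect_setequal(unique(cv$repeat_), 1:2)
  sm <- summary(cv)
  expect_true(all(c("median_r2", "sd_r2") %in% names(sm)))
  expect_equal(unique(sm$n_fits), 20)
  # every subject is tested exactly once per repeat
  fa <- skinwave:::.fold_assign(30, 10, seed = 9 + 1000)
  expect_equal(sort(as.vector(table(fa))), rep(3, 10))
  expect_error(cross_validate(d, folds = 40), "fewer subjects")
})

test_that("standardisation is fitted on the training rows only (no leakage)", {
  set.seed(50)
  X <- matrix(rnorm(50 * 8), 50, 8)
  Y <- matrix(rnorm(50 * 2), 50, 2)
  train <- 1:35
  m <- fit_surrogate(X[train, ], Y[train, ], hidden = c(4), seed = 1,
                     epochs = 3)
  expect_equal(m$scaler_x$center, colMeans(X[train, ]))
  expect_false(isTRUE(all.equal(m$scaler_x$center, colMeans(X))))
})

test_that("subject-level prediction unpacks the grid and the implied area", {
  # stub model: zero weights, target scaler centred on a known output
  grid_val <- 1.1
  centre <- c(rep(grid_val, 25), 0.05, 1.2, 1.125)
  sizes <- c(3003, 4, 28)
  net <- list(W = list(matrix(0, 3003, 4), matrix(0, 4, 28)),
              b = list(numeric(4), numeric(28)))
  stub <- structure(list(
    net = net,
    scaler_x = list(center = numeric(3003), scale = rep(1, 3003)),
    scaler_y = list(center = centre, scale = rep(1, 28)),
    hidden = 4, seed = 1L, val_loss = 0, epochs_run = 0L, best_epoch = 0L,
    target_names = c(paste0("g", 1:25), "mu", "k", "theta_nat")),
    class = "skinwave_mlp")
  out <- predict_subject(stub, numeric(3003))
  expect_equal(out$growth_grid, matrix(grid_val, 5, 5))
  expect_equal(out$extra_area, 187.5)
  expect_equal(out$mu, 0.05)
  expect_error(predict_subject(stub, numeric(100)), "3003")
  # an all-ones grid implies zero extra area
  stub$scaler_y$center <- c(rep(1, 25), 0.05, 1.2, 1.125)
  expect_equal(predict_subject(stub, numeric(3003))$extra_area, 0)
})
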