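# The inverse surrogate: a fully connected multilayer perceptron mapping the
# three resampled waveforms (3 x 1001 = 3003 inputs) to 28 targets -- the 25
# coarsened day-7 growth values followed by mu, k and theta_nat -- with
# repeated k-fold cross-validation for architecture evaluation.

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` taken about the mean of
#' `y_true`. Equals 1 for perfect prediction, 0 for predicting the mean,
#' and is unbounded below.
#'
#' @param y_true,y_pred Numeric vectors of equal length (>= 2).
#' @return Scalar R-squared.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
r_squared <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("R^2 undefined for constant y_true")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Assemble the design matrices from subject records
#'
#' Each input row is the concatenation of the three resampled waveforms in
#' the fixed order baseline, day 0, day 3.5 (1001 samples each). Each target
#' row is the 25 growth-grid values -- column `(iy - 1) * 5 + ix` holds grid
#' cell `(ix, iy)`, x-index fastest -- followed by `mu`, `k`, `theta_nat`.
#' Density is not a target.
#'
#' @param records List of `subject_record` objects.
#' @return An object of class `design_pair`: list with `X` (n x 3003),
#'   `Y` (n x 28) and `extra_area` (n).
#' @export
build_design <- function(records) {
  stopifnot(length(records) >= 1)
  n_s <- length(records[[1]]$waveforms$baseline$times)
  xrow <- function(r) {
    w <- r$waveforms
    if (is.null(w$baseline) || is.null(w$day0) || is.null(w$day3p5))
      stop("record is missing a waveform")
    c(w$baseline$normal_displacement, w$day0$normal_displacement,
      w$day3p5$normal_displacement)
  }
  yrow <- function(r) {
    if (is.null(r$growth_grid)) stop("record is missing the growth grid")
    c(as.vector(r$growth_grid), r$params$mu, r$params$k, r$params$theta_nat)
  }
  X <- do.call(rbind, lapply(records, xrow))
  Y <- do.call(rbind, lapply(records, yrow))
  if (anyNA(X) || anyNA(Y)) stop("non-finite values in the design")
  ng <- length(as.vector(records[[1]]$growth_grid))
  colnames(Y) <- c(paste0("g", seq_len(ng)), "mu", "k", "theta_nat")
  structure(list(X = X, Y = Y,
                 extra_area = vapply(records, function(r)
                   if (is.null(r$extra_area)) NA_real_ else r$extra_area,
                   numeric(1)),
                 n_samples = n_s),
            class = "design_pair")
}

# column-wise standardisation fitted on (training) data
.fit_scaler <- function(M) {
  mu <- colMeans(M)
  sd <- apply(M, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  list(center = mu, scale = sd)
}
.apply_scaler <- function(M, s) sweep(sweep(M, 2, s$center), 2, s$scale, "/")
.invert_scaler <- function(M, s) sweep(sweep(M, 2, s$scale, "*"), 2, s$center, "+")

.init_mlp <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

.mlp_forward <- function(net, X) {
  L <- length(net$W)
  H <- X
  acts <- vector("list", L + 1L)
  acts[[1]] <- H
  for (l in seq_len(L)) {
    Z <- H %*% net$W[[l]]
    Z <- sweep(Z, 2, net$b[[l]], "+")
    H <- if (l < L) pmax(Z, 0) else Z  # ReLU hidden, linear output
    acts[[l + 1L]] <- H
  }
  list(out = H, acts = acts)
}

# one Adam step on a minibatch (MSE loss, standardized targets); decoupled
# weight decay on the weights (not the biases)
.mlp_step <- function(net, opt, Xb, Yb, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  L <- length(net$W)
  fw <- .mlp_forward(net, Xb)
  nb <- nrow(Xb)
  delta <- 2 * (fw$out - Yb) / (nb * ncol(Yb))
  opt$t <- opt$t + 1
  corr1 <- 1 - 0.9^opt$t
  corr2 <- 1 - 0.999^opt$t
  for (l in seq(L, 1L)) {
    A <- fw$acts[[l]]
    gW <- crossprod(A, delta)
    gb <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(net$W[[l]])) * (fw$acts[[l]] > 0)
    }
    opt$mW[[l]] <- beta1 * opt$mW[[l]] + (1 - beta1) * gW
    opt$vW[[l]] <- beta2 * opt$vW[[l]] + (1 - beta2) * gW^2
    opt$mb[[l]] <- beta1 * opt$mb[[l]] + (1 - beta1) * gb
    opt$vb[[l]] <- beta2 * opt$vb[[l]] + (1 - beta2) * gb^2
    net$W[[l]] <- net$W[[l]] -
      lr * (opt$mW[[l]] / corr1) / (sqrt(opt$vW[[l]] / corr2) + eps) -
      lr * weight_decay * net$W[[l]]
    net$b[[l]] <- net$b[[l]] -
      lr * (opt$mb[[l]] / corr1) / (sqrt(opt$vb[[l]] / corr2) + eps)
  }
  list(net = net, opt = opt)
}

#' Fit the waveform-to-properties surrogate
#'
#' Multi-output regression MLP with ReLU hidden layers and a linear output,
#' trained with the Adam optimiser on mean-squared error over per-column
#' standardized inputs and targets (standardisation is fitted on the
#' training rows only, and stored with the model). A fraction of the
#' training rows is held out as an inner validation split for early
#' stopping. Training is deterministic given `seed`.
#'
#' @param X Inputs, n x p (rows = subjects).
#' @param Y Targets, n x q.
#' @param hidden Hidden-layer widths, default `c(32, 64, 32)`.
#' @param seed Integer seed for initialisation and shuffling.
#' @param epochs Maximum training epochs.
#' @param batch Minibatch size.
#' @param lr Adam learning rate.
#' @param val_frac Inner validation fraction for early stopping.
#' @param patience Early-stopping patience in epochs.
#' @param weight_decay Decoupled L2 weight decay.
#' @return An object of class `skinwave_mlp`.
#' @export
fit_surrogate <- function(X, Y, hidden = c(32, 64, 32), seed = 1L,
                          epochs = 500L, batch = 64L, lr = 1e-3,
                          val_frac = 0.1, patience = 40L,
                          weight_decay = 0) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 2)
  if (anyNA(X) || anyNA(Y) || !all(is.finite(X)) || !all(is.finite(Y)))
    stop("non-finite values in the training data")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  sx <- .fit_scaler(X)
  sy <- .fit_scaler(Y)
  Xs <- .apply_scaler(X, sx)
  Ys <- .apply_scaler(Y, sy)
  n <- nrow(Xs)
  n_val <- max(0L, min(n - 2L, round(val_frac * n)))
  perm <- sample.int(n)
  vidx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
  tidx <- setdiff(perm, vidx)
  sizes <- c(ncol(Xs), hidden, ncol(Ys))
  net <- .init_mlp(sizes)
  opt <- list(mW = lapply(net$W, function(w) w * 0),
              vW = lapply(net$W, function(w) w * 0),
              mb = lapply(net$b, function(b) b * 0),
              vb = lapply(net$b, function(b) b * 0), t = 0)
  best <- list(net = net, loss = Inf, epoch = 0L)
  stall <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(tidx)
    for (s in seq(1L, length(ord), by = batch)) {
      bidx <- ord[s:min(s + batch - 1L, length(ord))]
      if (length(bidx) < 2L) next
      upd <- .mlp_step(net, opt, Xs[bidx, , drop = FALSE],
                       Ys[bidx, , drop = FALSE], lr,
                       weight_decay = weight_decay)
      net <- upd$net
      opt <- upd$opt
    }
    mon_idx <- if (n_val > 0) vidx else tidx
    pred <- .mlp_forward(net, Xs[mon_idx, , drop = FALSE])$out
    loss <- mean((pred - Ys[mon_idx, , drop = FALSE])^2)
    if (loss < best$loss - 1e-7) {
      best <- list(net = net, loss = loss, epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  structure(list(net = best$net, scaler_x = sx, scaler_y = sy,
                 hidden = hidden, seed = as.integer(seed),
                 val_loss = best$loss, epochs_run = ep,
                 best_epoch = best$epoch,
                 target_names = colnames(Y)),
            class = "skinwave_mlp")
}

#' @export
print.skinwave_mlp <- function(x, ...) {
  cat(sprintf("skinwave_mlp: hidden (%s), %d inputs -> %d targets; best epoch %d (val MSE %.3g)\n",
              paste(x$hidden, collapse = ", "),
              length(x$scaler_x$center), length(x$scaler_y$center),
              x$best_epoch, x$val_loss))
  invisible(x)
}

#' @export
predict.skinwave_mlp <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$scaler_x$center))
    stop("wrong input dimensionality: expected ",
         length(object$scaler_x$center), " columns")
  Xs <- .apply_scaler(X, object$scaler_x)
  out <- .invert_scaler(.mlp_forward(object$net, Xs)$out, object$scaler_y)
  colnames(out) <- object$target_names
  out
}

# near-equal fold assignment, shuffled with a repeat-specific seed
.fold_assign <- function(n, folds, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  sample(rep(seq_len(folds), length.out = n))
}

#' Repeated k-fold cross-validation of surrogate architectures
#'
#' For every candidate architecture, runs `folds`-fold cross-validation
#' `repeats` times with repeat-specific shuffles; every subject is tested
#' exactly once per repeat. R-squared is computed per target on the held-out
#' subjects only; input/target standardisation is refitted inside every
#' training fold (no leakage). The growth-field summary target `growth_avg`
#' is the mean R-squared over the 25 grid targets of the same fit.
#'
#' @param design A [build_design()] pair.
#' @param architectures List of hidden-layer width vectors.
#' @param folds,repeats CV shape (default 10 x 5).
#' @param base_seed Base seed; repeat and fold seeds derive from it.
#' @param ... Passed to [fit_surrogate()] (epochs, batch, lr, ...).
#' @return A `cv_report`: data frame with columns `architecture`, `target`,
#'   `repeat_`, `fold`, `r2`.
#' @export
cross_validate <- function(design, architectures = list(c(32, 64, 32)),
                           folds = 10L, repeats = 5L, base_seed = 1L, ...) {
  stopifnot(inherits(design, "design_pair"))
  X <- design$X; Y <- design$Y
  n <- nrow(X)
  if (n < folds) stop("fewer subjects than folds")
  grid_cols <- grep("^g\\d+$", colnames(Y))
  rows <- list()
  for (a in seq_along(architectures)) {
    arch <- architectures[[a]]
    arch_lab <- paste(arch, collapse = "x")
    for (rep_i in seq_len(repeats)) {
      fa <- .fold_assign(n, folds, seed = base_seed + 1000L * rep_i)
      for (fold_i in seq_len(folds)) {
        test <- which(fa == fold_i)
        train <- which(fa != fold_i)
        fit_seed <- (base_seed + 7919L * rep_i + 104729L * fold_i +
                       13L * a) %% 2147483647L
        mdl <- fit_surrogate(X[train, , drop = FALSE],
                             Y[train, , drop = FALSE],
                             hidden = arch, seed = fit_seed, ...)
        pred <- predict(mdl, X[test, , drop = FALSE])
        # R^2 is undefined for a target that is (essentially) constant over
        # the test fold: grid regions with no measurable growth (below 0.1%
        # of area across the fold) are excluded from the growth-field
        # average rather than scored against numerical-noise variance
        r2 <- vapply(seq_len(ncol(Y)), function(j) {
          if (j %in% grid_cols && stats::sd(Y[test, j]) < 1e-3) NA_real_
          else if (stats::sd(Y[test, j]) == 0) NA_real_
          else r_squared(Y[test, j], pred[, j])
        }, numeric(1))
        names(r2) <- colnames(Y)
        r2 <- c(r2, growth_avg = mean(r2[grid_cols], na.rm = TRUE))
        rows[[length(rows) + 1L]] <- data.frame(
          architecture = arch_lab, target = names(r2),
          repeat_ = rep_i, fold = fold_i, r2 = unname(r2))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cv_report", "data.frame")
  out
}

#' Summarise a cross-validation report
#'
#' Median and standard deviation of the held-out R-squared per architecture
#' and target, over all folds and repeats.
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return Data frame with `architecture`, `target`, `median_r2`, `sd_r2`,
#'   `n_fits`.
#' @export
summary.cv_report <- function(object, ...) {
  sp <- split(object, list(object$architecture, object$target), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    architecture = d$architecture[1], target = d$target[1],
    median_r2 = stats::median(d$r2, na.rm = TRUE),
    sd_r2 = stats::sd(d$r2, na.rm = TRUE),
    n_fits = nrow(d))))
  rownames(out) <- NULL
  out[order(out$architecture, out$target), ]
}

#' Export a CV report and its summary
#' @param report A `cv_report`.
#' @param csv_path Long-format CSV destination.
#' @param json_path JSON summary destination (medians and sds per target).
#' @return Invisibly, the summary data frame.
#' @export
export_cv_report <- function(report, csv_path = NULL, json_path = NULL) {
  sm <- summary(report)
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(sm, json_path, dataframe = "rows", digits = NA)
  invisible(sm)
}
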