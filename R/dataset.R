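# Dataset persistence and the pipeline drivers that bind cohort, protocol
# and surrogate together. A dataset is a directory: config.yaml, cohort.csv,
# per-subject RDS records under subjects/, and failures.csv if any subject's
# solve did not converge.

.subject_file <- function(dir, i) file.path(dir, "subjects",
                                            sprintf("subject_%04d.rds", i))

#' Simulate a virtual cohort through the full protocol
#'
#' Samples the cohort by Latin hypercube, then runs the four-phase
#' measurement protocol for every subject on the configured mesh. The run is
#' resumable: subjects whose record file already exists are skipped, so an
#' interrupted run continues where it stopped and yields the same dataset
#' (per-subject results are independent and deterministic). Solver failures
#' are logged per subject; the run aborts only if more than 1 percent of
#' subjects fail.
#'
#' @param config A [run_config()]; `n_subjects`, `seed` and `ranges` control
#'   the cohort.
#' @param dir Output dataset directory (created if missing).
#' @param progress Print per-subject progress lines.
#' @return The dataset directory, invisibly.
#' @export
simulate_cohort <- function(config = run_config(), dir, progress = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(file.path(dir, "subjects"), recursive = TRUE,
             showWarnings = FALSE)
  write_run_config(config, file.path(dir, "config.yaml"))
  cohort <- sample_cohort(config$n_subjects, config$ranges, config$seed)
  write_cohort_csv(cohort, file.path(dir, "cohort.csv"))
  mesh <- build_quarter_mesh(config$mesh[1], config$mesh[2], config$mesh[3],
                             dims = config$dims)
  warm <- inflation_warmstart(mesh, config$footprint, config$volume_cc)
  failures <- data.frame(subject_id = integer(0), message = character(0))
  hash <- config_hash(config)
  for (i in seq_len(nrow(cohort))) {
    f <- .subject_file(dir, i)
    if (file.exists(f)) next
    t0 <- proc.time()[3]
    rec <- tryCatch(
      run_protocol(cohort_params(cohort, i), config, warm = warm),
      error = function(e) e)
    if (inherits(rec, "error")) {
      failures <- rbind(failures, data.frame(
        subject_id = i, message = conditionMessage(rec)))
      if (progress)
        message(sprintf("subject %d/%d FAILED: %s", i, nrow(cohort),
                        conditionMessage(rec)))
      next
    }
    rec$raw_waveforms <- NULL  # raw samples are bulky; the grid form is used
    rec$subject_id <- i
    rec$config_hash <- hash
    saveRDS(rec, f)
    if (progress)
      message(sprintf("subject %d/%d done in %.1f s", i, nrow(cohort),
                      proc.time()[3] - t0))
  }
  if (nrow(failures)) {
    utils::write.csv(failures, file.path(dir, "failures.csv"),
                     row.names = FALSE)
    if (nrow(failures) > 0.01 * nrow(cohort))
      stop(sprintf("%d of %d subjects failed to simulate",
                   nrow(failures), nrow(cohort)))
  }
  invisible(dir)
}

#' Load a simulated dataset
#'
#' @param dir Dataset directory written by [simulate_cohort()].
#' @return An object of class `skinwave_dataset`: list with `design` (a
#'   [build_design()] pair), `cohort`, `config`, `records` and `failed`
#'   (subject ids without a record).
#' @export
load_dataset <- function(dir) {
  config <- read_run_config(file.path(dir, "config.yaml"))
  cohort <- read_cohort_csv(file.path(dir, "cohort.csv"))
  files <- vapply(cohort$subject_id, function(i) .subject_file(dir, i),
                  character(1))
  have <- file.exists(files)
  records <- lapply(files[have], readRDS)
  structure(list(design = build_design(records), cohort = cohort,
                 config = config, records = records,
                 failed = cohort$subject_id[!have]),
            class = "skinwave_dataset")
}

#' @export
print.skinwave_dataset <- function(x, ...) {
  cat(sprintf("skinwave_dataset: %d subjects (%d missing), X %d x %d, Y %d x %d\n",
              length(x$records), length(x$failed),
              nrow(x$design$X), ncol(x$design$X),
              nrow(x$design$Y), ncol(x$design$Y)))
  invisible(x)
}

#' Train the surrogate on a dataset
#'
#' Runs the repeated k-fold cross-validation over the candidate
#' architectures, then fits the selected architecture on the full dataset.
#'
#' @param dataset A `skinwave_dataset` (or dataset directory).
#' @param architectures Candidate hidden-layer width lists; default is the
#'   configured architecture only.
#' @param config Optional override of the dataset's configuration.
#' @return List with `model` (a `skinwave_mlp`), `cv` (a `cv_report`) and
#'   `summary`.
#' @export
train_surrogate <- function(dataset, architectures = NULL, config = NULL) {
  if (is.character(dataset)) dataset <- load_dataset(dataset)
  cfg <- if (is.null(config)) dataset$config else config
  if (is.null(architectures)) architectures <- list(cfg$hidden)
  cv <- cross_validate(dataset$design, architectures = architectures,
                       folds = cfg$folds, repeats = cfg$repeats,
                       base_seed = cfg$seed, epochs = cfg$epochs,
                       batch = cfg$batch, lr = cfg$lr,
                       val_frac = cfg$val_frac, patience = cfg$patience)
  model <- fit_surrogate(dataset$design$X, dataset$design$Y,
                         hidden = cfg$hidden, seed = cfg$seed,
                         epochs = cfg$epochs, batch = cfg$batch,
                         lr = cfg$lr, val_frac = cfg$val_frac,
                         patience = cfg$patience)
  model$config_hash <- config_hash(cfg)
  list(model = model, cv = cv, summary = summary(cv))
}

#' Predict subject properties from a waveform triple
#'
#' Applies the trained surrogate to one subject's three waveforms and
#' unpacks the 28 outputs: the 5 x 5 day-7 growth grid, `mu`, `k` and
#' `theta_nat`, plus the extra grown area implied by the predicted grid.
#'
#' @param model A `skinwave_mlp`.
#' @param waveforms Either a named list of three `waveform`s (`baseline`,
#'   `day0`, `day3p5`; raw waveforms are resampled first) or a numeric
#'   vector/1-row matrix already on the 3003-column input layout.
#' @param dims Quarter-model in-plane extents, mm (for the area metric).
#' @return List with `growth_grid`, `mu`, `k`, `theta_nat`, `extra_area`.
#' @export
predict_subject <- function(model, waveforms, dims = c(50, 37.5)) {
  stopifnot(inherits(model, "skinwave_mlp"))
  p <- length(model$scaler_x$center)
  n_s <- p / 3L
  if (inherits(waveforms, "waveform"))
    stop("supply all three waveforms (baseline, day0, day3p5)")
  if (is.list(waveforms) && !is.null(waveforms$baseline)) {
    ws <- lapply(waveforms[c("baseline", "day0", "day3p5")], function(w) {
      if (length(w$times) != n_s || !isTRUE(w$resampled))
        w <- resample_waveform(w, n = n_s)
      w
    })
    x <- c(ws$baseline$normal_displacement, ws$day0$normal_displacement,
           ws$day3p5$normal_displacement)
  } else {
    x <- as.numeric(waveforms)
  }
  if (length(x) != p) stop("expected ", p, " input values")
  y <- predict(model, matrix(x, nrow = 1L))[1, ]
  ng <- length(y) - 3L
  side <- as.integer(round(sqrt(ng)))
  grid <- matrix(y[seq_len(ng)], side, side)
  list(growth_grid = grid,
       mu = unname(y["mu"]), k = unname(y["k"]),
       theta_nat = unname(y["theta_nat"]),
       extra_area = grid_extra_area(grid, dims))
}
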