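#' Labelled multichannel trial container
#'
#' The universal input of the package: a list of epoched trials (electrodes
#' by samples matrices, equal dimensions), one class label per trial, and a
#' sampling rate.
#'
#' @param trials list of numeric matrices, all `ne x nt`.
#' @param labels factor (or coercible) of class labels, one per trial.
#' @param fs sampling rate in Hz.
#' @return object of class `trial_set`.
#' @export
trial_set <- function(trials, labels, fs) {
  labels <- as.factor(labels)
  if (length(trials) != length(labels)) stop("one label per trial", call. = FALSE)
  dims <- unique(t(vapply(trials, dim, integer(2))))
  if (nrow(dims) != 1) stop("all trials must share dimensions", call. = FALSE)
  if (!all(vapply(trials, function(x) all(is.finite(x)), logical(1)))) {
    stop("trials contain non-finite values", call. = FALSE)
  }
  structure(list(trials = trials, labels = labels, fs = fs,
                 ne = dims[1, 1], nt = dims[1, 2]),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials, %d electrodes x %d samples @ %g Hz\n",
              length(x$trials), x$ne, x$nt, x$fs))
  print(table(x$labels))
  invisible(x)
}

#' @export
length.trial_set <- function(x) length(x$trials)

# Subset a trial_set by trial index.
ts_subset <- function(ts, idx) {
  trial_set(ts$trials[idx], droplevels(ts$labels[idx]), ts$fs)
}

#' Stratified train/test split of a trial set
#'
#' @param ts a [trial_set()].
#' @param train_frac fraction of each class assigned to training.
#' @param seed integer seed for the shuffle.
#' @return list with `train` and `test` trial sets.
#' @export
split_trials <- function(ts, train_frac = 0.75, seed = 1) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac in (0,1)", call. = FALSE)
  set.seed(seed)
  tr <- unlist(lapply(levels(ts$labels), function(cl) {
    idx <- which(ts$labels == cl)
    sample(idx, round(length(idx) * train_frac))
  }))
  list(train = ts_subset(ts, sort(tr)),
       test = ts_subset(ts, setdiff(seq_along(ts$trials), tr)))
}

# Coloured 1/f^a noise with a white floor, unit variance.
colored_noise <- function(nt, fs, exponent = 1, floor_db = -20) {
  x <- rnorm(nt)
  f <- seq(0, fs - fs / nt, length.out = nt)
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  p <- pmax(f, fs / nt)^(-exponent) + 10^(floor_db / 10)
  y <- Re(stats::fft(stats::fft(x) * sqrt(p), inverse = TRUE)) / nt
  as.numeric(scale(y))
}

# Random-phase narrowband oscillation: white noise masked to [lo, hi] Hz in
# the frequency domain, unit variance. Covariance, not phase, carries the
# class signal.
narrowband_noise <- function(nt, fs, lo, hi) {
  x <- rnorm(nt)
  X <- stats::fft(x)
  f <- seq(0, fs - fs / nt, length.out = nt)
  f <- pmin(f, fs - f)
  X[f < lo | f > hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / nt
  as.numeric(scale(y))
}

#' Synthetic EEG cohort configuration
#'
#' Parameters of the generator: broadband 1/f-plus-white noise mixed across
#' electrodes, with class-specific narrowband oscillations planted at given
#' electrodes and bands. Defaults emulate a 4-class motor-task recording.
#'
#' @param ne electrodes. @param nt samples per trial. @param fs Hz.
#' @param n_classes number of classes.
#' @param n_trials_per_class trials per class.
#' @param planted_bands list of length `n_classes`; element `k` is a list of
#'   records `list(electrodes =, band = c(lo, hi), power =)` planted for
#'   class `k` (may be empty).
#' @param snr amplitude of planted oscillations relative to the unit-variance
#'   background noise (0 disables them).
#' @param noise_exponent 1/f exponent of the background (default 1).
#' @param floor_db white-noise floor relative to the 1 Hz power (default -20).
#' @param mixing electrode correlation matrix (symmetric PD, `ne x ne`), or
#'   `NULL` for an AR(1)-style default with neighbour correlation 0.3.
#' @param seed integer seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(ne = 8, nt = 400, fs = 200, n_classes = 4,
                         n_trials_per_class = 40, planted_bands = NULL,
                         snr = 4, noise_exponent = 1, floor_db = -20,
                         mixing = NULL, seed = 1) {
  if (is.null(mixing)) mixing <- 0.3^abs(outer(1:ne, 1:ne, "-"))
  if (!isSymmetric(mixing) ||
      min(eigen(mixing, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("mixing must be symmetric positive definite", call. = FALSE)
  }
  if (snr < 0) stop("snr must be >= 0", call. = FALSE)
  if (is.null(planted_bands)) {
    planted_bands <- default_bands(ne, fs, n_classes)
  }
  for (cls in planted_bands) {
    for (rec in cls) {
      if (rec$band[1] <= 0 || rec$band[2] >= fs / 2 || rec$band[1] >= rec$band[2]) {
        stop("planted band outside (0, fs/2)", call. = FALSE)
      }
      if (any(rec$electrodes > ne)) stop("planted electrode out of range", call. = FALSE)
    }
  }
  structure(list(ne = ne, nt = nt, fs = fs, n_classes = n_classes,
                 n_trials_per_class = n_trials_per_class,
                 planted_bands = planted_bands, snr = snr,
                 noise_exponent = noise_exponent, floor_db = floor_db,
                 mixing = mixing, seed = seed),
            class = "synth_config")
}

# Disjoint canonical bands (alpha, beta, low-gamma, high-gamma) at distinct
# electrode pairs, as far as fs allows.
default_bands <- function(ne, fs, n_classes) {
  bands <- list(c(8, 13), c(13, 30), c(35, 50), c(60, 90))
  bands <- lapply(bands, function(b) pmin(b, fs / 2 - 1))
  lapply(seq_len(n_classes), function(k) {
    els <- ((k - 1) * 2) %% ne + 1:2
    els <- ((els - 1) %% ne) + 1
    list(list(electrodes = els, band = bands[[(k - 1) %% 4 + 1]], power = 1))
  })
}

#' Generate a synthetic trial cohort
#'
#' Each trial is spatially mixed 1/f-plus-white background noise; the
#' trial's class adds narrowband random-phase oscillations at its planted
#' electrodes and bands, scaled by `snr`. Classes are balanced and the
#' output is fully determined by `config$seed`.
#'
#' @param config a [synth_config()].
#' @return a [trial_set()].
#' @export
generate_trials <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  Mh <- chol(config$mixing)
  trials <- list()
  labels <- integer(0)
  for (k in seq_len(config$n_classes)) {
    for (i in seq_len(config$n_trials_per_class)) {
      noise <- t(vapply(seq_len(config$ne), function(e) {
        colored_noise(config$nt, config$fs, config$noise_exponent,
                      config$floor_db)
      }, numeric(config$nt)))
      X <- t(Mh) %*% noise
      if (config$snr > 0) {
        for (rec in config$planted_bands[[k]]) {
          for (e in rec$electrodes) {
            X[e, ] <- X[e, ] + config$snr * rec$power *
              narrowband_noise(config$nt, config$fs, rec$band[1], rec$band[2])
          }
        }
      }
      trials[[length(trials) + 1]] <- X
      labels <- c(labels, k)
    }
  }
  # interleave classes so contiguous batches are roughly balanced
  ord <- order(rep(seq_len(config$n_trials_per_class), config$n_classes))
  trial_set(trials[ord], factor(labels[ord]), config$fs)
}

#' Canonical test fixtures
#'
#' Named cohorts with known ground truth:
#' \describe{
#'   \item{easy4}{4 classes, disjoint alpha/beta/low-gamma/high-gamma bands
#'     at distinct electrode pairs, high snr.}
#'   \item{hard4}{overlapping bands, low snr.}
#'   \item{singleband}{one informative 10-20 Hz band; classes differ only in
#'     which electrode carries the band power (filterbank recovery target).}
#'   \item{multiband}{2 classes; class power lives in two disjoint bands
#'     (8-14 and 40-50 Hz) at class-specific electrodes, so a single optimal
#'     filter must pass both bands.}
#' }
#'
#' @param name fixture name.
#' @param seed integer seed.
#' @param n_trials_per_class trials per class (fixture default if NULL).
#' @return list with `trials` (a [trial_set()]) and `truth` (list of planted
#'   band/electrode records).
#' @export
make_fixture <- function(name = c("easy4", "hard4", "singleband", "multiband"),
                         seed = 1, n_trials_per_class = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    easy4 = synth_config(ne = 8, nt = 400, fs = 200, n_classes = 4,
                         n_trials_per_class = n_trials_per_class %||% 40,
                         snr = 4, seed = seed),
    hard4 = synth_config(ne = 8, nt = 400, fs = 200, n_classes = 4,
                         n_trials_per_class = n_trials_per_class %||% 40,
                         planted_bands = list(
                           list(list(electrodes = 1:2, band = c(8, 16), power = 1)),
                           list(list(electrodes = 2:3, band = c(12, 22), power = 1)),
                           list(list(electrodes = 3:4, band = c(18, 30), power = 1)),
                           list(list(electrodes = 4:5, band = c(25, 40), power = 1))),
                         snr = 1, seed = seed),
    singleband = synth_config(ne = 4, nt = 256, fs = 128, n_classes = 4,
                              n_trials_per_class = n_trials_per_class %||% 25,
                              planted_bands = lapply(1:4, function(k) {
                                list(list(electrodes = k, band = c(10, 20), power = 1))
                              }),
                              snr = 4, seed = seed),
    multiband = synth_config(ne = 4, nt = 256, fs = 128, n_classes = 2,
                             n_trials_per_class = n_trials_per_class %||% 40,
                             planted_bands = list(
                               list(list(electrodes = 1:2, band = c(8, 14), power = 1),
                                    list(electrodes = 1:2, band = c(40, 50), power = 1)),
                               list()),
                             snr = 4, seed = seed)
  )
  truth <- switch(name,
    singleband = list(band = c(10, 20), electrodes = 1:4),
    multiband = list(bands = list(c(8, 14), c(40, 50)), electrodes = 1:2),
    easy4 = cfg$planted_bands,
    hard4 = cfg$planted_bands
  )
  list(trials = generate_trials(cfg), truth = truth, config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write trial sets as plain text
#'
#' Serialises a trial set to a directory holding one CSV of stacked trial
#' rows plus a JSON header (labels, fs, dimensions).
#'
#' @param ts a [trial_set()].
#' @param dir directory to create/read.
#' @return `read_trials()` returns a [trial_set()]; `write_trials()` the
#'   directory path, invisibly.
#' @export
write_trials <- function(ts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  X <- do.call(rbind, ts$trials)
  utils::write.table(X, file.path(dir, "data.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(labels = as.character(ts$labels), fs = ts$fs, ne = ts$ne, nt = ts$nt),
    file.path(dir, "header.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_trials
#' @export
read_trials <- function(dir) {
  h <- jsonlite::read_json(file.path(dir, "header.json"), simplifyVector = TRUE)
  X <- as.matrix(utils::read.table(file.path(dir, "data.csv"), sep = ","))
  trials <- lapply(seq_along(h$labels), function(i) {
    unname(X[(i - 1) * h$ne + seq_len(h$ne), , drop = FALSE])
  })
  trial_set(trials, h$labels, h$fs)
}
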