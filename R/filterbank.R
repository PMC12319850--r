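# Default kernel length: ~250 ms of signal, rounded to the nearest odd
# integer so sinc kernels can be exactly symmetric (linear phase).
default_kernel_len <- function(fs) {
  k <- round(fs / 4)
  if (k %% 2 == 0) k <- k + 1
  max(k, 3L)
}

#' Windowed sinc bandpass kernel
#'
#' Builds a linear-phase FIR bandpass kernel as a difference of two windowed
#' sinc low-pass kernels (high cutoff minus low cutoff), following the
#' SincNet construction. `low = 0` degenerates to a pure low-pass. The
#' kernel is exactly symmetric about its centre and its DFT magnitude is
#' close to 1 inside `(low, high)` and close to 0 outside the transition
#' bands.
#'
#' @param low,high cutoff frequencies in Hz, `0 <= low < high <= fs/2`.
#' @param kernel_len odd kernel length in samples.
#' @param fs sampling rate in Hz.
#' @param window `"hamming"` (default) or `"rect"`.
#' @return numeric vector of length `kernel_len`.
#' @export
sinc_kernel <- function(low, high, kernel_len, fs, window = "hamming") {
  if (kernel_len %% 2 == 0) stop("kernel_len must be odd", call. = FALSE)
  if (low < 0 || high > fs / 2 || low >= high) {
    stop("need 0 <= low < high <= fs/2", call. = FALSE)
  }
  tt <- seq_len(kernel_len) - (kernel_len + 1) / 2  # centred sample offsets
  f1 <- low / fs
  f2 <- high / fs
  # sin(2 pi f t) / (pi t), continued to 2f at t = 0
  lp <- function(f) ifelse(tt == 0, 2 * f, sin(2 * pi * f * tt) / (pi * tt))
  w <- switch(window,
    hamming = 0.54 - 0.46 * cos(2 * pi * (seq_len(kernel_len) - 1) / (kernel_len - 1)),
    rect = rep(1, kernel_len),
    stop("unknown window", call. = FALSE)
  )
  (lp(f2) - lp(f1)) * w
}

# Partial derivatives of the sinc kernel w.r.t. the two cutoffs (Hz):
# d/df [sin(2 pi f t)/(pi t)] = 2 cos(2 pi f t); at t = 0 this is 2.
sinc_kernel_grad <- function(low, high, kernel_len, fs, window = "hamming") {
  tt <- seq_len(kernel_len) - (kernel_len + 1) / 2
  w <- switch(window,
    hamming = 0.54 - 0.46 * cos(2 * pi * (seq_len(kernel_len) - 1) / (kernel_len - 1)),
    rect = rep(1, kernel_len)
  )
  list(
    d_low  = -2 * cos(2 * pi * (low / fs) * tt) * w / fs,
    d_high =  2 * cos(2 * pi * (high / fs) * tt) * w / fs
  )
}

#' Filterbank specification
#'
#' Describes the temporal filtering front-end: either free convolutional
#' kernels (`kind = "conv"`) or sinc-parameterised bandpass filters
#' (`kind = "sinc"`), applied channel-independently (every filter to every
#' electrode) or channel-specifically (one filter per electrode per width
#' unit). A ChInd bank holds `nf` filter units; a ChSpec bank holds
#' `nf * ne` units. Both produce `nf * ne` output rows, so downstream layer
#' sizes do not depend on specificity.
#'
#' @param kind `"conv"` or `"sinc"`.
#' @param nf width: filters per electrode duplication (>= 1).
#' @param ne electrode count.
#' @param fs sampling rate, Hz.
#' @param specificity `"chind"` or `"chspec"`.
#' @param kernel_len odd kernel length in samples; default `fs/4` rounded
#'   to odd.
#' @param cutoffs sinc only: matrix with columns `low`, `high` (Hz), one row
#'   per filter unit.
#' @param kernels conv only: `kernel_len x n_units` matrix of kernel taps.
#' @param window sinc window (see [sinc_kernel()]).
#' @return object of class `filterbank_spec`.
#' @export
filterbank_spec <- function(kind = c("sinc", "conv"), nf, ne, fs,
                            specificity = c("chind", "chspec"),
                            kernel_len = NULL, cutoffs = NULL, kernels = NULL,
                            window = "hamming") {
  kind <- match.arg(kind)
  specificity <- match.arg(specificity)
  if (nf < 1) stop("nf must be >= 1", call. = FALSE)
  if (is.null(kernel_len)) kernel_len <- default_kernel_len(fs)
  if (kernel_len %% 2 == 0) stop("kernel_len must be odd", call. = FALSE)
  n_units <- if (specificity == "chind") nf else nf * ne
  if (kind == "sinc") {
    if (is.null(cutoffs)) stop("sinc spec needs `cutoffs`", call. = FALSE)
    cutoffs <- as.matrix(cutoffs)
    if (nrow(cutoffs) != n_units || ncol(cutoffs) != 2) {
      stop(sprintf("`cutoffs` must be a %d x 2 matrix (low, high)", n_units),
           call. = FALSE)
    }
    if (any(cutoffs[, 1] < 0) || any(cutoffs[, 2] > fs / 2) ||
        any(cutoffs[, 1] >= cutoffs[, 2])) {
      stop("each cutoff pair needs 0 <= low < high <= fs/2", call. = FALSE)
    }
  } else {
    if (is.null(kernels) || nrow(kernels) != kernel_len ||
        ncol(kernels) != n_units) {
      stop(sprintf("`kernels` must be %d x %d", kernel_len, n_units),
           call. = FALSE)
    }
  }
  structure(list(kind = kind, nf = nf, ne = ne, fs = fs,
                 specificity = specificity, kernel_len = kernel_len,
                 cutoffs = cutoffs, kernels = kernels, window = window),
            class = "filterbank_spec")
}

# Materialise the kernel_len x n_units kernel matrix of a spec.
spec_kernels <- function(spec) {
  if (spec$kind == "conv") return(spec$kernels)
  vapply(seq_len(nrow(spec$cutoffs)), function(u) {
    sinc_kernel(spec$cutoffs[u, 1], spec$cutoffs[u, 2], spec$kernel_len,
                spec$fs, spec$window)
  }, numeric(spec$kernel_len))
}

# Valid (no-padding) FIR filtering of every row of X with kernel k:
# out[, t] = sum_j k[j] * X[, t + j - 1].  Kernels here are either learned
# (orientation is immaterial) or symmetric sinc kernels, so this equals
# convolution with the flipped kernel.
conv_valid <- function(X, k) {
  nt <- ncol(X)
  kl <- length(k)
  ntp <- nt - kl + 1
  if (ntp < 2) stop("trial shorter than kernel", call. = FALSE)
  out <- matrix(0, nrow(X), ntp)
  for (j in seq_len(kl)) {
    out <- out + k[j] * X[, j:(j + ntp - 1), drop = FALSE]
  }
  out
}

#' Apply a filterbank to a trial
#'
#' Filters a channels-by-samples trial with every unit of the bank. Output
#' rows are ordered band-major: all electrodes of filter 1, then filter 2,
#' and so on — row `(f-1)*ne + e` is electrode `e` under filter `f`.
#' Channel-independent banks apply each filter to all electrodes;
#' channel-specific banks apply unit `(f, e)` only to electrode `e`.
#'
#' @param trial numeric matrix (`ne` x `nt`).
#' @param spec a [filterbank_spec()].
#' @return numeric matrix (`nf*ne` x `nt - kernel_len + 1`) with attributes
#'   `band_of_row` and `electrode_of_row`.
#' @export
filterbank_forward <- function(trial, spec) {
  ne <- spec$ne
  if (nrow(trial) != ne) stop("trial electrode count does not match spec", call. = FALSE)
  K <- spec_kernels(spec)
  ntp <- ncol(trial) - spec$kernel_len + 1
  if (ntp < 2) stop("trial shorter than kernel", call. = FALSE)
  out <- matrix(0, spec$nf * ne, ntp)
  for (f in seq_len(spec$nf)) {
    rows <- (f - 1) * ne + seq_len(ne)
    if (spec$specificity == "chind") {
      out[rows, ] <- conv_valid(trial, K[, f])
    } else {
      for (e in seq_len(ne)) {
        u <- (f - 1) * ne + e
        out[rows[e], ] <- conv_valid(trial[e, , drop = FALSE], K[, u])
      }
    }
  }
  attr(out, "band_of_row") <- rep(seq_len(spec$nf), each = ne)
  attr(out, "electrode_of_row") <- rep(seq_len(ne), times = spec$nf)
  out
}

#' Covariance pooling of a filtered trial
#'
#' Turns the band-major filtered time series into a single covariance
#' matrix. Channel-specific banks (and channel-independent banks keeping
#' interband covariance) use the full SCM over all `nf*ne` rows; a
#' channel-independent bank without interband covariance gets the
#' block-diagonal concatenation of per-band SCMs (off-diagonal blocks
#' exactly zero).
#'
#' @param filtered output of [filterbank_forward()].
#' @param nf width of the bank that produced it.
#' @param specificity `"chind"` or `"chspec"`.
#' @param keep_interband keep cross-band covariance blocks? (Only
#'   meaningful for ChInd with `nf > 1`; ChSpec always keeps them.)
#' @param center passed to [scm()].
#' @return covariance matrix of dimension `nf*ne`.
#' @export
scm_pool <- function(filtered, nf, specificity = c("chind", "chspec"),
                     keep_interband = TRUE, center = TRUE) {
  specificity <- match.arg(specificity)
  ne <- nrow(filtered) / nf
  if (ne != round(ne)) stop("row count is not a multiple of nf", call. = FALSE)
  sizes <- rep(as.integer(ne), nf)
  keep <- keep_interband || specificity == "chspec" || nf == 1
  interband_scm(filtered, sizes, keep_interband = keep, center = center)
}

#' Serialise a filterbank spec to JSON
#'
#' @param spec a [filterbank_spec()].
#' @param path file path; conv kernels are embedded in the JSON.
#' @return `path`, invisibly. `read_filterbank_spec()` round-trips it.
#' @export
write_filterbank_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_filterbank_spec
#' @export
read_filterbank_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  filterbank_spec(kind = x$kind, nf = x$nf, ne = x$ne, fs = x$fs,
                  specificity = x$specificity, kernel_len = x$kernel_len,
                  cutoffs = if (!is.null(x$cutoffs)) matrix(unlist(x$cutoffs), ncol = 2),
                  kernels = if (!is.null(x$kernels)) matrix(unlist(x$kernels), nrow = x$kernel_len),
                  window = x$window)
}
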