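#' @importFrom stats rnorm runif median sd quantile predict
#' @importFrom utils head tail
NULL

# Relative asymmetry above this is treated as a real error, not noise.
.SYM_TOL <- 1e-8

#' Symmetrize a nearly-symmetric matrix
#'
#' Returns `(S + t(S)) / 2` after checking that the asymmetry is numerical
#' noise (relative magnitude below `tol`). Larger asymmetry is an error:
#' every consumer in this package expects genuinely symmetric input.
#'
#' @param S square numeric matrix.
#' @param tol maximum admissible relative asymmetry.
#' @return symmetric matrix.
#' @keywords internal
sym_part <- function(S, tol = .SYM_TOL) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    stop("`S` must be a square matrix", call. = FALSE)
  }
  if (!all(is.finite(S))) stop("`S` contains non-finite entries", call. = FALSE)
  denom <- max(abs(S), .Machine$double.eps)
  asym <- max(abs(S - t(S))) / denom
  if (asym > tol) {
    stop(sprintf("matrix is not symmetric (relative asymmetry %.3g)", asym),
         call. = FALSE)
  }
  (S + t(S)) / 2
}

# Symmetric eigendecomposition; values ascending flipped to descending is not
# needed -- consumers are spectral functions invariant to ordering/sign.
eig_sym <- function(S) eigen(sym_part(S), symmetric = TRUE)

#' Sample covariance matrix of a trial
#'
#' Computes the SCM `C = T T' / (Nt - 1)` of a channels-by-samples trial
#' matrix, optionally after per-channel mean removal. With `Nt > Ne` and
#' linearly independent rows the result is symmetric positive definite;
#' otherwise it is positive semi-definite and flagged via the `"psd"`
#' attribute so downstream code can regularise first.
#'
#' @param trial numeric matrix, channels (electrodes) in rows, time samples
#'   in columns.
#' @param center logical; subtract each channel's mean first (default TRUE).
#' @return symmetric PSD matrix with attribute `psd` (logical; TRUE when the
#'   matrix cannot be guaranteed strictly positive definite).
#' @examples
#' x <- matrix(rnorm(4 * 256), 4, 256)
#' C <- scm(x)
#' all(eigen(C, symmetric = TRUE, only.values = TRUE)$values > 0)
#' @export
scm <- function(trial, center = TRUE) {
  if (!is.matrix(trial)) trial <- matrix(trial, nrow = 1)
  if (!all(is.finite(trial))) stop("trial contains non-finite entries", call. = FALSE)
  nt <- ncol(trial)
  ne <- nrow(trial)
  if (nt < 2) stop("degenerate input: need at least 2 samples", call. = FALSE)
  if (center) trial <- trial - rowMeans(trial)
  C <- tcrossprod(trial) / (nt - 1)
  C <- (C + t(C)) / 2
  # strict PD only guaranteed for Nt > Ne and full-rank rows; cheap rank proxy
  ev_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  attr(C, "psd") <- !(nt > ne && ev_min > ne * max(diag(C), 1) * .Machine$double.eps)
  C
}

# Apply a scalar spectral function g to a symmetric matrix: U g(lambda) U'.
spectral_apply <- function(S, g) {
  e <- eig_sym(S)
  out <- e$vectors %*% (g(e$values) * t(e$vectors))
  (out + t(out)) / 2
}

#' Eigenvalue rectification (ReEig)
#'
#' Floors the spectrum of a symmetric matrix at `eps`:
#' `U max(eps I, Sigma) U'`. This is the SPD-manifold analogue of the ReLU;
#' it also serves as the package's regulariser, turning any PSD matrix into
#' a strictly positive definite one. Idempotent.
#'
#' @param S symmetric matrix.
#' @param eps rectification threshold (default `1e-4`).
#' @return SPD matrix with all eigenvalues `>= eps`.
#' @export
reeig_rectify <- function(S, eps = 1e-4) {
  out <- spectral_apply(S, function(l) pmax(l, eps))
  attr(out, "psd") <- FALSE
  out
}

#' @rdname reeig_rectify
#' @export
regularize_spd <- reeig_rectify

#' Matrix logarithm of an SPD matrix (LogEig)
#'
#' `U log(Sigma) U'` from a symmetric eigendecomposition. Maps the SPD cone
#' to the space of symmetric matrices; `expm_spd()` inverts it.
#'
#' @param S strictly positive definite symmetric matrix.
#' @return symmetric matrix.
#' @export
logeig_map <- function(S) {
  e <- eig_sym(S)
  if (any(e$values <= 0)) {
    stop("matrix is not positive definite; regularise first (see reeig_rectify)",
         call. = FALSE)
  }
  out <- e$vectors %*% (log(e$values) * t(e$vectors))
  (out + t(out)) / 2
}

#' @rdname logeig_map
#' @export
expm_spd <- function(S) spectral_apply(S, exp)

# Fractional powers used by the AIRM machinery.
powm_spd <- function(S, p) {
  e <- eig_sym(S)
  if (any(e$values <= 0) && p < 0) stop("matrix is singular", call. = FALSE)
  out <- e$vectors %*% (e$values^p * t(e$vectors))
  (out + t(out)) / 2
}

#' Norm-preserving half-vectorisation
#'
#' Stacks the unique elements of a symmetric `n x n` matrix into a vector of
#' length `n (n + 1) / 2`, multiplying off-diagonal entries by `sqrt(2)` so
#' the Euclidean norm of the vector equals the Frobenius norm of the matrix.
#' Elements are taken column-wise from the upper triangle
#' (`S11, sqrt(2) S12, S22, sqrt(2) S13, ...`).
#'
#' @param S symmetric matrix.
#' @return numeric vector of length `n (n + 1) / 2`.
#' @export
vect_spd <- function(S) {
  S <- sym_part(S)
  n <- nrow(S)
  idx <- upper.tri(S, diag = TRUE)
  w <- matrix(sqrt(2), n, n)
  diag(w) <- 1
  (S * w)[idx]
}

# Inverse map: vector of length n(n+1)/2 back to the symmetric matrix.
unvect_spd <- function(v) {
  n <- (sqrt(8 * length(v) + 1) - 1) / 2
  if (abs(n - round(n)) > 1e-8) stop("length is not n(n+1)/2", call. = FALSE)
  n <- round(n)
  S <- matrix(0, n, n)
  S[upper.tri(S, diag = TRUE)] <- v
  w <- matrix(1 / sqrt(2), n, n)
  diag(w) <- 1
  S <- S * w
  S + t(S) - diag(diag(S), n)
}

#' Block-diagonal concatenation of SPD matrices
#'
#' Concatenates SPD matrices into one larger block-diagonal SPD matrix; its
#' eigenvalue multiset is the union of the blocks' multisets. Used to merge
#' per-band covariance matrices of a channel-independent filterbank into a
#' single matrix without cross-band terms.
#'
#' @param blocks list of symmetric PD matrices.
#' @return block-diagonal matrix with attribute `block_sizes`.
#' @export
conc_spd <- function(blocks) {
  if (!is.list(blocks) || length(blocks) == 0) {
    stop("`blocks` must be a non-empty list of matrices", call. = FALSE)
  }
  sizes <- vapply(blocks, function(b) {
    if (!is.matrix(b) || nrow(b) != ncol(b)) stop("blocks must be square", call. = FALSE)
    nrow(b)
  }, integer(1))
  n <- sum(sizes)
  out <- matrix(0, n, n)
  off <- 0L
  for (b in blocks) {
    k <- nrow(b)
    out[off + seq_len(k), off + seq_len(k)] <- sym_part(b)
    off <- off + k
  }
  attr(out, "block_sizes") <- sizes
  out
}

# Zero the off-diagonal blocks of a matrix partitioned by block_sizes.
zero_offdiag_blocks <- function(S, block_sizes) {
  stopifnot(sum(block_sizes) == nrow(S))
  mask <- matrix(0, nrow(S), ncol(S))
  off <- 0L
  for (k in block_sizes) {
    mask[off + seq_len(k), off + seq_len(k)] <- 1
    off <- off + k
  }
  out <- S * mask
  attr(out, "block_sizes") <- block_sizes
  out
}

#' Covariance of band-stacked signals, with or without interband blocks
#'
#' For a trial whose rows are stacked band-major (all electrodes of band 1,
#' then band 2, ...), computes the full covariance of the stack. The
#' off-diagonal blocks hold the interband covariance -- covariance between
#' electrodes of *different* frequency bands. With `keep_interband = FALSE`
#' those blocks are zeroed, which is exactly the block-diagonal
#' concatenation of the per-band SCMs.
#'
#' @param stacked numeric matrix, `(bands x electrodes)` rows by samples.
#' @param block_sizes integer vector of per-band row counts (must sum to
#'   `nrow(stacked)`).
#' @param keep_interband keep the cross-band covariance blocks?
#' @param center passed to [scm()].
#' @return covariance matrix with attribute `block_sizes`.
#' @export
interband_scm <- function(stacked, block_sizes, keep_interband = TRUE,
                          center = TRUE) {
  if (sum(block_sizes) != nrow(stacked)) {
    stop("block structure inconsistent with row count", call. = FALSE)
  }
  C <- scm(stacked, center = center)
  psd <- attr(C, "psd")
  if (!keep_interband) C <- zero_offdiag_blocks(C, block_sizes)
  attr(C, "block_sizes") <- block_sizes
  attr(C, "psd") <- psd
  C
}

# Random SPD matrix helper used across tests and fixtures.
rand_spd <- function(n, spread = 1) {
  A <- matrix(rnorm(n * n), n, n)
  Q <- qr.Q(qr(A))
  lam <- exp(spread * rnorm(n))
  S <- Q %*% (lam * t(Q))
  (S + t(S)) / 2
}
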