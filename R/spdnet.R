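#' Network architecture configuration
#'
#' Hyperparameters of an end-to-end SPDNet: a learnable filterbank
#' front-end (conv or sinc, channel-independent or channel-specific),
#' covariance pooling, `n_bire` BiMap-ReEig pairs with successive
#' floor-halving of the matrix dimension, then LogEig, norm-preserving
#' vectorisation, and an affine classifier head.
#'
#' @param ne electrode count.
#' @param n_classes number of classes.
#' @param fs sampling rate, Hz.
#' @param nf width: filters per electrode duplication.
#' @param n_bire depth: number of BiMap-ReEig pairs (default 3).
#' @param kind `"conv"` or `"sinc"` filter front-end.
#' @param specificity `"chind"` or `"chspec"`.
#' @param keep_interband keep cross-band covariance blocks (ChInd only).
#' @param reeig_eps ReEig rectification threshold (default 1e-4).
#' @param kernel_len odd kernel length; default `fs/4` rounded to odd.
#' @param window sinc window.
#' @param seed integer seed for parameter initialisation.
#' @return object of class `network_config`.
#' @export
network_config <- function(ne, n_classes, fs, nf = 1, n_bire = 3,
                           kind = c("conv", "sinc"),
                           specificity = c("chind", "chspec"),
                           keep_interband = TRUE, reeig_eps = 1e-4,
                           kernel_len = NULL, window = "hamming", seed = 1) {
  kind <- match.arg(kind)
  specificity <- match.arg(specificity)
  if (n_bire < 0) stop("n_bire must be >= 0", call. = FALSE)
  if (is.null(kernel_len)) kernel_len <- default_kernel_len(fs)
  cfg <- structure(list(ne = ne, n_classes = n_classes, fs = fs, nf = nf,
                        n_bire = n_bire, kind = kind,
                        specificity = specificity,
                        keep_interband = keep_interband,
                        reeig_eps = reeig_eps, kernel_len = kernel_len,
                        window = window, seed = seed),
                   class = "network_config")
  layer_widths(cfg)  # validates that no width collapses to zero
  cfg
}

#' Layer widths implied by a configuration
#'
#' The pooled covariance has dimension `nf * ne`; each BiMap halves it
#' (floor division for odd widths).
#'
#' @param config a [network_config()].
#' @return integer vector of length `n_bire + 1`.
#' @export
layer_widths <- function(config) {
  w <- config$nf * config$ne
  widths <- w
  for (k in seq_len(config$n_bire)) {
    w <- w %/% 2
    if (w < 1) stop("layer width collapsed to zero; reduce n_bire", call. = FALSE)
    widths <- c(widths, w)
  }
  as.integer(widths)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(y)))

# Map raw sinc parameters (a, b) to clamped cutoffs in Hz.
# low = softplus(a) clamped below nyq - 2; high = low + 1 + softplus(b)
# clamped at nyq. The clamps zero the corresponding gradient.
sinc_cutoffs <- function(a, b, fs) {
  nyq <- fs / 2
  low_raw <- softplus(a)
  low <- pmin(low_raw, nyq - 2)
  high_raw <- low + 1 + softplus(b)
  high <- pmin(high_raw, nyq)
  list(low = low, high = high,
       dlow_da = ifelse(low_raw < nyq - 2, 1 / (1 + exp(-a)), 0),
       dhigh_db = ifelse(high_raw < nyq, 1 / (1 + exp(-b)), 0),
       dhigh_dlow = ifelse(high_raw < nyq, 1, 0))
}

n_filter_units <- function(config) {
  if (config$specificity == "chind") config$nf else config$nf * config$ne
}

#' Initialise an end-to-end SPDNet
#'
#' Conv kernels start as zero-mean Gaussians scaled by `1/sqrt(kernel_len)`;
#' sinc cutoffs tile `(1, fs/2 - 1)` with contiguous bands; BiMap weights
#' are orthonormalised Gaussian matrices (QR); the affine head starts near
#' zero. All draws are governed by `config$seed`.
#'
#' @param config a [network_config()].
#' @return object of class `spdnet_model`.
#' @export
spdnet_init <- function(config) {
  set.seed(config$seed)
  nu <- n_filter_units(config)
  params <- list()
  if (config$kind == "conv") {
    params$kernels <- matrix(rnorm(config$kernel_len * nu) / sqrt(config$kernel_len),
                             config$kernel_len, nu)
  } else {
    nyq <- config$fs / 2
    f_of_u <- if (config$specificity == "chind") seq_len(nu) else
      (seq_len(nu) - 1) %/% config$ne + 1
    width <- (nyq - 2) / config$nf
    lows <- 1 + (f_of_u - 1) * width
    bws <- rep(pmax(width - 1, 1), nu)
    params$sinc_a <- softplus_inv(lows)
    params$sinc_b <- softplus_inv(bws)
  }
  widths <- layer_widths(config)
  params$W <- lapply(seq_len(config$n_bire), function(k) {
    A <- matrix(rnorm(widths[k] * widths[k + 1]), widths[k], widths[k + 1])
    qr.Q(qr(A))
  })
  d_vec <- widths[length(widths)] * (widths[length(widths)] + 1) / 2
  params$A <- matrix(0.01 * rnorm(config$n_classes * d_vec),
                     config$n_classes, d_vec)
  params$b <- rep(0, config$n_classes)
  structure(list(config = config, params = params, levels = NULL,
                 history = NULL),
            class = "spdnet_model")
}

#' @export
print.spdnet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<spdnet_model> %s/%s nf=%d n_bire=%d widths=%s classes=%d%s\n",
              cfg$kind, cfg$specificity, cfg$nf, cfg$n_bire,
              paste(layer_widths(cfg), collapse = "-"), cfg$n_classes,
              if (is.null(x$history)) " (untrained)" else
                sprintf(" (trained, %d epochs)", nrow(x$history))))
  invisible(x)
}

# Current kernel matrix (kernel_len x n_units) of a model.
model_kernels <- function(model) {
  cfg <- model$config
  if (cfg$kind == "conv") return(model$params$kernels)
  co <- sinc_cutoffs(model$params$sinc_a, model$params$sinc_b, cfg$fs)
  vapply(seq_along(co$low), function(u) {
    sinc_kernel(co$low[u], co$high[u], cfg$kernel_len, cfg$fs, cfg$window)
  }, numeric(cfg$kernel_len))
}

# The model's filterbank as a filterbank_spec (static snapshot).
model_filterbank <- function(model) {
  cfg <- model$config
  if (cfg$kind == "conv") {
    filterbank_spec("conv", cfg$nf, cfg$ne, cfg$fs, cfg$specificity,
                    cfg$kernel_len, kernels = model$params$kernels,
                    window = cfg$window)
  } else {
    co <- sinc_cutoffs(model$params$sinc_a, model$params$sinc_b, cfg$fs)
    filterbank_spec("sinc", cfg$nf, cfg$ne, cfg$fs, cfg$specificity,
                    cfg$kernel_len, cutoffs = cbind(co$low, co$high),
                    window = cfg$window)
  }
}

#' Bilinear SPD mapping (BiMap)
#'
#' `W' S W` with `W` on the Stiefel manifold (orthonormal columns), so a PD
#' input stays PD.
#'
#' @param S SPD matrix. @param W Stiefel weight (`d_in x d_out`).
#' @return SPD matrix of dimension `d_out`.
#' @export
bimap_forward <- function(S, W) {
  if (nrow(W) != nrow(S)) stop("dimension mismatch", call. = FALSE)
  M <- crossprod(W, S %*% W)
  (M + t(M)) / 2
}

# Daleckii-Krein backward through a spectral map U g(lambda) U'.
# e: eigen of the input; G: symmetric gradient w.r.t. the output.
spectral_backward <- function(e, G, g_vals, g_prime) {
  lam <- e$values
  n <- length(lam)
  D <- outer(lam, lam, "-")
  N <- outer(g_vals, g_vals, "-")
  close <- abs(D) < 1e-12 * max(abs(lam), 1)
  P <- matrix(0, n, n)
  P[!close] <- N[!close] / D[!close]
  Pd <- (outer(g_prime, g_prime, "+")) / 2
  P[close] <- Pd[close]
  Gt <- crossprod(e$vectors, G %*% e$vectors)
  dS <- e$vectors %*% ((P * Gt) %*% t(e$vectors))
  (dS + t(dS)) / 2
}

# Gradient matrix w.r.t. a symmetric L from the gradient of vect(L).
unvect_grad <- function(g, n) {
  G <- matrix(0, n, n)
  G[upper.tri(G, diag = TRUE)] <- g
  w <- matrix(1 / sqrt(2), n, n)
  diag(w) <- 1
  G <- G * w
  G + t(G) - diag(diag(G), n)
}

# Forward pass for one trial, keeping every intermediate needed by the
# backward pass.
forward_trial <- function(model, X, K = NULL) {
  cfg <- model$config
  p <- model$params
  if (is.null(K)) K <- model_kernels(model)
  ne <- cfg$ne
  ntp <- ncol(X) - cfg$kernel_len + 1
  if (ntp < 2) stop("trial shorter than kernel", call. = FALSE)
  Fm <- matrix(0, cfg$nf * ne, ntp)
  for (f in seq_len(cfg$nf)) {
    rows <- (f - 1) * ne + seq_len(ne)
    if (cfg$specificity == "chind") {
      Fm[rows, ] <- conv_valid(X, K[, f])
    } else {
      for (e in seq_len(ne)) {
        Fm[rows[e], ] <- conv_valid(X[e, , drop = FALSE], K[, (f - 1) * ne + e])
      }
    }
  }
  Fc <- Fm - rowMeans(Fm)
  C <- tcrossprod(Fc) / (ntp - 1)
  C <- (C + t(C)) / 2
  zero_blocks <- cfg$specificity == "chind" && !cfg$keep_interband && cfg$nf > 1
  if (zero_blocks) C <- zero_offdiag_blocks(C, rep(ne, cfg$nf))
  S <- C
  bimap_in <- vector("list", cfg$n_bire)
  reeig_eig <- vector("list", cfg$n_bire)
  stages <- list(pool = C)
  for (k in seq_len(cfg$n_bire)) {
    bimap_in[[k]] <- S
    S <- bimap_forward(S, p$W[[k]])
    stages[[paste0("bimap", k)]] <- S
    e <- eigen(S, symmetric = TRUE)
    reeig_eig[[k]] <- e
    S <- e$vectors %*% (pmax(e$values, cfg$reeig_eps) * t(e$vectors))
    S <- (S + t(S)) / 2
    stages[[paste0("reeig", k)]] <- S
  }
  le <- eigen(S, symmetric = TRUE)
  if (any(le$values <= 0)) {
    stop("non-PD matrix reached LogEig; with n_bire = 0 regularise the pool first",
         call. = FALSE)
  }
  L <- le$vectors %*% (log(le$values) * t(le$vectors))
  L <- (L + t(L)) / 2
  stages$logeig <- L
  v <- vect_spd(L)
  scores <- as.numeric(p$A %*% v + p$b)
  list(scores = scores, v = v, stages = stages,
       cache = list(X = X, Fc = Fc, ntp = ntp, zero_blocks = zero_blocks,
                    bimap_in = bimap_in, reeig_eig = reeig_eig,
                    logeig_eig = le))
}

# Backward pass for one trial; dscores is the gradient of the loss w.r.t.
# the raw scores. Returns gradients for every parameter plus the gradient
# at the pooled covariance (used by the relevance analysis).
backward_trial <- function(model, fwd, dscores, K = NULL) {
  cfg <- model$config
  p <- model$params
  if (is.null(K)) K <- model_kernels(model)
  ca <- fwd$cache
  ne <- cfg$ne
  dA <- outer(dscores, fwd$v)
  db <- dscores
  dv <- as.numeric(crossprod(p$A, dscores))
  d <- nrow(ca$logeig_eig$vectors)
  G <- unvect_grad(dv, d)
  G <- spectral_backward(ca$logeig_eig, G, log(ca$logeig_eig$values),
                         1 / ca$logeig_eig$values)
  dW <- vector("list", cfg$n_bire)
  for (k in rev(seq_len(cfg$n_bire))) {
    e <- ca$reeig_eig[[k]]
    G <- spectral_backward(e, G, pmax(e$values, cfg$reeig_eps),
                           as.numeric(e$values > cfg$reeig_eps))
    W <- p$W[[k]]
    S_in <- ca$bimap_in[[k]]
    dW[[k]] <- 2 * S_in %*% W %*% G
    G <- W %*% G %*% t(W)
  }
  if (ca$zero_blocks) G <- zero_offdiag_blocks(G, rep(ne, cfg$nf))
  dC <- G
  dFc <- 2 * (G %*% ca$Fc) / (ca$ntp - 1)
  dF <- dFc - rowMeans(dFc)
  # filter-kernel gradients
  kl <- cfg$kernel_len
  nu <- n_filter_units(cfg)
  dK <- matrix(0, kl, nu)
  X <- ca$X
  ntp <- ca$ntp
  for (f in seq_len(cfg$nf)) {
    rows <- (f - 1) * ne + seq_len(ne)
    dFf <- dF[rows, , drop = FALSE]
    if (cfg$specificity == "chind") {
      for (j in seq_len(kl)) {
        dK[j, f] <- sum(dFf * X[, j:(j + ntp - 1), drop = FALSE])
      }
    } else {
      for (e_i in seq_len(ne)) {
        u <- (f - 1) * ne + e_i
        xrow <- X[e_i, ]
        drow <- dFf[e_i, ]
        for (j in seq_len(kl)) {
          dK[j, u] <- sum(drow * xrow[j:(j + ntp - 1)])
        }
      }
    }
  }
  out <- list(A = dA, b = db, W = dW, dC = dC)
  if (cfg$kind == "conv") {
    out$kernels <- dK
  } else {
    co <- sinc_cutoffs(p$sinc_a, p$sinc_b, cfg$fs)
    da <- numeric(nu)
    dbw <- numeric(nu)
    for (u in seq_len(nu)) {
      g <- sinc_kernel_grad(co$low[u], co$high[u], kl, cfg$fs, cfg$window)
      dlow <- sum(dK[, u] * g$d_low)
      dhigh <- sum(dK[, u] * g$d_high)
      da[u] <- (dlow + dhigh * co$dhigh_dlow[u]) * co$dlow_da[u]
      dbw[u] <- dhigh * co$dhigh_db[u]
    }
    out$sinc_a <- da
    out$sinc_b <- dbw
  }
  out
}

#' Forward pass over a set of trials
#'
#' @param model an [spdnet_init()] (possibly trained) model.
#' @param trials a [trial_set()] or list of trial matrices.
#' @return matrix of class scores (`n_trials x n_classes`).
#' @export
network_forward <- function(model, trials) {
  tl <- if (inherits(trials, "trial_set")) trials$trials else trials
  K <- model_kernels(model)
  t(vapply(tl, function(X) forward_trial(model, X, K)$scores,
           numeric(model$config$n_classes)))
}

#' Predicted class labels
#'
#' @inheritParams network_forward
#' @return factor of predicted labels (training levels when available).
#' @export
spdnet_predict <- function(model, trials) {
  sc <- network_forward(model, trials)
  idx <- apply(sc, 1, which.max)
  lev <- model$levels %||% as.character(seq_len(model$config$n_classes))
  factor(lev[idx], levels = lev)
}

#' Test-set accuracy in percent
#'
#' @inheritParams network_forward
#' @return accuracy in `[0, 100]`.
#' @export
spdnet_accuracy <- function(model, trials) {
  stopifnot(inherits(trials, "trial_set"))
  100 * mean(as.character(spdnet_predict(model, trials)) ==
               as.character(trials$labels))
}

#' Per-layer feature maps
#'
#' Runs the forward pass and exposes every internal stage: the pooled
#' covariance, each post-BiMap and post-ReEig map (`1 + 2 * n_bire` SPD
#' stages) and the post-LogEig symmetric matrices, for layer-by-layer
#' probing.
#'
#' @inheritParams network_forward
#' @return named list of stages; each stage is a list of matrices, one per
#'   trial.
#' @export
intermediate_maps <- function(model, trials) {
  tl <- if (inherits(trials, "trial_set")) trials$trials else trials
  K <- model_kernels(model)
  per_trial <- lapply(tl, function(X) forward_trial(model, X, K)$stages)
  stage_names <- names(per_trial[[1]])
  out <- lapply(stage_names, function(nm) lapply(per_trial, `[[`, nm))
  names(out) <- stage_names
  out
}

# Softmax cross-entropy loss and score gradients for a batch.
softmax_ce <- function(scores, y_idx) {
  m <- apply(scores, 1, max)
  z <- exp(scores - m)
  probs <- z / rowSums(z)
  n <- nrow(scores)
  loss <- -mean(log(pmax(probs[cbind(seq_len(n), y_idx)], 1e-300)))
  dsc <- probs
  dsc[cbind(seq_len(n), y_idx)] <- dsc[cbind(seq_len(n), y_idx)] - 1
  list(loss = loss, dscores = dsc / n, probs = probs)
}

# Mean loss and accumulated parameter gradients over a batch of trials.
spdnet_loss_grads <- function(model, trials, y_idx) {
  K <- model_kernels(model)
  fwds <- lapply(trials, function(X) forward_trial(model, X, K))
  scores <- t(vapply(fwds, `[[`, numeric(model$config$n_classes), "scores"))
  ce <- softmax_ce(scores, y_idx)
  grads <- NULL
  for (i in seq_along(fwds)) {
    g <- backward_trial(model, fwds[[i]], ce$dscores[i, ], K)
    if (is.null(grads)) {
      grads <- g
    } else {
      grads$A <- grads$A + g$A
      grads$b <- grads$b + g$b
      for (k in seq_along(grads$W)) grads$W[[k]] <- grads$W[[k]] + g$W[[k]]
      if (!is.null(g$kernels)) grads$kernels <- grads$kernels + g$kernels
      if (!is.null(g$sinc_a)) {
        grads$sinc_a <- grads$sinc_a + g$sinc_a
        grads$sinc_b <- grads$sinc_b + g$sinc_b
      }
    }
  }
  grads$dC <- NULL
  list(loss = ce$loss, grads = grads)
}
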