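# Welch-style averaged amplitude spectrum: hamming-windowed segments with
# 50% overlap, mean modulus of the one-sided DFT.
welch_amplitude <- function(x, fs, seg_len) {
  n <- length(x)
  if (seg_len > n) seg_len <- n
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(seg_len) - 1) / (seg_len - 1))
  starts <- seq(1, n - seg_len + 1, by = max(1, floor(seg_len / 2)))
  amps <- vapply(starts, function(s) {
    seg <- x[s:(s + seg_len - 1)] * w
    Mod(stats::fft(seg))[seq_len(floor(seg_len / 2) + 1)]
  }, numeric(floor(seg_len / 2) + 1))
  list(freq = seq(0, floor(seg_len / 2)) * fs / seg_len,
       amp = rowMeans(matrix(amps, ncol = length(starts))))
}

# Shared Welch segment length for pre/post spectra comparison.
gain_seg_len <- function(n_post) 2^min(8, floor(log2(n_post)))

#' Frequency gain spectra of a model's filterbank
#'
#' For every filter unit, the dB ratio of the post-filter to pre-filter
#' Welch amplitude spectrum, averaged over trials (and over electrodes for
#' channel-independent banks). Positive values mean amplification,
#' negative attenuation. Bins where the ratio collapses to zero
#' (`-Inf` dB) are linearly interpolated across neighbouring finite bins; a
#' spectrum with more than 50% such bins is flagged discarded and carries
#' no gain values.
#'
#' @param model an [spdnet_init()] model (trained or not).
#' @param trials a [trial_set()] at the model's sampling rate.
#' @return tibble of class `gain_spectrum` with columns `filter`, `freq`
#'   (Hz), `gain_db`, `interpolated`, `discarded`.
#' @export
frequency_gain <- function(model, trials) {
  cfg <- model$config
  stopifnot(inherits(trials, "trial_set"))
  spec <- model_filterbank(model)
  ne <- cfg$ne
  nu <- n_filter_units(cfg)
  seg <- gain_seg_len(trials$nt - cfg$kernel_len + 1)
  pre_acc <- NULL
  post_acc <- vector("list", nu)
  for (X in trials$trials) {
    Fm <- filterbank_forward(X, spec)
    pre <- vapply(seq_len(ne), function(e) {
      welch_amplitude(X[e, ], cfg$fs, seg)$amp
    }, numeric(seg / 2 + 1))
    pre_acc <- if (is.null(pre_acc)) pre else pre_acc + pre
    for (u in seq_len(nu)) {
      rows <- if (cfg$specificity == "chind") {
        (u - 1) * ne + seq_len(ne)               # unit u = filter u, all electrodes
      } else {
        u                                        # unit u = one (filter, electrode) row
      }
      post <- rowMeans(vapply(rows, function(r) {
        welch_amplitude(Fm[r, ], cfg$fs, seg)$amp
      }, numeric(seg / 2 + 1)))
      post_acc[[u]] <- if (is.null(post_acc[[u]])) post else post_acc[[u]] + post
    }
  }
  freq <- welch_amplitude(trials$trials[[1]][1, ], cfg$fs, seg)$freq
  n_tr <- length(trials$trials)
  out <- purrr::map_dfr(seq_len(nu), function(u) {
    # pre spectrum matching this unit: its electrode (ChSpec) or all (ChInd)
    pre_u <- if (cfg$specificity == "chind") {
      rowMeans(pre_acc) / n_tr
    } else {
      pre_acc[, (u - 1) %% ne + 1] / n_tr
    }
    g <- 20 * log10((post_acc[[u]] / n_tr) / pre_u)
    bad <- !is.finite(g)
    discarded <- mean(bad) > 0.5
    interp <- bad & !discarded
    if (discarded) {
      g[] <- NA_real_
    } else if (any(bad)) {
      g[bad] <- stats::approx(freq[!bad], g[!bad], xout = freq[bad],
                              rule = 2)$y
    }
    tibble::tibble(filter = u, freq = freq, gain_db = g,
                   interpolated = interp, discarded = discarded)
  })
  class(out) <- c("gain_spectrum", class(out))
  out
}

#' Count passband peaks in a gain spectrum
#'
#' Smooths each filter's gain spectrum with a moving average, zeroes it
#' around its median, and counts prominence-thresholded peaks. More than
#' one peak labels the filter multiband: a single learned filter that lets
#' two or more distinct frequency regions pass.
#'
#' @param gain a `gain_spectrum` tibble from [frequency_gain()].
#' @param smooth_hz moving-average window (default 2 Hz).
#' @param height_frac peak height threshold as a fraction of the smoothed
#'   maximum (default 0.25).
#' @param height_db absolute peak height floor above the median level, in
#'   dB (default 3, the half-power convention); keeps flat ripple from
#'   counting as passbands.
#' @param min_width_hz minimum peak width (default 2 Hz).
#' @return tibble with `filter`, `n_peaks`, `multiband`; discarded spectra
#'   get `NA`.
#' @export
count_peaks <- function(gain, smooth_hz = 2, height_frac = 0.25,
                        height_db = 3, min_width_hz = 2) {
  dplyr::summarise(
    dplyr::group_by(gain, .data$filter),
    n_peaks = count_peaks_one(.data$gain_db, .data$freq, smooth_hz,
                              height_frac, height_db, min_width_hz),
    .groups = "drop",
    multiband = .data$n_peaks > 1
  )
}

count_peaks_one <- function(g, freq, smooth_hz, height_frac, height_db,
                            min_width_hz) {
  if (all(is.na(g))) return(NA_integer_)
  df <- freq[2] - freq[1]
  k <- max(1, round(smooth_hz / df))
  if (k %% 2 == 0) k <- k + 1
  sm <- as.numeric(stats::filter(g, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- g[is.na(sm)]
  sm <- sm - median(sm)
  if (max(sm) <= 0) return(0L)
  pk <- pracma::findpeaks(sm,
                          minpeakheight = max(height_frac * max(sm), height_db),
                          minpeakdistance = max(1, round(min_width_hz / df)))
  if (is.null(pk)) return(0L)
  # enforce the width requirement from the peak's own shoulders
  widths <- (pk[, 4] - pk[, 3]) * df
  sum(widths >= min_width_hz)
}

#' Layer-by-layer probe classification
#'
#' Extracts the feature maps at every SPD stage of the network (pooled
#' covariance, each post-BiMap and post-ReEig map), fits a Euclidean SVM
#' (on norm-preserving vectorisations) and a Riemannian tangent-space SVM
#' (LEM) on the training maps, and scores both on the test maps. Non-PD
#' maps are regularised with the model's ReEig threshold before probing.
#'
#' @param model a trained [spdnet_train()] model.
#' @param train,test [trial_set()]s matching the model's training split.
#' @return tibble with `stage`, `probe`, `accuracy`, and
#'   `delta_vs_network` (probe minus network test accuracy, percentage
#'   points).
#' @export
layer_by_layer <- function(model, train, test) {
  maps_tr <- intermediate_maps(model, train)
  maps_te <- intermediate_maps(model, test)
  stages <- setdiff(names(maps_tr), "logeig")
  net_acc <- spdnet_accuracy(model, test)
  eps <- model$config$reeig_eps
  rows <- purrr::map_dfr(stages, function(st) {
    tr <- lapply(maps_tr[[st]], regularize_spd, eps = eps)
    te <- lapply(maps_te[[st]], regularize_spd, eps = eps)
    pr_r <- rsvm_fit_predict(tr, train$labels, te, metric = "lem")
    Vtr <- t(vapply(tr, vect_spd, numeric(nrow(tr[[1]]) * (nrow(tr[[1]]) + 1) / 2)))
    Vte <- t(vapply(te, vect_spd, numeric(nrow(te[[1]]) * (nrow(te[[1]]) + 1) / 2)))
    sv <- e1071::svm(Vtr, train$labels, kernel = "linear", cost = 1,
                     scale = FALSE, type = "C-classification")
    pr_e <- predict(sv, Vte)
    acc <- function(p) 100 * mean(as.character(p) == as.character(test$labels))
    tibble::tibble(stage = st, probe = c("rsvm", "svm"),
                   accuracy = c(acc(pr_r), acc(pr_e)))
  })
  rows$delta_vs_network <- rows$accuracy - net_acc
  attr(rows, "network_accuracy") <- net_acc
  rows
}

#' Share of feature-map eigenvalues below the ReEig threshold
#'
#' Per network stage, the percentage of feature-map eigenvalues smaller
#' than the rectification threshold, averaged over trials. Immediately
#' after a ReEig layer this is exactly zero by construction; before the
#' first rectification it measures how close the pooled covariances sit to
#' the singular boundary.
#'
#' @param model an [spdnet_init()] model.
#' @param trials a [trial_set()].
#' @return tibble with `stage` and `pct_below`.
#' @export
eig_below_threshold <- function(model, trials) {
  maps <- intermediate_maps(model, trials)
  maps$logeig <- NULL
  eps <- model$config$reeig_eps
  purrr::map_dfr(names(maps), function(st) {
    pct <- vapply(maps[[st]], function(S) {
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      100 * mean(ev < eps)
    }, numeric(1))
    tibble::tibble(stage = st, pct_below = mean(pct))
  })
}

#' Gain applied by the first BiMap layer to covariance entries
#'
#' For first-layer weight `W`, the total gain applied to input entry
#' `C[p, q]` across the whole output is `G[p, q] = sum_ij (W_p o W_q)_ij`,
#' the summed outer product of rows `p` and `q` -- equivalently the rank-1
#' matrix `s s'` with `s = rowSums(W)`. Row sums of `G`, mapped back
#' through the band-major row order, aggregate the gain per electrode
#' (its variance plus all its covariance pairs).
#'
#' @param model a model whose first BiMap weight is probed, or a weight
#'   matrix directly.
#' @return list with `G` (gain matrix), `row_gain` (per covariance row),
#'   and -- when the electrode map is known -- `electrode_gain` tibble.
#' @export
bimap_gain <- function(model) {
  if (inherits(model, "spdnet_model")) {
    if (model$config$n_bire < 1) stop("model has no BiMap layer", call. = FALSE)
    W <- model$params$W[[1]]
    ne <- model$config$ne
    nf <- model$config$nf
  } else {
    W <- model
    ne <- NULL
  }
  s <- rowSums(W)
  G <- tcrossprod(s)
  row_gain <- rowSums(G)
  out <- list(G = G, row_gain = row_gain)
  if (!is.null(ne)) {
    el <- rep(seq_len(ne), times = nf)
    out$electrode_gain <- tibble::tibble(
      electrode = seq_len(ne),
      gain = as.numeric(tapply(row_gain, el, sum)))
  }
  out
}

#' Gradient-based electrode-frequency relevance
#'
#' For each class, the gradient of the class score with respect to the
#' pooled covariance matrix is computed per training trial, summed across
#' matrix rows to one scalar per (band, electrode) row, multiplied by that
#' filter's 0-1-normalised frequency gain spectrum, and aggregated over
#' bands and trials into an electrodes-by-frequencies relevance map.
#' Signed: positive values mean increasing power there raises the class
#' score.
#'
#' @param model a trained model.
#' @param trials a [trial_set()] (typically the training split).
#' @return object of class `relevance_map`: list with `rel` (array
#'   `n_classes x ne x n_freqs`), `freq`, and a `tidy()`-friendly tibble
#'   accessor via [tidy.relevance_map()].
#' @export
electrode_frequency_relevance <- function(model, trials) {
  cfg <- model$config
  ne <- cfg$ne
  nu <- n_filter_units(cfg)
  gain <- frequency_gain(model, trials)
  freq <- unique(gain$freq)
  nfx <- length(freq)
  # per-unit 0-1 min-max normalised gain (discarded spectra contribute 0)
  gmat <- matrix(0, nu, nfx)
  for (u in seq_len(nu)) {
    g <- gain$gain_db[gain$filter == u]
    if (!all(is.na(g))) {
      rng <- range(g)
      gmat[u, ] <- if (diff(rng) > 0) (g - rng[1]) / diff(rng) else 0 * g + 1
    }
  }
  K <- model_kernels(model)
  n_cl <- cfg$n_classes
  rel <- array(0, dim = c(n_cl, ne, nfx))
  for (X in trials$trials) {
    fwd <- forward_trial(model, X, K)
    for (cl in seq_len(n_cl)) {
      dsc <- numeric(n_cl)
      dsc[cl] <- 1
      dC <- backward_trial(model, fwd, dsc, K)$dC
      rsum <- rowSums(dC)                       # one scalar per (band, electrode)
      for (f in seq_len(cfg$nf)) {
        for (e in seq_len(ne)) {
          r <- (f - 1) * ne + e
          u <- if (cfg$specificity == "chind") f else r
          rel[cl, e, ] <- rel[cl, e, ] + rsum[r] * gmat[u, ]
        }
      }
    }
  }
  rel <- rel / length(trials$trials)
  lev <- model$levels %||% as.character(seq_len(n_cl))
  structure(list(rel = rel, freq = freq, classes = lev, ne = ne),
            class = "relevance_map")
}
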