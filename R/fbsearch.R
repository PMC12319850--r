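# Evaluate with a fixed seed without disturbing the caller's RNG stream --
# seeded subroutines inside an outer stochastic loop (e.g. fold assignment
# inside the filterbank search) must not reset the global state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  expr
}

# Seeded stratified k-fold assignment; errors if any fold misses a class.
stratified_folds <- function(labels, k, seed = 1) {
  labels <- as.factor(labels)
  if (k < 2) stop("need at least 2 folds", call. = FALSE)
  if (min(table(labels)) < k) {
    stop("stratification error: a class has fewer samples than folds", call. = FALSE)
  }
  with_local_seed(seed, {
    folds <- integer(length(labels))
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds
  })
}

#' Filterbank search configuration
#'
#' @param nf filters in the bank.
#' @param specificity `"chind"` or `"chspec"`.
#' @param metric Riemannian metric for the proxy classifier.
#' @param proxy `"rmdm"` or `"rsvm"`.
#' @param max_trials search budget in scored filterbanks (default 100).
#' @param max_walltime wall-clock budget in seconds (default `Inf`).
#' @param cv_folds stratified cross-validation folds (default 5).
#' @param kernel_len odd sinc kernel length; default `fs/4` rounded to odd
#'   at objective time.
#' @param seed integer seed for proposals and fold assignment.
#' @return object of class `search_config`.
#' @export
search_config <- function(nf = 1, specificity = c("chind", "chspec"),
                          metric = c("lem", "airm"),
                          proxy = c("rmdm", "rsvm"), max_trials = 100,
                          max_walltime = Inf, cv_folds = 5,
                          kernel_len = NULL, seed = 1) {
  specificity <- match.arg(specificity)
  metric <- match.arg(metric)
  proxy <- match.arg(proxy)
  if (max_trials < 1) stop("max_trials must be >= 1", call. = FALSE)
  if (cv_folds < 2) stop("cv_folds must be >= 2", call. = FALSE)
  if (specificity == "chspec" && nf > 4) {
    warning("channel-specific search at high nf has many parameters; ",
            "black-box optimisers struggle in this regime")
  }
  structure(list(nf = nf, specificity = specificity, metric = metric,
                 proxy = proxy, max_trials = max_trials,
                 max_walltime = max_walltime, cv_folds = cv_folds,
                 kernel_len = kernel_len, seed = seed),
            class = "search_config")
}

#' Cross-validated proxy accuracy of a static filterbank
#'
#' Filters every trial with the (static sinc) bank, pools covariance
#' matrices -- block-diagonal concatenation of per-band SCMs for
#' channel-independent banks, full SCM for channel-specific ones -- and
#' scores the configured proxy classifier by stratified k-fold
#' cross-validation. Deterministic given `config$seed`.
#'
#' @param spec a sinc [filterbank_spec()].
#' @param train a labelled [trial_set()].
#' @param config a [search_config()].
#' @return cross-validated accuracy in percent.
#' @export
fb_objective <- function(spec, train, config) {
  if (spec$kind != "sinc") stop("objective expects a sinc filterbank", call. = FALSE)
  covs <- lapply(train$trials, function(X) {
    Fm <- filterbank_forward(X, spec)
    S <- scm_pool(Fm, spec$nf, spec$specificity, keep_interband = FALSE)
    regularize_spd(S, 1e-10)
  })
  folds <- stratified_folds(train$labels, config$cv_folds, config$seed)
  correct <- 0L
  for (f in seq_len(config$cv_folds)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    pred <- if (config$proxy == "rmdm") {
      rmdm_fit_predict(covs[tr], train$labels[tr], covs[te], config$metric)
    } else {
      rsvm_fit_predict(covs[tr], train$labels[tr], covs[te], config$metric)
    }
    correct <- correct + sum(as.character(pred) == as.character(train$labels[te]))
  }
  100 * correct / length(covs)
}

# Build the cutoff matrix for one candidate parameter vector
# (low_1, bw_1, low_2, bw_2, ...).
params_to_spec <- function(par, config, ne, fs, kernel_len) {
  nyq <- fs / 2
  n_units <- if (config$specificity == "chind") config$nf else config$nf * ne
  low <- pmin(pmax(par[seq(1, 2 * n_units, 2)], 0), nyq - 1.5)
  high <- pmin(low + pmax(par[seq(2, 2 * n_units, 2)], 1), nyq)
  filterbank_spec("sinc", config$nf, ne, fs, config$specificity, kernel_len,
                  cutoffs = cbind(low, high))
}

# Parzen-window (TPE-style) proposal: model the top-quantile trials with a
# per-dimension Gaussian KDE l(x), the rest with g(x), and take the best of
# `n_cand` KDE samples under l(x)/g(x).
propose_tpe <- function(X_obs, y_obs, lower, upper, n_cand = 24, gamma = 0.25) {
  n <- nrow(X_obs)
  n_good <- max(2, ceiling(gamma * n))
  ord <- order(y_obs, decreasing = TRUE)
  good <- X_obs[ord[seq_len(n_good)], , drop = FALSE]
  bad <- X_obs[ord[-seq_len(n_good)], , drop = FALSE]
  if (nrow(bad) < 2) bad <- X_obs
  d <- ncol(X_obs)
  bw <- function(M) {
    s <- apply(M, 2, sd)
    pmax(1.06 * s * nrow(M)^(-1 / 5), (upper - lower) / 50)
  }
  bw_g <- bw(good)
  kde_logdens <- function(M, h, x) {
    sum(log(rowMeans(vapply(seq_len(nrow(M)), function(i) {
      stats::dnorm(x, M[i, ], h)
    }, numeric(d))) + 1e-300))
  }
  bw_b <- bw(bad)
  best <- NULL
  best_score <- -Inf
  for (cand in seq_len(n_cand)) {
    # mix a uniform prior into the proposal density so the search keeps
    # exploring even when the incumbents sit in a flat region
    x <- if (cand %% 4 == 0) {
      runif(d, lower, upper)
    } else {
      i <- sample(nrow(good), 1)
      rnorm(d, good[i, ], bw_g)
    }
    x <- pmin(pmax(x, lower), upper)
    score <- kde_logdens(good, bw_g, x) - kde_logdens(bad, bw_b, x)
    if (score > best_score) {
      best_score <- score
      best <- x
    }
  }
  best
}

#' Black-box filterbank search
#'
#' Sequential model-based search over sinc cutoff pairs, scored by
#' [fb_objective()] on the training set only. Each filter is parameterised
#' as (low, bandwidth) with bandwidth >= 1 Hz so proposals can never invert
#' the cutoffs. The first quarter of the budget is random exploration;
#' afterwards candidates come from a Parzen-estimator density-ratio rule.
#' The search stops at `max_trials` scored banks or when `max_walltime`
#' seconds have elapsed (a trial is only logged if fully scored).
#'
#' @param train a labelled [trial_set()].
#' @param config a [search_config()].
#' @return object of class `fb_search_result`: `best_spec`,
#'   `best_cv_accuracy` (%), and `trial_log` (tibble of scored candidates).
#' @export
fb_search <- function(train, config) {
  t0 <- Sys.time()
  fs <- train$fs
  ne <- train$ne
  nyq <- fs / 2
  kernel_len <- config$kernel_len %||% default_kernel_len(fs)
  n_units <- if (config$specificity == "chind") config$nf else config$nf * ne
  d <- 2 * n_units
  lower <- rep(c(0.5, 1), n_units)
  upper <- rep(c(nyq - 2, nyq / 2), n_units)
  set.seed(config$seed)
  n_init <- max(5, ceiling(config$max_trials / 4))
  X_obs <- matrix(NA_real_, 0, d)
  y_obs <- numeric(0)
  log_rows <- list()
  for (tr in seq_len(config$max_trials)) {
    if (as.numeric(difftime(Sys.time(), t0, units = "secs")) >
        config$max_walltime) break
    par <- if (nrow(X_obs) < n_init || runif(1) < 0.15) {
      # keep a floor of pure exploration after the random-initialisation
      # phase; pure exploitation stalls when all incumbents are mediocre
      runif(d, lower, upper)
    } else {
      propose_tpe(X_obs, y_obs, lower, upper)
    }
    spec <- params_to_spec(par, config, ne, fs, kernel_len)
    score <- fb_objective(spec, train, config)
    X_obs <- rbind(X_obs, par)
    y_obs <- c(y_obs, score)
    log_rows[[tr]] <- tibble::tibble(
      trial = tr, score = score,
      low = list(spec$cutoffs[, 1]), high = list(spec$cutoffs[, 2]))
  }
  if (length(y_obs) == 0) {
    stop("walltime exhausted before any filterbank was scored", call. = FALSE)
  }
  best <- which.max(y_obs)
  best_spec <- params_to_spec(X_obs[best, ], config, ne, fs, kernel_len)
  structure(list(best_spec = best_spec, best_cv_accuracy = y_obs[best],
                 trial_log = dplyr::bind_rows(log_rows), config = config),
            class = "fb_search_result")
}

#' @export
print.fb_search_result <- function(x, ...) {
  cat(sprintf("<fb_search_result> %d trials, best CV accuracy %.1f%%\n",
              nrow(x$trial_log), x$best_cv_accuracy))
  co <- x$best_spec$cutoffs
  for (u in seq_len(nrow(co))) {
    cat(sprintf("  filter %d: %.1f-%.1f Hz\n", u, co[u, 1], co[u, 2]))
  }
  invisible(x)
}

#' Frequency coverage of a set of sinc filterbanks
#'
#' For each grid frequency, the percentage of all bandpass filters (pooled
#' across the given banks and their units) whose `[low, high]` interval
#' contains it.
#'
#' @param specs list of sinc [filterbank_spec()]s (a single spec is
#'   accepted).
#' @param grid frequency grid in Hz; defaults to 0 to Nyquist in 0.5 Hz
#'   steps.
#' @return tibble with columns `freq` and `coverage_pct`.
#' @export
coverage_spectrum <- function(specs, grid = NULL) {
  if (inherits(specs, "filterbank_spec")) specs <- list(specs)
  if (length(specs) == 0) stop("empty spec list", call. = FALSE)
  if (any(vapply(specs, function(s) s$kind, "") != "sinc")) {
    stop("coverage is defined for sinc filterbanks", call. = FALSE)
  }
  cuts <- do.call(rbind, lapply(specs, function(s) s$cutoffs))
  if (is.null(grid)) grid <- seq(0, specs[[1]]$fs / 2, by = 0.5)
  cov <- vapply(grid, function(f) {
    100 * mean(cuts[, 1] <= f & f <= cuts[, 2])
  }, numeric(1))
  tibble::tibble(freq = grid, coverage_pct = cov)
}
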