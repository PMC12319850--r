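#' Training configuration
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param weight_decay L2 penalty added to the gradients of conv kernels,
#'   BiMap weights and the affine weight (not biases or sinc cutoffs);
#'   default 1e-4.
#' @param epochs passes over the training set (default 100).
#' @param batch_size minibatch size (default 32).
#' @param seed integer seed for batch shuffling (initialisation is seeded
#'   by the model's own config).
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, weight_decay = 1e-4,
                         epochs = 100, batch_size = 32, seed = 1) {
  if (learning_rate <= 0 || weight_decay < 0) stop("invalid rates", call. = FALSE)
  if (epochs < 1 || batch_size < 1) stop("invalid counts", call. = FALSE)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = epochs, batch_size = batch_size, seed = seed),
            class = "train_config")
}

sym_mat <- function(A) (A + t(A)) / 2

# Project an ambient gradient onto the tangent space of the Stiefel
# manifold at W.
stiefel_project <- function(W, G) G - W %*% sym_mat(crossprod(W, G))

# First-order QR retraction with sign-fixed R so the map is deterministic.
stiefel_retract <- function(W) {
  qq <- qr(W)
  Q <- qr.Q(qq)
  s <- sign(diag(qr.R(qq)))
  s[s == 0] <- 1
  Q * rep(s, each = nrow(Q))
}

adam_init <- function(p) list(m = p * 0, v = p * 0)

# One Adam step on a Euclidean parameter.
adam_step <- function(p, g, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mh <- st$m / (1 - b1^t)
  vh <- st$v / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), st = st)
}

# One Riemannian Adam step on a Stiefel parameter: project the gradient to
# the tangent space, run pointwise Adam moments on tangent components,
# retract with QR, and parallel-transport the first moment by projection at
# the new point.
radam_step_stiefel <- function(W, G, st, lr, t, b1 = 0.9, b2 = 0.999,
                               eps = 1e-8) {
  xi <- stiefel_project(W, G)
  st$m <- b1 * st$m + (1 - b1) * xi
  st$v <- b2 * st$v + (1 - b2) * xi^2
  mh <- st$m / (1 - b1^t)
  vh <- st$v / (1 - b2^t)
  W_new <- stiefel_retract(W - lr * mh / (sqrt(vh) + eps))
  st$m <- stiefel_project(W_new, st$m)
  list(p = W_new, st = st)
}

#' Train an end-to-end SPDNet
#'
#' Minimises softmax cross-entropy with a Riemannian Adam scheme: BiMap
#' weights live on the Stiefel manifold (tangent-projected gradients, QR
#' retraction every step, momentum transported by projection) while all
#' Euclidean parameters follow standard Adam. Fully seeded and
#' deterministic.
#'
#' @param model an [spdnet_init()] model.
#' @param train a [trial_set()].
#' @param config a [train_config()].
#' @return the trained model, with `$history` (tibble of per-epoch mean
#'   loss) and `$levels` set.
#' @export
spdnet_train <- function(model, train, config = train_config()) {
  stopifnot(inherits(model, "spdnet_model"), inherits(train, "trial_set"))
  if (nlevels(train$labels) != model$config$n_classes) {
    stop("label count does not match n_classes", call. = FALSE)
  }
  set.seed(config$seed)
  y_idx <- as.integer(train$labels)
  n <- length(train$trials)
  p <- model$params
  st <- list(A = adam_init(p$A), b = adam_init(p$b),
             W = lapply(p$W, adam_init))
  if (!is.null(p$kernels)) st$kernels <- adam_init(p$kernels)
  if (!is.null(p$sinc_a)) {
    st$sinc_a <- adam_init(p$sinc_a)
    st$sinc_b <- adam_init(p$sinc_b)
  }
  lr <- config$learning_rate
  wd <- config$weight_decay
  t_step <- 0
  losses <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(n)
    batch_losses <- c()
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      model$params <- p
      lg <- spdnet_loss_grads(model, train$trials[idx], y_idx[idx])
      if (!is.finite(lg$loss)) {
        stop(sprintf("non-finite loss at epoch %d (trials %s)", ep,
                     paste(utils::head(idx), collapse = ",")), call. = FALSE)
      }
      batch_losses <- c(batch_losses, lg$loss)
      g <- lg$grads
      t_step <- t_step + 1
      up <- adam_step(p$A, g$A + wd * p$A, st$A, lr, t_step)
      p$A <- up$p; st$A <- up$st
      up <- adam_step(p$b, g$b, st$b, lr, t_step)
      p$b <- up$p; st$b <- up$st
      for (k in seq_along(p$W)) {
        up <- radam_step_stiefel(p$W[[k]], g$W[[k]] + wd * p$W[[k]],
                                 st$W[[k]], lr, t_step)
        p$W[[k]] <- up$p; st$W[[k]] <- up$st
      }
      if (!is.null(p$kernels)) {
        up <- adam_step(p$kernels, g$kernels + wd * p$kernels, st$kernels,
                        lr, t_step)
        p$kernels <- up$p; st$kernels <- up$st
      }
      if (!is.null(p$sinc_a)) {
        up <- adam_step(p$sinc_a, g$sinc_a, st$sinc_a, lr, t_step)
        p$sinc_a <- up$p; st$sinc_a <- up$st
        up <- adam_step(p$sinc_b, g$sinc_b, st$sinc_b, lr, t_step)
        p$sinc_b <- up$p; st$sinc_b <- up$st
      }
    }
    losses[ep] <- mean(batch_losses)
  }
  model$params <- p
  model$levels <- levels(train$labels)
  model$history <- tibble::tibble(epoch = seq_len(config$epochs),
                                  loss = losses)
  model$train_config <- config
  model
}

#' Per-participant, multi-seed evaluation protocol
#'
#' For every participant and every seed, builds a freshly initialised
#' model, trains it on the participant's training split and scores it on
#' the unseen test split. Accuracy is reported in percent. The result rows
#' are independent across participant-seed combinations, so execution
#' order cannot change them.
#'
#' @param dataset named list of participants, each a list with `train` and
#'   `test` [trial_set()]s.
#' @param model_builder `function(train, seed)` returning an untrained
#'   [spdnet_init()] model.
#' @param config a [train_config()].
#' @param seeds integer vector of initialisation seeds (default 3 seeds).
#' @param condition label recorded in the score table.
#' @return tibble with columns participant, seed, condition, accuracy, of
#'   class `score_table`; the participant-and-seed mean is in
#'   `attr(, "mean_accuracy")`.
#' @export
evaluate_protocol <- function(dataset, model_builder, config = train_config(),
                              seeds = 1:3, condition = "model") {
  if (length(seeds) == 0) stop("need at least one seed", call. = FALSE)
  if (is.null(names(dataset))) names(dataset) <- paste0("P", seq_along(dataset))
  rows <- purrr::map_dfr(names(dataset), function(pid) {
    part <- dataset[[pid]]
    if (is.null(part$train) || is.null(part$test)) {
      stop(sprintf("participant %s is missing a train/test split", pid),
           call. = FALSE)
    }
    purrr::map_dfr(seeds, function(sd) {
      model <- model_builder(part$train, sd)
      cfg <- config
      cfg$seed <- sd
      fit <- spdnet_train(model, part$train, cfg)
      tibble::tibble(participant = pid, seed = sd, condition = condition,
                     accuracy = spdnet_accuracy(fit, part$test))
    })
  })
  class(rows) <- c("score_table", class(rows))
  attr(rows, "mean_accuracy") <- mean(rows$accuracy)
  rows
}

#' Exact two-sided Wilcoxon signed-rank p-value
#'
#' Computes the signed-rank statistic of the paired differences `a - b`
#' (zero differences dropped before ranking, ties given average ranks) and
#' its exact two-sided p-value by enumerating the null distribution of the
#' positive-rank sum through a convolution over the (doubled, hence
#' integral) ranks. No normal approximation is used at any `n`, which at
#' small samples gives the discrete values `2 * 2^-n` when every
#' difference has the same sign.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return exact two-sided p-value; `1` (with a warning) when every pair
#'   is tied.
#' @export
wilcoxon_exact <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1) {
    stop("need paired vectors of equal positive length", call. = FALSE)
  }
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all pairs tied; p = 1")
    return(1)
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  r2 <- as.integer(round(2 * r))   # doubled ranks are integers even with ties
  total <- sum(r2)
  counts <- c(1, numeric(total))   # counts[s + 1] = #subsets with doubled-sum s
  for (rk in r2) {
    shifted <- c(numeric(rk), counts[seq_len(total + 1 - rk)])
    counts <- counts + shifted
  }
  n2 <- 2^length(d)
  w2 <- as.integer(round(2 * w))
  p_le <- sum(counts[seq_len(w2 + 1)]) / n2
  p_ge <- sum(counts[(w2 + 1):(total + 1)]) / n2
  min(1, 2 * min(p_le, p_ge))
}
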