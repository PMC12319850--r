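#' Riemannian distance between SPD matrices
#'
#' Geodesic distance on the SPD manifold under the affine-invariant metric
#' (AIRM, `||logm(S1^{-1/2} S2 S1^{-1/2})||_F`, invariant to congruence
#' `S -> A S A'`) or the log-Euclidean metric
#' (LEM, `||logm(S1) - logm(S2)||_F`).
#'
#' @param S1,S2 strictly positive definite matrices of equal dimension.
#' @param metric `"airm"` or `"lem"`.
#' @return non-negative scalar; zero iff `S1 == S2`.
#' @export
spd_dist <- function(S1, S2, metric = c("airm", "lem")) {
  metric <- match.arg(metric)
  if (!identical(dim(S1), dim(S2))) stop("dimension mismatch", call. = FALSE)
  if (metric == "lem") {
    sqrt(sum((logeig_map(S1) - logeig_map(S2))^2))
  } else {
    isq <- powm_spd(S1, -0.5)
    sqrt(sum(logeig_map(isq %*% S2 %*% isq)^2))
  }
}

#' Fréchet (geometric) mean of SPD matrices
#'
#' Under LEM the mean has the closed form `expm(mean(logm(S_i)))`. Under
#' AIRM it is the Karcher mean, computed by fixed-point iteration
#' `M <- M^{1/2} expm(step * mean_i logm(M^{-1/2} S_i M^{-1/2})) M^{1/2}`
#' with step halving on divergence, to a tolerance on the mean tangent
#' displacement.
#'
#' @param Ss list of SPD matrices.
#' @param metric `"airm"` or `"lem"`.
#' @param tol convergence tolerance on the Frobenius norm of the mean
#'   tangent displacement (AIRM only).
#' @param max_iter iteration cap (AIRM only).
#' @return SPD matrix.
#' @export
frechet_mean <- function(Ss, metric = c("airm", "lem"), tol = 1e-9,
                         max_iter = 200) {
  metric <- match.arg(metric)
  if (!is.list(Ss) || length(Ss) == 0) stop("need a non-empty list", call. = FALSE)
  if (metric == "lem") {
    L <- Reduce(`+`, lapply(Ss, logeig_map)) / length(Ss)
    return(expm_spd(L))
  }
  M <- Reduce(`+`, Ss) / length(Ss)  # arithmetic mean as initial iterate
  step <- 1
  res_prev <- Inf
  for (it in seq_len(max_iter)) {
    Msq <- powm_spd(M, 0.5)
    Misq <- powm_spd(M, -0.5)
    Tm <- Reduce(`+`, lapply(Ss, function(S) logeig_map(Misq %*% S %*% Misq))) /
      length(Ss)
    res <- sqrt(sum(Tm^2))
    if (res < tol) return(M)
    if (res > res_prev) step <- step / 2 else res_prev <- res
    M <- Msq %*% expm_spd(step * Tm) %*% Msq
    M <- (M + t(M)) / 2
  }
  stop(sprintf(
    "AIRM mean did not converge in %d iterations (residual %.3g)",
    max_iter, res_prev), call. = FALSE)
}

#' Project SPD matrices to a tangent space
#'
#' Maps each matrix to a norm-preserving tangent vector. LEM: `vect(logm S)`,
#' reference-free. AIRM: `vect(logm(R^{-1/2} S R^{-1/2}))` where the
#' reference `R` defaults to the Fréchet mean of the set; at the reference
#' the vector norm equals the AIRM distance to it.
#'
#' @param Ss list of SPD matrices.
#' @param metric `"airm"` or `"lem"`.
#' @param reference SPD matrix, or `"auto"` to use the AIRM Fréchet mean of
#'   `Ss` (ignored for LEM).
#' @return matrix (`length(Ss)` rows by `n(n+1)/2` columns) with attributes
#'   `reference` and `metric`.
#' @export
tangent_project <- function(Ss, metric = c("airm", "lem"), reference = "auto") {
  metric <- match.arg(metric)
  if (metric == "lem") {
    V <- t(vapply(Ss, function(S) vect_spd(logeig_map(S)),
                  numeric(nrow(Ss[[1]]) * (nrow(Ss[[1]]) + 1) / 2)))
    ref <- NULL
  } else {
    ref <- if (identical(reference, "auto")) frechet_mean(Ss, "airm") else reference
    Risq <- powm_spd(ref, -0.5)
    V <- t(vapply(Ss, function(S) vect_spd(logeig_map(Risq %*% S %*% Risq)),
                  numeric(nrow(Ss[[1]]) * (nrow(Ss[[1]]) + 1) / 2)))
  }
  attr(V, "reference") <- ref
  attr(V, "metric") <- metric
  V
}

#' Minimum distance to Riemannian mean classifier (rMDM)
#'
#' Fits one Fréchet mean per class and assigns each test matrix to the class
#' whose mean is nearest under the chosen metric. Ties break to the lowest
#' class index. Deterministic.
#'
#' @param train list of SPD matrices.
#' @param labels class labels (factor or coercible), one per training matrix.
#' @param metric `"airm"` or `"lem"`.
#' @return object of class `rmdm` with per-class means.
#' @export
rmdm_fit <- function(train, labels, metric = c("airm", "lem")) {
  metric <- match.arg(metric)
  labels <- as.factor(labels)
  if (length(train) != length(labels)) stop("length mismatch", call. = FALSE)
  if (any(table(labels) == 0)) stop("every class needs at least one sample", call. = FALSE)
  means <- lapply(levels(labels), function(cl) {
    frechet_mean(train[labels == cl], metric)
  })
  names(means) <- levels(labels)
  structure(list(means = means, metric = metric, levels = levels(labels)),
            class = "rmdm")
}

#' @param object fitted `rmdm` model.
#' @param newdata list of SPD matrices to classify.
#' @param ... unused.
#' @rdname rmdm_fit
#' @export
predict.rmdm <- function(object, newdata, ...) {
  d <- vapply(newdata, function(S) {
    vapply(object$means, function(M) spd_dist(S, M, object$metric), numeric(1))
  }, numeric(length(object$means)))
  d <- matrix(d, nrow = length(object$means))
  factor(object$levels[apply(d, 2, which.min)], levels = object$levels)
}

#' @param test list of SPD matrices to classify.
#' @rdname rmdm_fit
#' @export
rmdm_fit_predict <- function(train, labels, test, metric = c("airm", "lem")) {
  predict(rmdm_fit(train, labels, metric), test)
}

#' Tangent-space SVM classifier (rSVM)
#'
#' Projects SPD matrices to the tangent space (reference computed from the
#' training set only) and fits a linear-kernel SVM on the tangent vectors.
#'
#' @inheritParams rmdm_fit
#' @param cost SVM regularisation constant (default 1).
#' @param standardize standardise tangent features before the SVM?
#'   Default FALSE.
#' @return object of class `rsvm`.
#' @export
rsvm_fit <- function(train, labels, metric = c("airm", "lem"), cost = 1,
                     standardize = FALSE) {
  metric <- match.arg(metric)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least two classes", call. = FALSE)
  V <- tangent_project(train, metric)
  fit <- e1071::svm(V, labels, kernel = "linear", cost = cost,
                    scale = standardize, type = "C-classification")
  structure(list(svm = fit, metric = metric,
                 reference = attr(V, "reference"),
                 levels = levels(labels)),
            class = "rsvm")
}

#' @param object fitted `rsvm` model.
#' @param newdata list of SPD matrices to classify.
#' @param ... unused.
#' @rdname rsvm_fit
#' @export
predict.rsvm <- function(object, newdata, ...) {
  ref <- if (object$metric == "airm") object$reference else "auto"
  V <- tangent_project(newdata, object$metric, reference = ref)
  predict(object$svm, V)
}

#' @param test list of SPD matrices to classify.
#' @rdname rsvm_fit
#' @export
rsvm_fit_predict <- function(train, labels, test, metric = c("airm", "lem"),
                             cost = 1, standardize = FALSE) {
  predict(rsvm_fit(train, labels, metric, cost, standardize), test)
}
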