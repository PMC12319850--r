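#' Save and load model checkpoints as JSON
#'
#' Serialises a model's configuration and all parameters (filter kernels or
#' sinc cutoff parameters, BiMap weights, affine head, class levels) to a
#' single JSON file with full double precision.
#'
#' @param model an [spdnet_init()] or trained model.
#' @param path file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   reconstructed model.
#' @export
save_model <- function(model, path) {
  payload <- list(
    config = unclass(model$config),
    params = list(
      kernels = model$params$kernels,
      sinc_a = model$params$sinc_a,
      sinc_b = model$params$sinc_b,
      W = model$params$W,
      A = model$params$A,
      b = model$params$b),
    levels = model$levels,
    history = if (!is.null(model$history)) as.list(model$history))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(network_config, x$config[c(
    "ne", "n_classes", "fs", "nf", "n_bire", "kind", "specificity",
    "keep_interband", "reeig_eps", "kernel_len", "window", "seed")])
  model <- spdnet_init(cfg)
  p <- x$params
  as_mat <- function(m) if (is.matrix(m)) m else as.matrix(m)
  if (!is.null(p$kernels)) model$params$kernels <- as_mat(p$kernels)
  if (!is.null(p$sinc_a)) {
    model$params$sinc_a <- as.numeric(p$sinc_a)
    model$params$sinc_b <- as.numeric(p$sinc_b)
  }
  if (length(p$W)) {
    model$params$W <- if (is.list(p$W)) {
      lapply(p$W, as_mat)
    } else if (length(dim(p$W)) == 3) {
      lapply(seq_len(dim(p$W)[1]), function(k) as_mat(p$W[k, , ]))
    } else {
      list(as_mat(p$W))
    }
  }
  model$params$A <- as_mat(p$A)
  model$params$b <- as.numeric(p$b)
  model$levels <- x$levels
  if (!is.null(x$history)) model$history <- tibble::as_tibble(x$history)
  model
}
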