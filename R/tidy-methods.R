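#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy the training history of a fitted network
#'
#' @param x a trained [spdnet_train()] model.
#' @param ... unused.
#' @return tibble with `epoch` and `loss`.
#' @method tidy spdnet_model
#' @export
tidy.spdnet_model <- function(x, ...) {
  if (is.null(x$history)) stop("model is untrained", call. = FALSE)
  x$history
}

#' One-row summary of a fitted network
#'
#' @param x a trained [spdnet_train()] model.
#' @param ... unused.
#' @return tibble with architecture and final-loss columns.
#' @method glance spdnet_model
#' @export
glance.spdnet_model <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(
    kind = cfg$kind, specificity = cfg$specificity, nf = cfg$nf,
    n_bire = cfg$n_bire, n_classes = cfg$n_classes,
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    final_loss = if (is.null(x$history)) NA_real_ else
      x$history$loss[nrow(x$history)])
}

#' Tidy a filterbank search log
#'
#' @param x an [fb_search()] result.
#' @param ... unused.
#' @return tibble with one row per scored filter: `trial`, `score`,
#'   `filter`, `low`, `high`.
#' @method tidy fb_search_result
#' @export
tidy.fb_search_result <- function(x, ...) {
  tidyr::unnest(
    dplyr::mutate(x$trial_log,
                  filter = purrr::map(.data$low, seq_along)),
    c("filter", "low", "high"))
}

#' @rdname tidy.fb_search_result
#' @method glance fb_search_result
#' @export
glance.fb_search_result <- function(x, ...) {
  tibble::tibble(n_trials = nrow(x$trial_log),
                 best_cv_accuracy = x$best_cv_accuracy)
}

#' Tidy an electrode-frequency relevance map
#'
#' @param x a [electrode_frequency_relevance()] result.
#' @param ... unused.
#' @return tibble with `class`, `electrode`, `freq`, `relevance`.
#' @method tidy relevance_map
#' @export
tidy.relevance_map <- function(x, ...) {
  purrr::map_dfr(seq_along(x$classes), function(cl) {
    purrr::map_dfr(seq_len(x$ne), function(e) {
      tibble::tibble(class = x$classes[cl], electrode = e, freq = x$freq,
                     relevance = x$rel[cl, e, ])
    })
  })
}

#' Plot frequency gain spectra
#'
#' @param object a `gain_spectrum` tibble from [frequency_gain()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot gain_spectrum
#' @export
autoplot.gain_spectrum <- function(object, ...) {
  ggplot2::ggplot(object[!object$discarded, ],
                  ggplot2::aes(.data$freq, .data$gain_db,
                               colour = factor(.data$filter))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "frequency (Hz)", y = "gain (dB)", colour = "filter") +
    ggplot2::theme_minimal()
}

#' Plot a score table from the evaluation protocol
#'
#' @param object a `score_table` from [evaluate_protocol()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot score_table
#' @export
autoplot.score_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$condition, .data$accuracy)) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$participant),
                         width = 0.1, height = 0) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4) +
    ggplot2::labs(y = "test accuracy (%)") +
    ggplot2::theme_minimal()
}

#' Plot an electrode-frequency relevance map
#'
#' @param object a `relevance_map`.
#' @param ... unused.
#' @return a ggplot (heatmap per class).
#' @method autoplot relevance_map
#' @export
autoplot.relevance_map <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$freq, factor(.data$electrode),
                               fill = .data$relevance)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~class) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "frequency (Hz)", y = "electrode") +
    ggplot2::theme_minimal()
}
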