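# ggplot2 visualizations for the main result types.

#' Plot a GFP curve, optionally colored by microstate segmentation
#'
#' @param object a `gfp_curve`.
#' @param segmentation optional [backfit()] result for the same epoch.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.gfp_curve <- function(object, segmentation = NULL, ...) {
  df <- tibble::tibble(
    time_s = (seq_along(object$values) - 1) / object$fs,
    gfp = object$values
  )
  if (!is.null(segmentation)) {
    df$state <- factor(segmentation$labels[segmentation$sample_labels])
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$gfp)) +
      ggplot2::geom_area(ggplot2::aes(fill = .data$state, group = 1),
                         alpha = 0.6) +
      ggplot2::geom_line()
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$gfp)) +
      ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "time (s)", y = "GFP (µV)") +
    ggplot2::theme_minimal()
}

#' Heatmap of microstate template topographies
#'
#' @param object a `microstate_model`.
#' @param channel_labels optional channel names.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.microstate_model <- function(object, channel_labels = NULL, ...) {
  df <- tidy(object)
  labels <- channel_labels %||%
    (if (ncol(object$templates) == 9) motor_montage() else
       paste0("ch", seq_len(ncol(object$templates))))
  df$channel <- factor(labels[df$channel], levels = labels)
  ggplot2::ggplot(df, ggplot2::aes(.data$channel, .data$template,
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = NULL, y = "template", fill = "loading") +
    ggplot2::theme_minimal()
}

#' Heatmaps of band-averaged PDC matrices
#'
#' @param object a `band_connectivity`.
#' @param channel_labels optional channel names.
#' @param ... unused.
#' @return A ggplot faceted by band.
#' @export
autoplot.band_connectivity <- function(object, channel_labels = NULL, ...) {
  df <- tidy(object)
  n <- nrow(object$matrices[[1]])
  labels <- channel_labels %||%
    (if (n == 9) motor_montage() else paste0("ch", seq_len(n)))
  df$from <- factor(labels[df$from], levels = labels)
  df$to <- factor(labels[df$to], levels = rev(labels))
  ggplot2::ggplot(df, ggplot2::aes(.data$from, .data$to, fill = .data$pdc)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~band) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "source", y = "sink", fill = "PDC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}

#' Fold accuracies of a cross-validation run
#'
#' @param object a `cv_result`.
#' @param chance optional chance level drawn as a dashed line.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.cv_result <- function(object, chance = NULL, ...) {
  df <- object$folds
  p <- ggplot2::ggplot(df, ggplot2::aes(factor(.data$fold), .data$accuracy)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean, color = "#b2182b") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "fold", y = "accuracy",
                  title = sprintf("%s: %.3f ± %.3f", object$protocol,
                                  object$mean, object$std)) +
    ggplot2::theme_minimal()
  if (!is.null(chance)) {
    p <- p + ggplot2::geom_hline(yintercept = chance, linetype = "dashed")
  }
  p
}

#' Histogram of the permutation null with an optional observed accuracy
#'
#' @param object a `null_distribution`.
#' @param observed optional observed accuracy drawn as a vertical line.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.null_distribution <- function(object, observed = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object), ggplot2::aes(.data$accuracy)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70", color = "grey40") +
    ggplot2::geom_vline(xintercept = object$q95, linetype = "dashed") +
    ggplot2::labs(x = "permuted accuracy", y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, color = "#b2182b")
  }
  p
}
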