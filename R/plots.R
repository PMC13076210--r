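#' Heatmap of ion-series proportions per fragmentation method
#'
#' @param proportions Output of [annotation_proportions()].
#' @return A ggplot object.
#' @export
plot_annotation_proportions <- function(proportions) {
  ggplot2::ggplot(proportions,
                  ggplot2::aes(x = .data$series, y = .data$method,
                               fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$proportion)), size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::labs(x = "ion series", y = NULL,
                  fill = "mean\nproportion",
                  title = "Mean proportion of annotated peaks per ion series") +
    ggplot2::theme_minimal()
}

#' Target/decoy histograms of fragment-ion ratios
#'
#' Mirrors the rescoring diagnostic: the observed/theoretical ratio
#' (all theoretical fragments) stacked over the predicted-ion ratio
#' (only fragments the model predicts), split by target/decoy status.
#'
#' @param features Feature tibble with `obs_theo_ratio`,
#'   `pred_ratio`, `is_decoy`.
#' @return A ggplot object.
#' @export
plot_ratio_histograms <- function(features) {
  long <- tidyr::pivot_longer(
    features[, c("obs_theo_ratio", "pred_ratio", "is_decoy")],
    cols = c("obs_theo_ratio", "pred_ratio"),
    names_to = "ratio_type", values_to = "ratio"
  )
  long$ratio_type <- factor(
    long$ratio_type, levels = c("obs_theo_ratio", "pred_ratio"),
    labels = c("observed / theoretical", "observed & predicted / predicted")
  )
  long$class <- ifelse(long$is_decoy, "decoy", "target")
  ggplot2::ggplot(dplyr::filter(long, is.finite(.data$ratio)),
                  ggplot2::aes(x = .data$ratio, fill = .data$class)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.55,
                            bins = 40, boundary = 0) +
    ggplot2::facet_wrap(~.data$ratio_type, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "ratio", y = "PSMs", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Recovered true-positive fraction across FDR thresholds
#'
#' @param ... Named [recovered_tp_fraction()] tibbles (e.g.
#'   `base = ..., rescored = ...`).
#' @return A ggplot object.
#' @export
plot_recovered_tp <- function(...) {
  curves <- dplyr::bind_rows(list(...), .id = "scoring")
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$fdr, y = .data$recovered,
                               colour = .data$scoring)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "PSM-level FDR threshold",
                  y = "fraction of recoverable true positives",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Mirror plot of observed versus predicted fragment intensities
#'
#' @param target Observed target vector (masked entries ignored).
#' @param prediction Predicted vector over the same dictionary.
#' @param dictionary Ion dictionary (for m/z-free positioning the
#'   x axis is the dictionary index, coloured by series).
#' @return A ggplot object.
#' @export
plot_mirror <- function(target, prediction, dictionary) {
  m <- target != -1
  df <- tibble::tibble(
    index = rep(dictionary$index[m], 2L),
    series = rep(dictionary$series[m], 2L),
    intensity = c(target[m], -pmax(prediction[m], 0)),
    which = rep(c("observed", "predicted"), each = sum(m))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, xend = .data$index,
                                   y = 0, yend = .data$intensity,
                                   colour = .data$series)) +
    ggplot2::geom_segment() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "ion dictionary index",
                  y = "intensity (up: observed, down: predicted)",
                  colour = "series") +
    ggplot2::theme_minimal()
}

#' Training-history plot for a fitted intensity model
#'
#' @param object Fitted `intensity_model`.
#' @param ... Unused.
#' @return A ggplot object of train/validation loss per epoch.
#' @export
autoplot.intensity_model <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history,
                              cols = -"epoch", names_to = "set",
                              values_to = "loss")
  ggplot2::ggplot(dplyr::filter(long, !is.na(.data$loss)),
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "masked spectral distance",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
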