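# ggplot2 convenience figures for each result type.

#' Plot a recording trace
#'
#' @param object An [eeg_recording()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eeg_recording
#' @export
autoplot.eeg_recording <- function(object, ...) {
  fsr <- attr(object, "fs")
  df <- tibble::tibble(time_s = object$sample / fsr, amplitude = object$amplitude)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "amplitude",
                  title = attr(object, "subject_id")) +
    ggplot2::theme_minimal()
}

#' Band-power boxplots by group
#'
#' Relative band power per diagnostic group, one panel per band --
#' the pipeline's group-contrast summary figure.
#'
#' @param features Feature tibble with a `group` column (ideally
#'   relative power).
#' @param bands Band columns to show (default the ten canonical bands).
#' @return A ggplot.
#' @export
plot_band_powers <- function(features, bands = eeg_bands()$band) {
  bands <- intersect(bands, names(features))
  long <- tidyr::pivot_longer(features, dplyr::all_of(bands),
                              names_to = "band", values_to = "power")
  long$band <- factor(long$band, levels = eeg_bands()$band)
  ggplot2::ggplot(long, ggplot2::aes(.data$group, .data$power, fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~band, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "relative power") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none",
                   axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Feature-test overview plot
#'
#' Adjusted p-values across the 55 candidate features on a -log10
#' scale, with the significance level and selected features marked.
#'
#' @param object An `eeg_feature_tests` from [select_features()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eeg_feature_tests
#' @export
autoplot.eeg_feature_tests <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$feature <- factor(df$feature, levels = feature_names())
  alpha <- attr(object, "alpha") %||% 0.05
  ggplot2::ggplot(df, ggplot2::aes(.data$feature, -log10(pmax(.data$p_adjusted, 1e-300)),
                                   colour = .data$selected)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(x = NULL, y = expression(-log[10]~p[adj])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}

#' Confusion-matrix heatmap of a cross-validation run
#'
#' @param object An `eeg_cv` from [cross_validate()].
#' @param split `"test"` (default) or `"train"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eeg_cv
#' @export
autoplot.eeg_cv <- function(object, split = c("test", "train"), ...) {
  split <- match.arg(split)
  cm <- if (split == "test") object$confusion_test else object$confusion_train
  df <- as.data.frame(as.table(cm))
  names(df) <- c("truth", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = paste("pooled", split, "confusion")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
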