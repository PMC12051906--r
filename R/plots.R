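#' Plot a PSD spectrogram
#'
#' Heat map of the windows x frequency-bins dB matrix from
#' [psd_spectrogram()].
#'
#' @param spec Matrix returned by [psd_spectrogram()].
#' @return A ggplot object.
#' @export
plot_spectrogram <- function(spec) {
  df <- data.frame(
    time = rep(as.numeric(rownames(spec)), times = ncol(spec)),
    freq = rep(as.numeric(colnames(spec)), each = nrow(spec)),
    db = as.vector(spec))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq,
                                   fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot repeated-run AUCs
#'
#' One point per repeat plus the mean for an [run_repeated_experiment()]
#' result.
#'
#' @param object An `eval_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_result <- function(object, ...) {
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$seed), y = .data$auc)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = object$mean_auc, linetype = 2) +
    ggplot2::labs(x = "seed", y = "subject-averaged AUC",
                  title = object$method) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the transfer benchmark ladder
#'
#' Mean AUC with a +/- 1 SD ribbon per variant for a
#' [run_transfer_benchmark()] result, ordered as the ablation ladder.
#'
#' @param object A `benchmark_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.benchmark_result <- function(object, ...) {
  s <- attr(object, "summary")
  order_lvls <- c("trunc_source_only", "none", "ea", "ea_da", "msa")
  s$variant <- factor(s$variant, levels = intersect(order_lvls, s$variant))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$variant, y = .data$mean_auc)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_auc - .data$sd_auc,
      ymax = .data$mean_auc + .data$sd_auc)) +
    ggplot2::labs(x = NULL, y = "mean target AUC") +
    ggplot2::theme_minimal()
}
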