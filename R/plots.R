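#' Plot mapping-error rate against the allele-frequency threshold
#'
#' @param report an `experiment_report` from [run_experiment()] containing
#'   `threshold`-mode cells
#' @export
plot_error_by_threshold <- function(report) {
  cells <- report$cells[report$cells$mode == "threshold", , drop = FALSE]
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$threshold,
                                      y = .data$error_rate)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::labs(x = "alternate allele frequency threshold",
                  y = "proportion of incorrectly mapped reads") +
    ggplot2::theme_classic()
}

#' Plot a pseudo-ROC curve
#'
#' @param roc a [pseudo_roc()] tibble (or named list of them)
#' @export
plot_pseudo_roc <- function(roc) {
  if (!is.data.frame(roc)) {
    roc <- dplyr::bind_rows(roc, .id = "set")
  } else roc$set <- "alignments"
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$FPR, y = .data$TPR,
                                    colour = .data$set)) +
    ggplot2::geom_path() + ggplot2::geom_point() +
    ggplot2::labs(x = "false-positive mapping rate",
                  y = "true-positive mapping rate") +
    ggplot2::theme_classic()
}

#' Plot allelic-ratio profiles by signed variant length
#'
#' @param profiles named list of [allelic_ratio_profile()] tibbles (e.g.
#'   `list(graph = ..., linear = ...)`)
#' @export
plot_bias_profile <- function(profiles) {
  tb <- dplyr::bind_rows(profiles, .id = "mapping")
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$length, y = .data$mean_ratio,
                                   colour = .data$mapping)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_ratio - .data$sem,
      ymax = .data$mean_ratio + .data$sem), size = 0.3) +
    ggplot2::labs(x = "variant length (deletions < 0 < insertions)",
                  y = "allelic ratio (alt / total)") +
    ggplot2::theme_classic()
}
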