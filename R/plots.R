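# --- ggplot2 visualizations --------------------------------------------------

#' Gain curve of a threshold search
#'
#' Information gain at every candidate cutpoint, with the selected
#' threshold marked — the diagnostic view of the small/large
#' dichotomization.
#'
#' @param object An `fcd_threshold` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.fcd_threshold <- function(object, ...) {
  ggplot2::ggplot(object$gain_curve,
                  ggplot2::aes(x = .data$candidate, y = .data$gain)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$threshold, color = "red",
                        linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "candidate threshold (mm^3, log scale)",
                  y = "information gain (bits)",
                  title = sprintf("T = %.0f mm^3, gain = %.3f bits",
                                  object$threshold, object$gain)) +
    ggplot2::theme_minimal()
}

#' Volume / report-label scatter with the selected threshold
#'
#' One point per lesion, volume on a log axis against its MRI-report
#' label, with the small/large cutpoint marked.
#'
#' @param thr An `fcd_threshold` object.
#' @return A ggplot.
#' @export
plot_threshold_scatter <- function(thr) {
  stopifnot(inherits(thr, "fcd_threshold"))
  d <- thr$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$volume,
                                  y = .data$report_positive,
                                  color = .data$size)) +
    ggplot2::geom_jitter(height = 0.08, width = 0, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = thr$threshold, color = "red",
                        linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lesion volume (mm^3, log scale)",
                  y = "MRI report positive", color = "size") +
    ggplot2::theme_minimal()
}

#' Recovery-experiment diagnostics
#'
#' Histograms of the recovered threshold and odds ratio across
#' replicates, with the ground truth marked.
#'
#' @param object An `fcd_recovery` object.
#' @param what `"threshold"` or `"odds_ratio"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.fcd_recovery <- function(object, what = c("threshold", "odds_ratio"),
                                  ...) {
  what <- match.arg(what)
  reps <- object$replicates[is.na(object$replicates$error), ]
  if (what == "threshold") {
    ggplot2::ggplot(reps, ggplot2::aes(x = .data$threshold)) +
      ggplot2::geom_histogram(bins = 30, fill = "grey70", color = "grey30") +
      ggplot2::geom_vline(xintercept = object$config$threshold_true,
                          color = "red", linetype = 2) +
      ggplot2::labs(x = "recovered threshold (mm^3)", y = "replicates") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(reps[!reps$separated, ],
                    ggplot2::aes(x = .data$or_small)) +
      ggplot2::geom_histogram(bins = 30, fill = "grey70", color = "grey30") +
      ggplot2::geom_vline(xintercept = object$config$or_small,
                          color = "red", linetype = 2) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "recovered small-lesion odds ratio (log scale)",
                    y = "replicates") +
      ggplot2::theme_minimal()
  }
}

#' Log-volume distribution by SRE group
#'
#' @param run An `fcd_run` object.
#' @return A ggplot.
#' @export
plot_volume_by_group <- function(run) {
  stopifnot(inherits(run, "fcd_run"))
  d <- run$cohort[!is.na(run$cohort$lesion_log10), ]
  d$group <- ifelse(d$sre, "SRE", "non-SRE")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$lesion_log10)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6,
                         ggplot2::aes(color = .data$size)) +
    ggplot2::geom_hline(yintercept = log10(run$threshold$threshold),
                        linetype = 2, color = "red") +
    ggplot2::labs(x = NULL, y = "log10 normalized lesion volume (mm^3)",
                  color = "size") +
    ggplot2::theme_minimal()
}
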