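# ggplot2 displays for audit and experiment results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-category record counts of a curation audit
#'
#' @param object A `curation_audit`.
#' @param ... Unused.
#' @return A ggplot: category bar chart with counts printed above bars.
#' @export
autoplot.curation_audit <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "records",
                  title = sprintf("%d of %d records not supported (%.2f%%)",
                                  object$error$n_errors, object$error$n,
                                  object$error$percent)) +
    ggplot2::theme_minimal()
}

#' Per-record comparison of database and literature log10(KD)
#'
#' Scatter of database versus literature-corrected values, one point per
#' record with a literature value (the `NoKD` and `MultisiteKD`
#' categories are necessarily absent).
#'
#' @param audit A `curation_audit` or the tibble from
#'   [categorize_entries()].
#' @return A ggplot.
#' @export
plot_kd_comparison <- function(audit) {
  rec <- if (inherits(audit, "curation_audit")) audit$records else audit
  rec <- rec[!is.na(rec$corrected_molar), , drop = FALSE]
  ggplot2::ggplot(rec, ggplot2::aes(x = log10(.data$corrected_molar),
                                    y = log10(.data$db_molar),
                                    colour = .data$category)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "literature log10(KD) [M]",
                  y = "database log10(KD) [M]", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot mean +/- sd pooled correlation per subset and separation
#'
#' @param object A `kd_experiment`.
#' @param ... Unused.
#' @return A ggplot of the cross-validated Pearson correlation against
#'   the minimum cluster-separation threshold, one line per subset,
#'   faceted by model.
#' @export
autoplot.kd_experiment <- function(object, ...) {
  summ <- summarize_experiment(object)
  pd <- ggplot2::position_dodge(width = 0.02)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$separation, y = .data$mean_r,
                                     colour = .data$subset,
                                     group = .data$subset)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_r - .data$sd_r,
                                        ymax = .data$mean_r + .data$sd_r),
                           width = 0.015, position = pd) +
    ggplot2::geom_line(position = pd) +
    ggplot2::geom_point(position = pd) +
    ggplot2::facet_wrap(~ .data$model) +
    ggplot2::labs(x = "minimum cluster separation",
                  y = "pooled Pearson r (mean ± sd over trials)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
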