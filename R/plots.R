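# ggplot2 displays for the main result types.  Styling follows the usual
# validation-figure conventions: alt-fraction dot plots with the tier
# thresholds, per-exon log2 ratio panels, and coverage QC bars.

#' Plot observed alternative-allele fractions along the gene
#'
#' Dot plot of the observed alt fraction of every evaluated truth variant
#' by position, with the standard and relaxed detection thresholds drawn
#' as horizontal lines and exon boundaries as a rug; the figure that shows
#' at a glance which sites competitive mapping pushes below threshold.
#'
#' @param experiment A `validation_experiment`.
#' @return A ggplot object.
#' @export
plot_alt_fractions <- function(experiment) {
  truth <- experiment$truth
  pv <- tidy(experiment)
  th <- experiment$config$thresholds
  df <- dplyr::left_join(
    truth[, c("pos", "class")],
    pv[, c("pos", "called_fraction", "status")], by = "pos")
  # fall back to pileup-observed fractions for uncalled sites
  ms <- experiment$matched_sites
  df$fraction <- df$called_fraction
  miss <- is.na(df$fraction) & df$pos %in% ms$pos
  df$fraction[miss] <- ms$observed_fraction[match(df$pos[miss], ms$pos)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$fraction,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = th$standard_alt_fraction,
                        linetype = "solid") +
    ggplot2::geom_hline(yintercept = th$relaxed_alt_fraction,
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_rug(data = experiment$locus$exons,
                      ggplot2::aes(x = .data$start), inherit.aes = FALSE,
                      sides = "b", alpha = 0.5) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "master position (bp)",
                  y = "alternative read fraction",
                  colour = "variant class") +
    ggplot2::theme_minimal()
}

#' Plot per-target log2 depth ratios against the control panel
#'
#' One point per control per target, with the calling thresholds; the
#' standard readout of depth-of-coverage CNV detection.
#'
#' @param ratios Tibble from [normalize_and_ratio()].
#' @param params A [cnv_params()] (for the threshold lines).
#' @return A ggplot object.
#' @export
plot_cnv_ratios <- function(ratios, params = cnv_params()) {
  ggplot2::ggplot(ratios, ggplot2::aes(x = .data$name, y = .data$log2_ratio)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6, na.rm = TRUE) +
    ggplot2::stat_summary(fun = stats::median, geom = "point", colour = "red",
                          size = 2, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = c(params$log2_del, params$log2_amp),
                        linetype = "dashed") +
    ggplot2::labs(x = "target", y = "log2(index / control)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Plot coverage QC per target
#'
#' @param qc Tibble from [coverage_qc()].
#' @return A ggplot object.
#' @export
plot_coverage_qc <- function(qc) {
  agg <- attr(qc, "aggregate")
  ggplot2::ggplot(qc, ggplot2::aes(x = .data$name, y = .data$mean_depth,
                                   fill = .data$lowcov)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = agg$floor, linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40",
                                          `TRUE` = "firebrick"),
                               name = "below floor") +
    ggplot2::labs(x = "target", y = "mean depth (x)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot()` dispatches to the matching `plot_*` display:
#' a `validation_experiment` draws the alt-fraction dot plot and
#' `cnv_calls` draw their per-target ratio panel.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-pseudocall
NULL

#' @rdname autoplot-pseudocall
#' @export
autoplot.validation_experiment <- function(object, ...) {
  plot_alt_fractions(object)
}

#' @rdname autoplot-pseudocall
#' @param ratios Ratio tibble to plot (defaults to the per-target table).
#' @export
autoplot.cnv_calls <- function(object, ratios = NULL, ...) {
  pt <- attr(object, "per_target")
  df <- tibble(name = pt$name, log2_ratio = pt$median_log2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$name, y = .data$log2_ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(-0.6, 0.6), linetype = "dashed") +
    ggplot2::labs(x = "target", y = "median log2 ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
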