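#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Biplot of a PCA position/oligo profile
#'
#' Positions are drawn as points in the plane of the first two components
#' and kmer loadings as labelled arrows from the origin, the joint display
#' used to localize cis-elements around the cleavage site.
#'
#' @param object a [pa_pca()] profile.
#' @param label_threshold label only kmers whose loading length reaches
#'   this fraction of the maximum (default 0.5).
#' @param arrow_scale multiplier stretching loading arrows for readability.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.pa_pca_profile <- function(object, label_threshold = 0.5,
                                    arrow_scale = NULL, ...) {
  pos <- object$positions
  lds <- object$loadings
  if (is.null(arrow_scale))
    arrow_scale <- 0.8 * max(pos$distance) /
      max(lds$length, .Machine$double.eps)
  lab <- lds[lds$length >= label_threshold * max(lds$length), ]
  ggplot2::ggplot(pos, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_point(colour = "steelblue", alpha = 0.7) +
    ggplot2::geom_segment(
      data = lds,
      ggplot2::aes(x = 0, y = 0, xend = arrow_scale * .data$pc1,
                   yend = arrow_scale * .data$pc2),
      colour = "firebrick", alpha = 0.5,
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_text(
      data = lab,
      ggplot2::aes(x = arrow_scale * .data$pc1 * 1.08,
                   y = arrow_scale * .data$pc2 * 1.08, label = .data$kmer),
      colour = "firebrick", size = 3
    ) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$variance_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$variance_explained[2]),
      title = sprintf("%d-mer PCA over %s", object$k, format(object$region))
    ) +
    ggplot2::theme_minimal()
}

#' Position profile of origin distances
#'
#' Line plot of each position's distance from the origin in the first two
#' components — the per-position localization signal in which cis-element
#' peaks (DUR, PUR, CS, DR) appear.
#'
#' @param profile a [pa_pca()] profile.
#' @param peaks optional [pa_detect_peaks()] result to highlight.
#' @return A ggplot.
#' @export
plot_position_profile <- function(profile, peaks = NULL) {
  p <- ggplot2::ggplot(profile$positions,
                       ggplot2::aes(x = .data$position,
                                    y = .data$distance)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "position relative to cleavage site",
                  y = "PCA origin distance") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks))
    p <- p + ggplot2::geom_vline(data = peaks,
                                 ggplot2::aes(xintercept = .data$peak),
                                 colour = "firebrick", linetype = "dotted")
  p
}

#' ROC-style threshold curve
#'
#' @param object a [pa_roc()] result.
#' @param ... unused.
#' @return A ggplot of Sn and Sp against the decision threshold.
#' @export
plot_roc <- function(object, ...) {
  long <- tidyr::pivot_longer(object[, c("threshold", "sn", "sp")],
                              c("sn", "sp"), names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold,
                                     y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "youden_threshold"),
                        linetype = "dotted") +
    ggplot2::labs(x = "decision threshold", y = "percent",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Average occupancy profiles of real and false sites
#'
#' Mean per-position occupancy with a pointwise 95% band (normal
#' approximation across sequences), the display in which the nucleosome
#' dip at real sites is read.
#'
#' @param data a [pa_dataset()] with a `track` list-column.
#' @return A ggplot.
#' @export
plot_occupancy_profile <- function(data) {
  region <- pa_dataset_region(data)
  pos <- pa_from_index(seq_len(region$length), region)
  prof <- purrr::map_dfr(split(data$track, data$label), function(tr) {
    m <- do.call(rbind, tr)
    mu <- colMeans(m)
    se <- apply(m, 2, stats::sd) / sqrt(nrow(m))
    tibble::tibble(position = pos, mean = mu,
                   lo = mu - 1.96 * se, hi = mu + 1.96 * se)
  }, .id = "label")
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$position, y = .data$mean,
                                     colour = .data$label,
                                     fill = .data$label)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position relative to cleavage site",
                  y = "occupancy probability", colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Scan profile with called sites
#'
#' @param windows a [pa_scan()] result.
#' @param true_site optional known cleavage position to mark.
#' @return A ggplot of per-window probability along the sequence.
#' @export
plot_scan <- function(windows, true_site = NULL) {
  calls <- attr(windows, "calls")
  p <- ggplot2::ggplot(windows, ggplot2::aes(x = .data$site,
                                             y = .data$prob)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "candidate cleavage position",
                  y = "site probability") +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls))
    p <- p + ggplot2::geom_point(data = calls, colour = "firebrick")
  if (!is.null(true_site))
    p <- p + ggplot2::geom_vline(xintercept = true_site,
                                 linetype = "dashed", colour = "grey40")
  p
}
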