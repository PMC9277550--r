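#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot PCA scores
#'
#' Score plot of the first two components with percent variance in the
#' axis labels.
#'
#' @param object A [pca()] result.
#' @param colour Optional vector (length = samples) mapped to point
#'   colour, e.g. stage labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_ord <- function(object, colour = NULL, ...) {
  d <- object$scores
  if (ncol(d) < 3) stop("need at least two components to plot", call. = FALSE)
  if (!is.null(colour)) d$colour <- colour
  ve <- round(100 * object$var_explained[1:2], 1)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", ve[1]),
                  y = sprintf("PC2 (%.1f%%)", ve[2])) +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour), size = 2) +
      ggplot2::labs(colour = NULL)
  }
}

#' VIP score plot for a PLS fit
#'
#' Predictors ordered by VIP with the conventional VIP = 1 reference
#' line.
#'
#' @param object A [fit_pls2()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pls_fit <- function(object, ...) {
  d <- tibble::tibble(term = names(object$vip), vip = unname(object$vip))
  d$term <- stats::reorder(d$term, d$vip)
  ggplot2::ggplot(d, ggplot2::aes(.data$vip, .data$term)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$vip,
                                       yend = .data$term),
                          colour = "grey70") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = "VIP", y = NULL) +
    ggplot2::theme_minimal()
}

#' OAV band summary plot
#'
#' @param oav Output of [compute_oav()].
#' @return A ggplot object: compounds with defined OAV on a log10 axis,
#'   coloured by band.
#' @export
plot_oav <- function(oav) {
  d <- oav[!is.na(oav$oav), , drop = FALSE]
  d$compound <- stats::reorder(d$compound, d$oav)
  ggplot2::ggplot(d, ggplot2::aes(.data$oav, .data$compound,
                                  colour = .data$band)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = c(0.1, 1), linetype = 2,
                        colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odor activity value", y = NULL, colour = "band") +
    ggplot2::theme_minimal()
}

#' Succession area chart
#'
#' Stage-mean relative abundances of the most abundant taxa as a
#' stacked area chart, the standard way to display community
#' succession over fermentation.
#'
#' @param t An [abund_tbl].
#' @param n Number of taxa shown individually; the rest are pooled.
#' @return A ggplot object.
#' @export
plot_succession <- function(t, n = 15) {
  rel <- if (abund_mode(t) == "counts") to_relative(t) else t
  m <- abund_matrix(rel)
  means <- sort(colMeans(m), decreasing = TRUE)
  keep <- names(means)[seq_len(min(n, length(means)))]
  long <- tidyr::pivot_longer(tibble::as_tibble(rel),
                              cols = -c("sample_id", "stage", "replicate"),
                              names_to = "taxon", values_to = "abundance")
  long$taxon <- ifelse(long$taxon %in% keep, long$taxon, "Other")
  d <- dplyr::summarise(dplyr::group_by(long, .data$stage, .data$taxon),
                        abundance = mean(.data$abundance), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$stage, .data$abundance,
                                  fill = .data$taxon, group = .data$taxon)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "fermentation stage", y = "mean relative abundance",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
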