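# ggplot2 views of the result types.

cas_family_palette <- function() {
  # warm = effector, cold = adaptation, fuchsia = RT (field convention)
  c(cas10 = "#d73027", csm2 = "#f46d43", csm3 = "#fdae61",
    csm4 = "#fee090", csm5 = "#f98e52", cmr1 = "#f46d43",
    cmr3 = "#fdae61", cmr4 = "#fee090", cmr5 = "#f98e52",
    cmr6 = "#e34a33", cas1 = "#4575b4", cas2 = "#74add1",
    cas6 = "#abd9e9", RT = "#d01c8b", `RT-cas1` = "#d01c8b",
    `cas6-RT-cas1` = "#d01c8b", decoy = "grey70", other = "grey70")
}

#' Gene-arrow diagram of a locus
#'
#' Draws the retained cas genes (coloured by family, RT in fuchsia) and
#' arrays (hatched boxes) of one extracted locus along its genomic span.
#'
#' @param locus a `locus` from [extract_locus()].
#' @return A ggplot object.
#' @export
plot_locus <- function(locus) {
  f <- locus$features
  f$fill <- ifelse(f$family %in% names(cas_family_palette()),
                   f$family, "other")
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = f,
      ggplot2::aes(x = .data$start, xend = .data$end, y = 1, yend = 1,
                   colour = .data$fill),
      linewidth = 6, lineend = "butt") +
    ggplot2::geom_text(
      data = f,
      ggplot2::aes(x = (.data$start + .data$end) / 2, y = 1.12,
                   label = .data$family),
      angle = 45, hjust = 0, size = 3) +
    ggplot2::scale_colour_manual(values = cas_family_palette(),
                                 guide = "none") +
    ggplot2::ylim(0.7, 1.45) +
    ggplot2::labs(x = sprintf("%s:%d-%d", locus$region$contig,
                              locus$region$start, locus$region$end),
                  y = NULL,
                  title = sprintf("%s locus, fusion %s", locus$subtype,
                                  locus$fusion_class)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
  if (!is.null(locus$arrays) && nrow(locus$arrays)) {
    p <- p + ggplot2::geom_rect(
      data = locus$arrays,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = 0.88, ymax = 1.12),
      fill = NA, colour = "black", linetype = "22")
  }
  p
}

#' Distribution heat map (clade x effector x fusion class)
#'
#' @param distribution tibble from [tabulate_distribution()].
#' @return A ggplot object.
#' @export
plot_distribution <- function(distribution) {
  ggplot2::ggplot(distribution,
                  ggplot2::aes(x = .data$fusion_class, y = .data$clade,
                               fill = .data$n)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$effector)) +
    ggplot2::scale_fill_gradient(low = "#f7fbff", high = "#2171b5",
                                 guide = "none") +
    ggplot2::labs(x = "RT fusion class", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Array map along contigs
#'
#' @param object a `crispr_arrays` tibble.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.crispr_arrays <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$start, xend = .data$end,
                               y = .data$contig, yend = .data$contig,
                               colour = .data$orientation)) +
    ggplot2::geom_segment(linewidth = 4) +
    ggplot2::geom_text(ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    label = paste0(.data$band, "/",
                                                   .data$criterion)),
                       vjust = -1, size = 3) +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = "orientation") +
    ggplot2::theme_minimal()
}

#' Clade sizes and supports of a partition
#'
#' @param object a [clade_partition()].
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.clade_partition <- function(object, ...) {
  counts <- dplyr::count(as_tibble(object), .data$clade)
  ggplot2::ggplot(counts, ggplot2::aes(x = stats::reorder(.data$clade,
                                                          -.data$n),
                                       y = .data$n)) +
    ggplot2::geom_col(fill = "#4575b4") +
    ggplot2::labs(x = NULL, y = "leaves") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
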