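#' Plot a lineage forest
#'
#' Draws each track as a horizontal segment over its frame span, with
#' vertical connectors for mother-daughter relations.
#'
#' @param x a [labeled_sequence] with lineage or a `tracking_graph`.
#' @return a ggplot object.
#' @export
plot_lineage <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_lineage requires ggplot2")
  if (inherits(x, "tracking_graph")) x <- as_labeled_sequence(x)
  lin <- x$lineage
  if (!nrow(lin)) stop("no lineage records to plot")
  # order tracks into lineage families for a tidy vertical layout
  lin <- lin[order(lin$parent, lin$begin, lin$label), ]
  lin$ypos <- seq_len(nrow(lin))
  seg <- lin
  con <- merge(lin, lin, by.x = "parent", by.y = "label",
               suffixes = c("", ".p"))
  p <- ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$begin, xend = .data$end,
                                       y = .data$ypos, yend = .data$ypos)) +
    ggplot2::geom_text(ggplot2::aes(x = .data$begin, y = .data$ypos,
                                    label = .data$label),
                       hjust = 1.2, size = 2.8) +
    ggplot2::labs(x = "frame", y = NULL, title = "cell lineage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (nrow(con))
    p <- p + ggplot2::geom_segment(
      data = con,
      ggplot2::aes(x = .data$begin, xend = .data$begin,
                   y = .data$ypos.p, yend = .data$ypos),
      linetype = "dotted")
  p
}
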