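#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Clade size distribution plot
#'
#' @param object A `clade_partition`.
#' @param ... Unused.
#' @return A ggplot: histogram of clade sizes with the orphan count in the
#'   subtitle.
#' @method autoplot clade_partition
#' @export
autoplot.clade_partition <- function(object, ...) {
  sizes <- tibble(size = lengths(object$clades))
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "steelblue", colour = "white") +
    ggplot2::labs(
      x = "clade size (genes)", y = "clades",
      title = "Clade size distribution",
      subtitle = paste0(length(object$clades), " clades, ",
                        length(object$orphans), " orphans (threshold ",
                        object$threshold, ")")
    )
}

#' Within- vs between-cluster identity plot
#'
#' @param split Result of [identity_split()].
#' @return A ggplot: identity densities by relation with mean markers.
#' @export
plot_identity_split <- function(split) {
  means <- tibble(relation = c("within", "between"),
                  m = c(split$mean_within, split$mean_between))
  ggplot2::ggplot(split$pairs,
                  ggplot2::aes(x = .data$identity, colour = .data$relation)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(data = means,
                        ggplot2::aes(xintercept = .data$m,
                                     colour = .data$relation),
                        linetype = "dashed") +
    ggplot2::labs(x = "pairwise identity", y = "density",
                  title = "Gene identity within vs between physical clusters")
}

#' Presence-call heatmap
#'
#' @param calls Output of [call_presence()].
#' @return A ggplot tile map of calls over genes x samples.
#' @export
plot_presence <- function(calls) {
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$sample_id, y = .data$gene_id,
                                      fill = .data$call)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(Present = "#2b8cbe",
                                          Partial = "#fec44f",
                                          Deleted = "#de2d26")) +
    ggplot2::labs(x = NULL, y = NULL, title = "Gene presence across samples") +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
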