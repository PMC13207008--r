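# ggplot2 summaries of the main result types.

#' Volcano plot of a differential-expression result
#'
#' @param de A `cerna_de` tibble from [nb_test()].
#' @param lfc_threshold,alpha Thresholds drawn and used for coloring;
#'   default to the values stored in the object.
#' @return A ggplot.
#' @export
plot_volcano <- function(de, lfc_threshold = NULL, alpha = NULL) {
  lfc_threshold <- lfc_threshold %||% attr(de, "lfc_threshold") %||% 1
  alpha <- alpha %||% attr(de, "alpha") %||% 0.05
  df <- as_tibble(de) |> filter(!is.na(.data$p_value))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2FC, -log10(.data$p_value),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::geom_vline(xintercept = c(-lfc_threshold, lfc_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = unique(df$contrast)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cerna_de <- function(object, ...) plot_volcano(object, ...)

#' Genomic-class composition of a circRNA catalog
#'
#' @param catalog Classified catalog (after [classify_circ()]).
#' @return A ggplot bar chart.
#' @export
plot_catalog_classes <- function(catalog) {
  cc <- catalog_summaries(catalog)$class_counts
  ggplot2::ggplot(cc, ggplot2::aes(.data$genomic_class, .data$n,
                                   fill = .data$genomic_class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "circRNAs") +
    ggplot2::theme_minimal()
}

#' Dot plot of pathway enrichment
#'
#' @param enrichment A [fisher_enrich()] result.
#' @param top_n Pathways shown (by p-value).
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrichment, top_n = 15) {
  df <- as_tibble(enrichment) |>
    arrange(.data$p_value) |>
    head(top_n) |>
    mutate(pathway_name = factor(.data$pathway_name,
                                 rev(unique(.data$pathway_name))))
  ggplot2::ggplot(df, ggplot2::aes(-log10(.data$p_value), .data$pathway_name,
                                   size = .data$k, colour = .data$enriched)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "-log10 p", y = NULL, size = "genes") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cerna_enrichment <- function(object, ...) plot_enrichment(object, ...)

#' circRNA hub degrees of a ceRNA network
#'
#' @param network A `cerna_network`.
#' @param top_n circRNAs shown.
#' @return A ggplot.
#' @export
plot_hubs <- function(network, top_n = 15) {
  df <- head(hub_ranking(network), top_n) |>
    mutate(circ_id = factor(.data$circ_id, rev(.data$circ_id)))
  ggplot2::ggplot(df, ggplot2::aes(.data$n_mirs, .data$circ_id,
                                   fill = .data$is_hub)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "distinct miRNA partners", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cerna_network <- function(object, ...) plot_hubs(object, ...)

#' Expression profile of one ceRNA axis across samples
#'
#' Plots the normalized (log2) expression of the axis circRNA, miRNA and
#' mRNA across samples grouped by condition, the visual counterpart of the
#' sponge sign pattern.
#'
#' @param expr Named list of normalized expression matrices (`circ`, `mir`,
#'   `mrna`), e.g. `report$network$expr`.
#' @param samples Sample sheet tibble.
#' @param axis One row of an axis tibble ([enumerate_axes()]).
#' @return A ggplot.
#' @export
plot_axis_profiles <- function(expr, samples, axis) {
  stopifnot(nrow(axis) == 1L)
  df <- purrr::imap(
    list(circ = axis$circ_id, mir = axis$mir_id, mrna = axis$mrna_id),
    function(id, cls) {
      tibble(sample = colnames(expr[[cls]]), molecule = paste0(cls, ": ", id),
             value = expr[[cls]][id, ])
    }) |>
    purrr::list_rbind() |>
    left_join(samples, by = "sample")
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$value)) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.08),
                        alpha = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "#c0392b") +
    ggplot2::facet_wrap(~molecule, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "log2 normalized expression",
                  title = axis$axis) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
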