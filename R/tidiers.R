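# broom-style tidiers for fitted/derived objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a differential-expression result
#'
#' @param x A `cerna_de` object from [nb_test()].
#' @param ... Unused.
#' @return The underlying results tibble (one row per feature).
#' @export
tidy.cerna_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cerna_de")
  as_tibble(out)
}

#' One-row summary of a differential-expression result
#'
#' @inheritParams tidy.cerna_de
#' @return Tibble with the contrast, feature/call counts and the common
#'   dispersion estimate.
#' @export
glance.cerna_de <- function(x, ...) {
  tibble(
    contrast = x$contrast[1],
    n_features = nrow(x),
    n_tested = sum(!is.na(x$p_value)),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    common_dispersion = attr(x, "common_dispersion"),
    lfc_threshold = attr(x, "lfc_threshold"),
    alpha = attr(x, "alpha")
  )
}

#' Tidy a pathway-enrichment result
#'
#' @param x A `cerna_enrichment` object from [fisher_enrich()].
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.cerna_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cerna_enrichment")
  as_tibble(out)
}

#' One-row summary of a pathway-enrichment result
#'
#' @inheritParams tidy.cerna_enrichment
#' @return Tibble with pathway counts and the query/background sizes.
#' @export
glance.cerna_enrichment <- function(x, ...) {
  tibble(
    n_pathways = nrow(x),
    n_enriched = sum(x$enriched),
    n_query = if (nrow(x)) x$n[1] else 0L,
    n_background = if (nrow(x)) x$N[1] else 0L,
    alpha = attr(x, "alpha")
  )
}

#' Tidy a ceRNA network (edge list)
#'
#' @param x A `cerna_network`.
#' @param ... Unused.
#' @return The edge tibble.
#' @export
tidy.cerna_network <- function(x, ...) as_tibble(x$edges)

#' One-row summary of a ceRNA network
#'
#' @inheritParams tidy.cerna_network
#' @return Tibble of node counts by type and edge counts by type.
#' @export
glance.cerna_network <- function(x, ...) {
  tc <- table(factor(x$nodes$type, c("circ", "mir", "mrna")))
  te <- table(factor(x$edges$edge_type, c("circ_mir", "mir_mrna")))
  tibble(n_circ = as.integer(tc["circ"]), n_mir = as.integer(tc["mir"]),
         n_mrna = as.integer(tc["mrna"]),
         n_circ_mir_edges = as.integer(te["circ_mir"]),
         n_mir_mrna_edges = as.integer(te["mir_mrna"]))
}
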