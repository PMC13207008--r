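# Fisher's-exact (hypergeometric upper-tail) pathway over-representation of
# gene sets against a pathway-membership table.

#' Pathway over-representation by Fisher's exact test
#'
#' For each pathway, tests whether the query gene set is over-represented
#' among the pathway members relative to the background:
#' `p = P[X >= k]` with `X ~ Hypergeometric(N, K, n)` where `N` is the
#' background size, `K` the background genes in the pathway, `n` the query
#' size and `k` the query genes in the pathway (the one-sided Fisher test).
#' Query genes absent from the background are dropped with a warning.
#'
#' @param query_genes Character vector of query gene ids (duplicates are
#'   collapsed).
#' @param pathway_table Tibble with `gene_id`, `pathway_id` and optionally
#'   `pathway_name`.
#' @param background_genes Background universe; defaults to all genes in
#'   `pathway_table`.
#' @param alpha Raw-p threshold for the `enriched` flag (default 0.05; no
#'   multiplicity adjustment by default, mirroring common pathway practice).
#' @param fdr Also compute BH-adjusted p-values and require them below
#'   `alpha` for the `enriched` flag?
#' @return A `cerna_enrichment` tibble sorted by p-value: `pathway_id`,
#'   `pathway_name`, `k`, `K`, `n`, `N`, `p_value` (and `adj_p` when
#'   `fdr = TRUE`), `enriched`.
#' @export
fisher_enrich <- function(query_genes, pathway_table,
                          background_genes = NULL, alpha = 0.05,
                          fdr = FALSE) {
  stopifnot(all(c("gene_id", "pathway_id") %in% names(pathway_table)))
  if (is.null(background_genes))
    background_genes <- unique(pathway_table$gene_id)
  background_genes <- unique(as.character(background_genes))
  if (!length(background_genes)) stop("empty background gene set")
  query <- unique(as.character(query_genes))
  dropped <- setdiff(query, background_genes)
  if (length(dropped)) {
    warning(length(dropped), " query gene(s) absent from background dropped")
    query <- intersect(query, background_genes)
  }
  n <- length(query)
  N <- length(background_genes)
  if (!"pathway_name" %in% names(pathway_table))
    pathway_table$pathway_name <- pathway_table$pathway_id
  res <- pathway_table |>
    filter(.data$gene_id %in% background_genes) |>
    group_by(.data$pathway_id, .data$pathway_name) |>
    summarise(K = dplyr::n_distinct(.data$gene_id),
              k = sum(unique(.data$gene_id) %in% query),
              .groups = "drop") |>
    mutate(n = n, N = N,
           p_value = phyper(.data$k - 1L, .data$K, N - .data$K, n,
                            lower.tail = FALSE))
  if (fdr) {
    res$adj_p <- bh_adjust(res$p_value)
    res$enriched <- res$adj_p < alpha
  } else {
    res$enriched <- res$p_value < alpha
  }
  res <- arrange(res, .data$p_value, .data$pathway_id) |>
    select("pathway_id", "pathway_name", "k", "K", "n", "N",
           dplyr::everything())
  structure(res, class = c("cerna_enrichment", class(res)), alpha = alpha)
}

#' Venn overlaps of enriched pathway sets across comparisons
#'
#' @param per_comparison_enriched Named list (one element per comparison) of
#'   enriched pathway ids.
#' @return Region tibble from [venn_regions()]; the row where every
#'   comparison is a member lists the conserved pathways.
#' @export
pathway_venn <- function(per_comparison_enriched) {
  venn_regions(per_comparison_enriched)
}
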