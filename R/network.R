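# Sign-constrained ceRNA network construction: focal circRNA selection,
# Pearson correlation filtering, tripartite assembly, axis enumeration,
# pathway subnetwork extraction and hub ranking.
#
# The ceRNA (sponge) hypothesis fixes the expected correlation signs:
# circ-miR negative, miR-mRNA negative, circ-mRNA positive.

edge_sign <- c(circ_mir = -1, mir_mrna = -1, circ_mrna = +1)

#' Normalize an expression matrix for correlation analysis
#'
#' @param counts Tibble (`feature_id` + sample columns) or matrix of counts.
#' @param samples Sample sheet with `sample`, `mapped_reads`.
#' @param method `"srpbm"` (junction reads per billion mapped, for
#'   circRNAs), `"cpm"` (per million mapped) or `"size_factor"`
#'   (median-of-ratios).
#' @param log2 Apply `log2(x + 1)`? (Default `TRUE`; correlations are
#'   computed on this scale.)
#' @return Numeric matrix (features x samples).
#' @export
normalize_expression <- function(counts, samples,
                                 method = c("srpbm", "cpm", "size_factor"),
                                 log2 = TRUE) {
  method <- match.arg(method)
  mat <- if (is.data.frame(counts)) counts_matrix(counts) else as.matrix(counts)
  mr <- setNames(samples$mapped_reads, samples$sample)[colnames(mat)]
  out <- switch(method,
    srpbm = sweep(mat, 2, mr, "/") * 1e9,
    cpm = sweep(mat, 2, mr, "/") * 1e6,
    size_factor = sweep(mat, 2, size_factors(mat), "/")
  )
  if (log2) out <- base::log2(out + 1)
  out
}

#' Collapse expression matrices to per-group means
#'
#' Alternative correlation basis: instead of all samples (n = 12 in the
#' default design), correlate the per-group mean profiles (n = 4). Noisier
#' in degrees of freedom but robust to within-group structure.
#'
#' @param expr Named list of expression matrices (features x samples).
#' @param samples Sample sheet with `sample`, `group`.
#' @return List of matrices with one column per group.
#' @export
group_mean_expr <- function(expr, samples) {
  groups <- unique(samples$group)
  purrr::map(expr, function(m) {
    out <- vapply(groups, function(g) {
      rowMeans(m[, samples$sample[samples$group == g], drop = FALSE])
    }, numeric(nrow(m)))
    colnames(out) <- groups
    out
  })
}

#' Vectorized Pearson correlation with t-distributed p-values
#'
#' `r` is the sample Pearson correlation; the two-sided p-value comes from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom, with
#' `|r| = 1` mapped to `p = 0`. Zero-variance vectors give `NA` (untestable).
#'
#' @param x,y Numeric matrices with matched columns (samples); correlations
#'   are computed row-wise between `x[i, ]` and `y[i, ]`.
#' @return Tibble with `r`, `p`, `n`.
#' @export
pearson_rows <- function(x, y) {
  x <- rbind(x); y <- rbind(y)
  stopifnot(ncol(x) == ncol(y), nrow(x) == nrow(y))
  n <- ncol(x)
  if (n < 3L) stop("need at least 3 matched samples for correlation")
  cx <- x - rowMeans(x)
  cy <- y - rowMeans(y)
  sx <- rowSums(cx^2)
  sy <- rowSums(cy^2)
  r <- rowSums(cx * cy) / sqrt(sx * sy)
  r[sx == 0 | sy == 0] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  p <- ifelse(abs(r) >= 1, 0,
              2 * pt(-abs(r * sqrt(n - 2) / sqrt(1 - r^2)), df = n - 2))
  tibble(r = r, p = p, n = n)
}

#' Select focal (study-group-associated) DE circRNAs
#'
#' Implements the two-stage focal selection: (i) circRNAs differentially
#' expressed in the primary contrast and either unique to it or shared with
#' the secondary contrast, i.e. `unique(primary) | (primary & secondary)`;
#' (ii) optionally gated on host-gene pathway enrichment: a circRNA is kept
#' only when its parental gene belongs to a significantly enriched
#' hypoxia-related pathway.
#'
#' @param de_sets Named list of DE circRNA id vectors, one per contrast.
#' @param primary,secondary Names of the primary and secondary contrasts in
#'   `de_sets`.
#' @param unique_scope `"all"`: unique means absent from every other
#'   contrast in `de_sets`; `"pair"`: absent from the secondary contrast
#'   only.
#' @param hosts Tibble mapping `circ_id` to `parental_gene` (from
#'   [classify_circ()]).
#' @param enrichment A [fisher_enrich()] result for the host genes, or
#'   `NULL` to skip the gate.
#' @param pathway_table Pathway membership table (needed for the gate).
#' @param hypoxia_pathways Character vector of hypoxia-related pathway names
#'   or ids the gate restricts to; `NULL` means any enriched pathway.
#' @return Tibble `circ_id`, `provenance` (`unique_primary` or `shared`),
#'   `parental_gene`, `passes_gate`; the focal set is the rows with
#'   `passes_gate`.
#' @export
select_focal_circs <- function(de_sets, primary, secondary,
                               unique_scope = c("all", "pair"),
                               hosts = NULL, enrichment = NULL,
                               pathway_table = NULL,
                               hypoxia_pathways = NULL) {
  unique_scope <- match.arg(unique_scope)
  if (!all(c(primary, secondary) %in% names(de_sets)))
    stop("missing contrast in de_sets: need '", primary, "' and '",
         secondary, "'")
  a <- unique(de_sets[[primary]])
  b <- unique(de_sets[[secondary]])
  others <- if (unique_scope == "all")
    unlist(de_sets[setdiff(names(de_sets), primary)], use.names = FALSE)
  else b
  uniq <- setdiff(a, others)
  shared <- intersect(a, b)
  out <- tibble(
    circ_id = c(uniq, setdiff(shared, uniq)),
    provenance = c(rep("unique_primary", length(uniq)),
                   rep("shared", length(setdiff(shared, uniq))))
  ) |> arrange(.data$circ_id)

  if (!is.null(hosts)) {
    out <- left_join(out, select(hosts, "circ_id", "parental_gene"),
                     by = "circ_id")
  } else {
    out$parental_gene <- NA_character_
  }
  if (is.null(enrichment)) {
    out$passes_gate <- TRUE
    return(out)
  }
  if (is.null(pathway_table))
    stop("pathway_table is required when gating on enrichment")
  enr <- filter(as_tibble(enrichment), .data$enriched)
  if (!is.null(hypoxia_pathways)) {
    enr <- filter(enr, .data$pathway_id %in% hypoxia_pathways |
                    .data$pathway_name %in% hypoxia_pathways)
  }
  gate_genes <- pathway_table |>
    filter(.data$pathway_id %in% enr$pathway_id) |>
    pull("gene_id") |>
    unique()
  out$passes_gate <- !is.na(out$parental_gene) &
    out$parental_gene %in% gate_genes
  out
}

#' Correlation-filter candidate interaction pairs
#'
#' Computes the Pearson correlation of each pair on matched sample vectors
#' of normalized expression and keeps pairs satisfying the ceRNA sign
#' constraint for their edge type (`circ_mir` and `mir_mrna` require
#' `r < 0`; `circ_mrna` requires `r > 0`) at `p < alpha`. Pairs with a
#' zero-variance member are flagged untestable and excluded with a warning.
#'
#' @param pairs Tibble with `source`, `target`, `edge_type` (one of
#'   `circ_mir`, `mir_mrna`, `circ_mrna`); `source`/`target` index rows of
#'   the respective expression matrices.
#' @param expr Named list of normalized expression matrices (samples in
#'   matched column order) keyed `circ`, `mir`, `mrna` -- e.g. from
#'   [normalize_expression()].
#' @param alpha Two-sided p-value threshold (default 0.05).
#' @return `pairs` with `pearson_r`, `r_p_value`, `n_samples`,
#'   `passes_sign_filter`; untestable pairs dropped.
#' @export
correlation_filter <- function(pairs, expr, alpha = 0.05) {
  if (!nrow(pairs)) {
    return(mutate(pairs, pearson_r = numeric(0), r_p_value = numeric(0),
                  n_samples = integer(0), passes_sign_filter = logical(0)))
  }
  stopifnot(all(pairs$edge_type %in% names(edge_sign)))
  side <- function(kind) sub("_.*", "", kind)  # source class
  tail_ <- function(kind) sub(".*_", "", kind) # target class
  cols <- colnames(expr[[1]])
  x <- t(vapply(seq_len(nrow(pairs)), function(i) {
    expr[[side(pairs$edge_type[i])]][pairs$source[i], cols]
  }, numeric(length(cols))))
  y <- t(vapply(seq_len(nrow(pairs)), function(i) {
    expr[[tail_(pairs$edge_type[i])]][pairs$target[i], cols]
  }, numeric(length(cols))))
  ct <- pearson_rows(x, y)
  out <- pairs |>
    mutate(pearson_r = ct$r, r_p_value = ct$p, n_samples = ct$n)
  bad <- is.na(out$pearson_r)
  if (any(bad)) {
    warning(sum(bad), " pair(s) untestable (zero variance) and excluded")
    out <- out[!bad, , drop = FALSE]
  }
  out$passes_sign_filter <-
    sign(out$pearson_r) == edge_sign[out$edge_type] & out$r_p_value < alpha
  out
}

#' Assemble the tripartite ceRNA network
#'
#' Keeps the circ-miR and miR-mRNA pairs that passed the sign/significance
#' filter; nodes with no surviving edge are dropped.
#'
#' @param circ_mir,mir_mrna Filtered pair tibbles from
#'   [correlation_filter()] (only rows with `passes_sign_filter` are used).
#' @return A `cerna_network` list with `nodes` (`id`, `type`) and `edges`
#'   (`source`, `target`, `edge_type`, correlation columns).
#' @export
assemble_network <- function(circ_mir, mir_mrna) {
  cm <- filter(circ_mir, .data$passes_sign_filter)
  mm <- filter(mir_mrna, .data$passes_sign_filter)
  edges <- bind_rows(cm, mm) |>
    arrange(.data$edge_type, .data$source, .data$target)
  nodes <- bind_rows(
    tibble(id = cm$source, type = "circ"),
    tibble(id = c(cm$target, mm$source), type = "mir"),
    tibble(id = mm$target, type = "mrna")
  ) |>
    distinct() |>
    arrange(.data$type, .data$id)
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  tc <- table(factor(x$nodes$type, c("circ", "mir", "mrna")))
  te <- table(factor(x$edges$edge_type, c("circ_mir", "mir_mrna")))
  cat(sprintf("<cerna_network> %d circRNA, %d miRNA, %d mRNA nodes; %d circ-miR and %d miR-mRNA edges\n",
              tc["circ"], tc["mir"], tc["mrna"], te["circ_mir"], te["mir_mrna"]))
  invisible(x)
}

#' Enumerate ceRNA axes in a network
#'
#' An axis is a triple `(circ, miR, mRNA)` whose circ-miR and miR-mRNA
#' edges are both in the network and whose circ-mRNA correlation is
#' positive at `p < alpha` -- the full sponge sign pattern.
#'
#' @param network A [assemble_network()] result.
#' @param expr Named list of normalized expression matrices (as in
#'   [correlation_filter()]), used for the circ-mRNA leg.
#' @param alpha Significance threshold for the circ-mRNA correlation.
#' @return Tibble of axes: `circ_id`, `mir_id`, `mrna_id`, `axis`
#'   (label `circ-miR-mRNA`), the three correlations and the circ-mRNA
#'   p-value, sorted by label.
#' @export
enumerate_axes <- function(network, expr, alpha = 0.05) {
  cm <- filter(network$edges, .data$edge_type == "circ_mir") |>
    select(circ_id = "source", mir_id = "target", circ_mir_r = "pearson_r")
  mm <- filter(network$edges, .data$edge_type == "mir_mrna") |>
    select(mir_id = "source", mrna_id = "target", mir_mrna_r = "pearson_r")
  cand <- inner_join(cm, mm, by = "mir_id", relationship = "many-to-many")
  if (!nrow(cand)) {
    return(tibble(circ_id = character(), mir_id = character(),
                  mrna_id = character(), axis = character(),
                  circ_mir_r = numeric(), mir_mrna_r = numeric(),
                  circ_mrna_r = numeric(), circ_mrna_p = numeric()))
  }
  leg <- correlation_filter(
    tibble(source = cand$circ_id, target = cand$mrna_id,
           edge_type = "circ_mrna"),
    expr, alpha = alpha
  )
  cand <- cand |>
    inner_join(
      leg |> select(circ_id = "source", mrna_id = "target",
                    circ_mrna_r = "pearson_r", circ_mrna_p = "r_p_value",
                    "passes_sign_filter") |> distinct(),
      by = c("circ_id", "mrna_id")
    ) |>
    filter(.data$passes_sign_filter) |>
    select(-"passes_sign_filter") |>
    mutate(axis = paste(.data$circ_id, .data$mir_id, .data$mrna_id,
                        sep = "--")) |>
    select("circ_id", "mir_id", "mrna_id", "axis", "circ_mir_r",
           "mir_mrna_r", "circ_mrna_r", "circ_mrna_p") |>
    arrange(.data$axis)
  cand
}

#' Extract a pathway-specific subnetwork
#'
#' Induces the subgraph on the given mRNAs, their miRNA partners, and those
#' miRNAs' circRNA partners.
#'
#' @param network A [assemble_network()] result.
#' @param gene_set Non-empty character vector of mRNA ids (e.g. pathway
#'   members).
#' @return A `cerna_network` restricted to the induced node set, plus a
#'   `node_counts` attribute (named counts by type).
#' @export
extract_subnetwork <- function(network, gene_set) {
  if (!length(gene_set)) stop("gene_set must be non-empty")
  genes <- intersect(unique(gene_set),
                     network$nodes$id[network$nodes$type == "mrna"])
  if (!length(genes)) {
    warning("gene_set is disjoint from the network: empty subnetwork")
  }
  mm <- filter(network$edges, .data$edge_type == "mir_mrna",
               .data$target %in% genes)
  mirs <- unique(mm$source)
  cm <- filter(network$edges, .data$edge_type == "circ_mir",
               .data$target %in% mirs)
  circs <- unique(cm$source)
  nodes <- filter(network$nodes,
                  (.data$type == "mrna" & .data$id %in% genes) |
                  (.data$type == "mir" & .data$id %in% mirs) |
                  (.data$type == "circ" & .data$id %in% circs))
  sub <- structure(list(nodes = nodes, edges = bind_rows(cm, mm)),
                   class = "cerna_network")
  attr(sub, "node_counts") <- table(factor(nodes$type,
                                           c("circ", "mir", "mrna")))
  sub
}

#' Rank circRNAs by their number of distinct miRNA partners
#'
#' @param network A `cerna_network`.
#' @param hub_threshold Degree above which a circRNA is flagged as a hub
#'   (default `> 3`).
#' @return Tibble `circ_id`, `n_mirs`, `rank`, `is_hub`, sorted by
#'   descending degree with lexicographic tie-breaking.
#' @export
hub_ranking <- function(network, hub_threshold = 3) {
  deg <- network$edges |>
    filter(.data$edge_type == "circ_mir") |>
    group_by(circ_id = .data$source) |>
    summarise(n_mirs = dplyr::n_distinct(.data$target), .groups = "drop") |>
    arrange(dplyr::desc(.data$n_mirs), .data$circ_id) |>
    mutate(rank = dplyr::row_number(),
           is_hub = .data$n_mirs > hub_threshold)
  deg
}
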