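# End-to-end orchestration: catalog -> DE -> enrichment -> targets ->
# network -> promoter scan, from one in-memory input bundle and one
# parameter object. Everything downstream of the inputs is deterministic;
# all set-valued outputs are kept sorted so reruns are byte-identical.

#' Parameters for the ceRNA discovery pipeline
#'
#' @param focal_group Group whose adaptation signature is sought (default
#'   `"TH"`).
#' @param primary_contrast,secondary_contrast Two-group contrasts (character
#'   2-vectors) defining focal DE circRNAs: DE in the primary contrast and
#'   either unique to it or shared with the secondary contrast.
#' @param lfc_threshold Absolute log2 fold-change cutoff for DE calls.
#' @param alpha_de Adjusted-p cutoff for DE calls.
#' @param alpha_enrich Raw-p cutoff for pathway enrichment.
#' @param alpha_corr P cutoff for the Pearson correlation filter.
#' @param relative_score Relative profile-score threshold for the promoter
#'   scan (default 0.80).
#' @param hypoxia_pathways Pathway names treated as hypoxia-related for the
#'   host-gene gate (HIF-1 signaling and companions; edit to taste).
#' @param min_reads,min_samples Catalog detection filter.
#' @param unique_scope Uniqueness definition for focal selection (see
#'   [select_focal_circs()]).
#' @param corr_basis Correlate over all samples (`"samples"`, n = 12 in the
#'   default design) or over per-group mean profiles (`"group_means"`,
#'   n = 4).
#' @param enrichment_gate Apply the host-gene enrichment gate?
#' @param dispersion Dispersion method for [nb_test()].
#' @param stages Which stages to run, in dependency order.
#' @return A `cerna_params` list.
#' @export
cerna_params <- function(focal_group = "TH",
                         primary_contrast = c("TH", "YH"),
                         secondary_contrast = c("TH", "TL"),
                         lfc_threshold = 1,
                         alpha_de = 0.05,
                         alpha_enrich = 0.05,
                         alpha_corr = 0.05,
                         relative_score = 0.80,
                         hypoxia_pathways = c(
                           "HIF-1 signaling pathway",
                           "VEGF signaling pathway",
                           "AMPK signaling pathway",
                           "Glycolysis / Gluconeogenesis",
                           "Autophagy - animal",
                           "Mitophagy - animal"),
                         min_reads = 2, min_samples = 1,
                         unique_scope = c("all", "pair"),
                         corr_basis = c("samples", "group_means"),
                         enrichment_gate = TRUE,
                         dispersion = c("common", "moments"),
                         stages = c("catalog", "de", "enrich", "targets",
                                    "network", "scan")) {
  stopifnot(alpha_de > 0, alpha_de <= 1, alpha_enrich > 0, alpha_enrich <= 1,
            alpha_corr > 0, alpha_corr <= 1,
            relative_score >= 0, relative_score <= 1, lfc_threshold >= 0)
  structure(
    list(focal_group = focal_group,
         primary_contrast = primary_contrast,
         secondary_contrast = secondary_contrast,
         lfc_threshold = lfc_threshold, alpha_de = alpha_de,
         alpha_enrich = alpha_enrich, alpha_corr = alpha_corr,
         relative_score = relative_score,
         hypoxia_pathways = hypoxia_pathways,
         min_reads = min_reads, min_samples = min_samples,
         unique_scope = match.arg(unique_scope),
         corr_basis = match.arg(corr_basis),
         enrichment_gate = enrichment_gate,
         dispersion = match.arg(dispersion),
         stages = stages),
    class = "cerna_params"
  )
}

contrast_name <- function(ct) paste(ct, collapse = "_vs_")

# all pairwise contrasts anchored so that the focal group (when present)
# comes first
all_contrasts <- function(groups, focal_group) {
  combos <- utils::combn(sort(groups), 2, simplify = FALSE)
  purrr::map(combos, function(p) {
    if (p[2] == focal_group) rev(p) else p
  })
}

#' Run the full ceRNA discovery pipeline
#'
#' Executes, in dependency order: circRNA classification and SRPBM
#' normalization (`catalog`), per-contrast NB differential expression
#' (`de`), host-gene pathway enrichment (`enrich`), seed-match target
#' prediction (`targets`), sign-constrained network assembly and axis
#' enumeration (`network`), and PWM promoter scanning of the network mRNAs
#' (`scan`). Stages not listed in `params$stages` are skipped along with
#' everything that depends on them.
#'
#' @param inputs A `cerna_inputs` bundle ([simulate_cerna_study()] or
#'   [read_cerna_inputs()]).
#' @param params A [cerna_params()] object.
#' @return A `cerna_report` list with one element per executed stage, a
#'   `funnel` tibble of candidate-circRNA counts through the filter
#'   sequence, and a `summary` of headline counts.
#' @export
run_cerna_pipeline <- function(inputs, params = cerna_params()) {
  stopifnot(inherits(params, "cerna_params"))
  stages <- params$stages
  report <- list(params = params)
  run <- function(stage) stage %in% stages
  funnel <- list()

  if (run("catalog")) {
    catalog <- classify_circ(inputs$catalog, inputs$annotation)
    catalog$span_length <- catalog$end - catalog$start + 1L
    circ_srpbm <- srpbm(inputs$counts$circ, inputs$samples)
    det <- detection_sets(inputs$counts$circ, inputs$samples)
    report$catalog <- list(catalog = catalog,
                           summaries = catalog_summaries(catalog),
                           srpbm = circ_srpbm, detection = det)
  }

  if (run("de")) {
    contrasts <- all_contrasts(unique(inputs$samples$group),
                               params$focal_group)
    de <- purrr::map(contrasts, function(ct) {
      list(
        circ = nb_test(inputs$counts$circ, inputs$samples, ct,
                       dispersion = params$dispersion,
                       lfc_threshold = params$lfc_threshold,
                       alpha = params$alpha_de),
        mir = nb_test(inputs$counts$mir, inputs$samples, ct,
                      dispersion = params$dispersion,
                      lfc_threshold = params$lfc_threshold,
                      alpha = params$alpha_de),
        mrna = nb_test(inputs$counts$mrna, inputs$samples, ct,
                       dispersion = params$dispersion,
                       lfc_threshold = params$lfc_threshold,
                       alpha = params$alpha_de)
      )
    })
    names(de) <- purrr::map_chr(contrasts, contrast_name)
    de_sets <- purrr::map(de, function(x) {
      purrr::map(x, function(res) call_de(res, params$lfc_threshold,
                                          params$alpha_de)$de)
    })
    report$de <- list(results = de, sets = de_sets,
                      venn = de_venn(purrr::map(de_sets, "circ")))
  }

  primary <- contrast_name(params$primary_contrast)
  secondary <- contrast_name(params$secondary_contrast)

  if (run("enrich") && run("de") && run("catalog")) {
    catalog <- report$catalog$catalog
    hosts <- select(catalog, "circ_id", "parental_gene")
    circ_sets <- purrr::map(report$de$sets, "circ")
    focal0 <- select_focal_circs(circ_sets, primary, secondary,
                                 unique_scope = params$unique_scope,
                                 hosts = hosts)
    funnel$focal_de <- nrow(focal0)
    host_genes <- unique(stats::na.omit(focal0$parental_gene))
    enr <- fisher_enrich(host_genes, inputs$pathways,
                         alpha = params$alpha_enrich)
    focal <- select_focal_circs(circ_sets, primary, secondary,
                                unique_scope = params$unique_scope,
                                hosts = hosts,
                                enrichment = if (params$enrichment_gate) enr,
                                pathway_table = inputs$pathways,
                                hypoxia_pathways = params$hypoxia_pathways)
    funnel$focal_gated <- sum(focal$passes_gate)
    report$enrich <- list(host_enrichment = enr, focal = focal)
  }

  if (run("targets") && !is.null(report$enrich)) {
    focal_ids <- report$enrich$focal$circ_id[report$enrich$focal$passes_gate]
    de_mir <- sort(unique(unlist(
      purrr::map(report$de$sets[c(primary, secondary)], "mir"),
      use.names = FALSE)))
    de_mrna <- sort(unique(unlist(
      purrr::map(report$de$sets[c(primary, secondary)], "mrna"),
      use.names = FALSE)))
    circ_sites <- seed_sites_all(inputs$sequences$mir[de_mir],
                                 inputs$sequences$circ[focal_ids],
                                 target_kind = "circRNA")
    utr_sites <- seed_sites_all(inputs$sequences$mir[de_mir],
                                inputs$sequences$utr[de_mrna],
                                target_kind = "3UTR")
    cm_pairs <- interaction_pairs(circ_sites, focal_ids, de_mir)
    mm_pairs <- interaction_pairs(utr_sites, de_mrna, de_mir)
    funnel$with_sites <- dplyr::n_distinct(cm_pairs$target_id)
    report$targets <- list(circ_sites = circ_sites, utr_sites = utr_sites,
                           circ_mir_pairs = cm_pairs,
                           mir_mrna_pairs = mm_pairs,
                           de_mir = de_mir, de_mrna = de_mrna)
  }

  if (run("network") && !is.null(report$targets)) {
    expr <- list(
      circ = normalize_expression(inputs$counts$circ, inputs$samples,
                                  method = "srpbm"),
      mir = normalize_expression(inputs$counts$mir, inputs$samples,
                                 method = "cpm"),
      mrna = normalize_expression(inputs$counts$mrna, inputs$samples,
                                  method = "cpm")
    )
    if (params$corr_basis == "group_means") {
      expr <- group_mean_expr(expr, inputs$samples)
    }
    cm <- correlation_filter(
      report$targets$circ_mir_pairs |>
        select(source = "target_id", target = "mir_id") |>
        mutate(edge_type = "circ_mir") |>
        select("source", "target", "edge_type"),
      expr, alpha = params$alpha_corr)
    mm <- correlation_filter(
      report$targets$mir_mrna_pairs |>
        select(source = "mir_id", target = "target_id") |>
        mutate(edge_type = "mir_mrna") |>
        select("source", "target", "edge_type"),
      expr, alpha = params$alpha_corr)
    network <- assemble_network(cm, mm)
    axes <- enumerate_axes(network, expr, alpha = params$alpha_corr)
    funnel$corr_filtered <-
      dplyr::n_distinct(network$nodes$id[network$nodes$type == "circ"])
    funnel$in_axes <- dplyr::n_distinct(axes$circ_id)
    hif_genes <- inputs$pathways |>
      filter(.data$pathway_name %in% params$hypoxia_pathways[1] |
               .data$pathway_id %in% params$hypoxia_pathways[1]) |>
      pull("gene_id")
    subnet <- if (length(hif_genes))
      suppressWarnings(extract_subnetwork(network, hif_genes))
    report$network <- list(expr = expr, circ_mir = cm, mir_mrna = mm,
                           network = network, axes = axes,
                           hubs = hub_ranking(network),
                           hif_subnetwork = subnet)
  }

  if (run("scan") && !is.null(report$network)) {
    scan_genes <- sort(unique(report$network$axes$mrna_id))
    if (length(scan_genes)) {
      hits <- purrr::map(inputs$motifs, function(m) {
        scan_promoter(m, inputs$sequences$promoter[scan_genes],
                      threshold = params$relative_score)
      }) |> purrr::list_rbind()
      report$scan <- list(hits = hits,
                          best = promoter_report(hits, scan_genes))
    } else {
      report$scan <- list(hits = NULL, best = NULL)
    }
  }

  report$funnel <- tibble(
    step = as.character(names(funnel)),
    n_circ = as.integer(unlist(funnel, use.names = FALSE) %||% integer(0))
  )
  report$summary <- pipeline_summary(report)
  structure(report, class = "cerna_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_summary <- function(report) {
  s <- list()
  if (!is.null(report$catalog)) {
    cc <- report$catalog$summaries$class_counts
    s$n_circ_catalog <- sum(cc$n)
    s[paste0("n_", cc$genomic_class)] <- as.list(cc$n)
  }
  if (!is.null(report$de)) {
    for (ct in names(report$de$sets)) {
      s[[paste0("n_de_circ_", ct)]] <- length(report$de$sets[[ct]]$circ)
    }
  }
  if (!is.null(report$enrich)) {
    s$n_focal_circ <- sum(report$enrich$focal$passes_gate)
    s$n_enriched_pathways <-
      sum(as_tibble(report$enrich$host_enrichment)$enriched)
  }
  if (!is.null(report$network)) {
    nodes <- report$network$network$nodes
    s$n_network_circ <- sum(nodes$type == "circ")
    s$n_network_mir <- sum(nodes$type == "mir")
    s$n_network_mrna <- sum(nodes$type == "mrna")
    s$n_circ_mir_edges <- sum(report$network$network$edges$edge_type == "circ_mir")
    s$n_mir_mrna_edges <- sum(report$network$network$edges$edge_type == "mir_mrna")
    s$n_axes <- nrow(report$network$axes)
  }
  if (!is.null(report$scan) && !is.null(report$scan$best)) {
    s$n_promoters_with_hit <- sum(!is.na(report$scan$best$best_score))
  }
  s
}

#' @export
print.cerna_report <- function(x, ...) {
  cat("<cerna_report>\n")
  for (nm in names(x$summary)) {
    cat(sprintf("  %-28s %s\n", nm, x$summary[[nm]]))
  }
  if (!is.null(x$network) && nrow(x$network$axes)) {
    cat("  axes:\n")
    for (a in x$network$axes$axis) cat("    ", a, "\n")
  }
  invisible(x)
}

#' Write a machine-readable pipeline report to a directory
#'
#' Writes the funnel, summary, per-contrast DE tables, focal set,
#' enrichment, pair tables, axis table, hub ranking and promoter best-hit
#' table as TSV files (sorted, so reruns are byte-identical).
#'
#' @param report A `cerna_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, name) readr::write_tsv(x, file.path(dir, name))
  w(report$funnel, "funnel.tsv")
  w(tibble(metric = names(report$summary),
           value = unlist(report$summary, use.names = FALSE) %||% numeric(0)),
    "summary.tsv")
  if (!is.null(report$de)) {
    for (ct in names(report$de$results)) {
      w(as_tibble(report$de$results[[ct]]$circ),
        sprintf("de_circ_%s.tsv", ct))
    }
  }
  if (!is.null(report$enrich)) {
    w(as_tibble(report$enrich$host_enrichment), "host_enrichment.tsv")
    w(report$enrich$focal, "focal_circs.tsv")
  }
  if (!is.null(report$network)) {
    w(report$network$axes, "axes.tsv")
    w(report$network$hubs, "hubs.tsv")
    write_network(report$network$network, dir)
  }
  if (!is.null(report$scan) && !is.null(report$scan$best)) {
    w(report$scan$best, "promoter_best_hits.tsv")
  }
  invisible(dir)
}
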