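# circRNA catalog: merging back-splice junction (BSJ) records across
# samples, genomic classification against a GTF, SRPBM normalization and
# detection/specific-expression sets.
#
# Coordinates are 1-based inclusive throughout; the canonical circRNA id is
# "chrom:start|end" (strand is carried when provided but is not part of the
# identity). BED export converts to 0-based half-open.

canonical_circ_id <- function(chrom, start, end) {
  sprintf("%s:%d|%d", chrom, as.integer(start), as.integer(end))
}

#' Merge per-sample back-splice junction records into a catalog
#'
#' Records with identical `(chrom, start, end)` collapse into one catalog
#' entry whose per-sample junction reads are summed. Entries are then
#' filtered: a circRNA is retained if at least `min_samples` samples have at
#' least `min_reads` junction reads. The default (>= 2 reads in >= 1
#' sample) is a deliberately mild high-confidence rule; both knobs are
#' exposed.
#'
#' @param records Tibble of per-sample BSJ records with columns `sample`,
#'   `chrom`, `start`, `end`, `reads` and optionally `strand`; or a list of
#'   such tibbles (one per sample), which is row-bound.
#' @param min_reads Minimum junction reads for a sample to count as
#'   supporting detection.
#' @param min_samples Minimum number of supporting samples.
#' @return Wide catalog tibble sorted by `(chrom, start, end)`: `circ_id`,
#'   `chrom`, `start`, `end`, `strand`, `span_length`, then one count column
#'   per sample (absent sample/circ combinations are 0).
#' @export
merge_catalog <- function(records, min_reads = 2, min_samples = 1) {
  if (is.data.frame(records)) records <- list(records)
  records <- purrr::list_rbind(purrr::map(records, as_tibble))
  required <- c("sample", "chrom", "start", "end", "reads")
  if (!all(required %in% names(records)))
    stop("records need columns: ", paste(required, collapse = ", "))
  if (!"strand" %in% names(records)) records$strand <- "*"
  if (any(records$start > records$end)) stop("records with start > end")

  strands <- records |>
    distinct(.data$chrom, .data$start, .data$end, .data$strand) |>
    count(.data$chrom, .data$start, .data$end) |>
    filter(.data$n > 1L)
  if (nrow(strands))
    stop("conflicting strand annotations for ",
         canonical_circ_id(strands$chrom[1], strands$start[1], strands$end[1]))

  samples <- sort(unique(records$sample))
  wide <- records |>
    group_by(.data$chrom, .data$start, .data$end, .data$strand, .data$sample) |>
    summarise(reads = sum(.data$reads), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "reads",
                       values_fill = 0L, names_sort = TRUE) |>
    mutate(circ_id = canonical_circ_id(.data$chrom, .data$start, .data$end),
           span_length = .data$end - .data$start + 1L) |>
    select("circ_id", "chrom", "start", "end", "strand", "span_length",
           dplyr::all_of(samples))
  counts <- as.matrix(wide[, samples, drop = FALSE])
  keep <- rowSums(counts >= min_reads) >= min_samples
  wide[keep, , drop = FALSE] |>
    arrange(.data$chrom, .data$start, .data$end)
}

#' Long-format records from a wide catalog
#'
#' Inverse of the [merge_catalog()] reshaping (zero counts are dropped);
#' useful for round-tripping and for the merge-idempotence property.
#'
#' @param catalog Wide catalog from [merge_catalog()].
#' @return Long tibble with `sample`, `chrom`, `start`, `end`, `strand`,
#'   `reads`.
#' @export
catalog_to_records <- function(catalog) {
  meta <- c("circ_id", "chrom", "start", "end", "strand", "span_length",
            "genomic_class", "parental_gene")
  catalog |>
    tidyr::pivot_longer(-dplyr::any_of(meta), names_to = "sample",
                        values_to = "reads") |>
    filter(.data$reads > 0) |>
    select("sample", "chrom", "start", "end", "strand", "reads")
}

annotation_granges <- function(annotation) {
  if (methods::is(annotation, "GRanges")) {
    ann <- as_tibble(as.data.frame(annotation))
    names(ann)[names(ann) == "seqnames"] <- "chrom"
  } else {
    ann <- as_tibble(annotation)
  }
  ann
}

#' Classify circRNAs as exonic, intronic or intergenic
#'
#' A circRNA overlapping no annotated gene is `intergenic`. Otherwise its
#' parental gene is the overlapping gene covering the largest fraction of
#' the BSJ span (remaining ties broken lexicographically by gene id); the
#' record is `exonic` when both BSJ endpoints fall inside exons of that
#' gene, and `intronic` otherwise.
#'
#' @param catalog Catalog tibble with `circ_id`, `chrom`, `start`, `end`.
#' @param annotation Annotation tibble (from [read_gtf()] or the simulator)
#'   with `chrom`, `type`, `start`, `end`, `gene_id`; or a
#'   `GenomicRanges::GRanges` with those metadata columns. Exon rows
#'   (`type == "exon"`) define exons; gene extents are taken from
#'   `type == "gene"` rows when present, else from the exon span per gene.
#' @return `catalog` with `genomic_class` and `parental_gene` columns added.
#' @export
classify_circ <- function(catalog, annotation) {
  ann <- annotation_granges(annotation)
  if (!nrow(ann)) {
    warning("empty annotation: classifying all circRNAs as intergenic")
    return(mutate(catalog, genomic_class = "intergenic",
                  parental_gene = NA_character_))
  }
  exons <- filter(ann, .data$type == "exon")
  genes <- filter(ann, .data$type == "gene")
  if (!nrow(genes)) {
    genes <- exons |>
      group_by(.data$gene_id, .data$chrom) |>
      summarise(start = min(.data$start), end = max(.data$end),
                .groups = "drop")
  }
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end),
                                    gene_id = genes$gene_id)
  exon_gr <- GenomicRanges::GRanges(exons$chrom,
                                    IRanges::IRanges(exons$start, exons$end),
                                    gene_id = exons$gene_id)
  circ_gr <- GenomicRanges::GRanges(catalog$chrom,
                                    IRanges::IRanges(catalog$start, catalog$end))

  ov <- GenomicRanges::findOverlaps(circ_gr, gene_gr)
  cover <- tibble(
    circ_idx = S4Vectors::queryHits(ov),
    gene_id = gene_gr$gene_id[S4Vectors::subjectHits(ov)],
    covered = BiocGenerics::width(IRanges::pintersect(
      IRanges::ranges(circ_gr)[S4Vectors::queryHits(ov)],
      IRanges::ranges(gene_gr)[S4Vectors::subjectHits(ov)]
    ))
  ) |>
    arrange(.data$circ_idx, dplyr::desc(.data$covered), .data$gene_id) |>
    group_by(.data$circ_idx) |>
    slice(1L) |>
    ungroup()

  parental <- rep(NA_character_, nrow(catalog))
  parental[cover$circ_idx] <- cover$gene_id

  endpoint_in_exon <- function(pos_gr, gene) {
    ov <- GenomicRanges::findOverlaps(pos_gr, exon_gr)
    hit <- tibble(i = S4Vectors::queryHits(ov),
                  gene_id = exon_gr$gene_id[S4Vectors::subjectHits(ov)])
    out <- logical(length(pos_gr))
    hit <- filter(hit, .data$gene_id == gene[.data$i])
    out[unique(hit$i)] <- TRUE
    out
  }
  start_gr <- GenomicRanges::GRanges(catalog$chrom,
                                     IRanges::IRanges(catalog$start, catalog$start))
  end_gr <- GenomicRanges::GRanges(catalog$chrom,
                                   IRanges::IRanges(catalog$end, catalog$end))
  s_in <- endpoint_in_exon(start_gr, parental)
  e_in <- endpoint_in_exon(end_gr, parental)

  cls <- dplyr::case_when(
    is.na(parental) ~ "intergenic",
    s_in & e_in ~ "exonic",
    TRUE ~ "intronic"
  )
  mutate(catalog, genomic_class = cls, parental_gene = parental)
}

#' SRPBM normalization (spliced reads per billion mapped)
#'
#' `SRPBM = junction_reads / mapped_reads * 1e9`. Scale-invariant: jointly
#' doubling counts and mapped totals leaves values unchanged.
#'
#' @param counts Tibble with `feature_id` plus one column per sample, or a
#'   numeric matrix with sample columns.
#' @param mapped_reads Named numeric vector of per-sample mapped-read
#'   totals, or a sample sheet tibble with `sample` and `mapped_reads`.
#' @return Normalized values in the same shape as `counts`.
#' @export
srpbm <- function(counts, mapped_reads) {
  if (is.data.frame(mapped_reads)) {
    mapped_reads <- setNames(mapped_reads$mapped_reads, mapped_reads$sample)
  }
  tib <- is.data.frame(counts)
  mat <- if (tib) counts_matrix(counts) else as.matrix(counts)
  mr <- mapped_reads[colnames(mat)]
  if (anyNA(mr)) stop("mapped_reads missing for some samples")
  if (any(mr <= 0)) stop("mapped_reads must be positive for every sample")
  out <- sweep(mat, 2, mr, "/") * 1e9
  if (!tib) return(out)
  bind_cols(counts["feature_id"], as_tibble(out))
}

# tibble (feature_id + samples) -> named matrix
counts_matrix <- function(counts) {
  stopifnot("feature_id" %in% names(counts))
  m <- as.matrix(counts[setdiff(names(counts), "feature_id")])
  rownames(m) <- counts$feature_id
  m
}

#' Per-group detection and group-specific expression sets
#'
#' A feature is detected in a group when its value reaches `min_value` in at
#' least one sample of the group (apply to raw junction reads or to SRPBM,
#' whichever rule is wanted). The group-specific set is the detected set
#' minus every other group's detected set; all Venn regions over the
#' detected sets are also reported.
#'
#' @param counts Tibble (`feature_id` + sample columns) or matrix of values.
#' @param samples Sample sheet tibble with `sample` and `group`.
#' @param min_value Detection threshold (default 1).
#' @param groups Declared design; defaults to the groups present. Samples
#'   with a group outside the design raise an error.
#' @return List with `detected` and `specific` (named lists of feature ids)
#'   and `venn` (region tibble from [venn_regions()]).
#' @export
detection_sets <- function(counts, samples, min_value = 1, groups = NULL) {
  mat <- if (is.data.frame(counts)) counts_matrix(counts) else as.matrix(counts)
  if (is.null(groups)) groups <- unique(samples$group)
  if (length(groups) < 2L) stop("need at least two groups")
  if (!all(samples$group %in% groups))
    stop("unknown group label: ",
         paste(setdiff(samples$group, groups), collapse = ", "))
  detected <- purrr::map(setNames(groups, groups), function(g) {
    cols <- samples$sample[samples$group == g]
    sub <- mat[, cols, drop = FALSE]
    sort(rownames(sub)[rowSums(sub >= min_value) > 0])
  })
  specific <- purrr::imap(detected, function(d, g) {
    sort(setdiff(d, unlist(detected[setdiff(groups, g)], use.names = FALSE)))
  })
  list(detected = detected, specific = specific,
       venn = venn_regions(detected))
}

#' Summaries of a classified catalog
#'
#' @param catalog Classified catalog (after [classify_circ()]).
#' @return List of tibbles: `class_counts` (exonic/intronic/intergenic),
#'   `chrom_counts`, `lengths` (`circ_id`, `span_length`), and
#'   `per_gene` (number of circRNAs per parental gene, as a histogram:
#'   `circs_per_gene`, `n_genes`).
#' @export
catalog_summaries <- function(catalog) {
  stopifnot("genomic_class" %in% names(catalog))
  class_counts <- catalog |>
    count(genomic_class = factor(.data$genomic_class,
                                 c("exonic", "intronic", "intergenic")),
          .drop = FALSE, name = "n") |>
    mutate(genomic_class = as.character(.data$genomic_class))
  chrom_counts <- count(catalog, .data$chrom, name = "n")
  lengths <- catalog |>
    mutate(span_length = .data$end - .data$start + 1L) |>
    select("circ_id", "span_length")
  per_gene <- catalog |>
    filter(!is.na(.data$parental_gene)) |>
    count(.data$parental_gene, name = "n_circ") |>
    count(circs_per_gene = .data$n_circ, name = "n_genes")
  list(class_counts = class_counts, chrom_counts = chrom_counts,
       lengths = lengths, per_gene = per_gene)
}

#' Export a catalog as BED6 (0-based, half-open)
#'
#' @param catalog Catalog tibble with 1-based inclusive coordinates.
#' @return BED6 tibble (`chrom`, `start`, `end`, `name`, `score`, `strand`).
#' @export
catalog_to_bed <- function(catalog) {
  tibble(chrom = catalog$chrom,
         start = catalog$start - 1L,
         end = catalog$end,
         name = catalog$circ_id,
         score = 0L,
         strand = if ("strand" %in% names(catalog)) catalog$strand else "*")
}
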