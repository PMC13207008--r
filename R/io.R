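# Readers and writers for the plain-text interchange formats: TSV tables,
# FASTA (Biostrings), GTF (rtracklayer), BED, SIF and GraphML.

#' Read / write a feature-by-sample count table (TSV)
#'
#' The first column is `feature_id`; remaining columns are samples.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @param counts Tibble with `feature_id` plus sample columns.
#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read / write the sample sheet (sample, group, mapped_reads)
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @param samples Sample sheet tibble.
#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(samples, path) {
  readr::write_tsv(samples, path)
  invisible(path)
}

#' Read / write a pathway-membership table (gene_id, pathway_id, pathway_name)
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_pathways <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @param pathways Pathway table tibble.
#' @rdname read_pathways
#' @export
write_pathways <- function(pathways, path) {
  readr::write_tsv(pathways, path)
  invisible(path)
}

#' Read / write FASTA sequence sets
#'
#' Thin wrappers over Biostrings; sequences are handled as named character
#' vectors (RNA `U` is accepted and normalized to `T` downstream).
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), sub("\\s.*", "", names(x)))
}

#' @param seqs Named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(setNames(unlist(as_named_seqs(seqs)), names(seqs))),
    path)
  invisible(path)
}

#' Read a GTF annotation into a tibble
#'
#' @param path GTF file (1-based inclusive coordinates, `gene_id` /
#'   `transcript_id` attributes).
#' @return Tibble with `chrom`, `source`, `type`, `start`, `end`, `strand`,
#'   `gene_id`, `transcript_id`.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  tibble(
    chrom = as.character(df$seqnames),
    source = if ("source" %in% names(df)) as.character(df$source) else NA,
    type = as.character(df$type),
    start = df$start, end = df$end,
    strand = as.character(df$strand),
    gene_id = df$gene_id,
    transcript_id = if ("transcript_id" %in% names(df)) df$transcript_id
                    else NA_character_
  )
}

#' Write an annotation tibble as GTF
#'
#' @param annotation Tibble as returned by [read_gtf()] (or the simulator).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand,
    type = annotation$type,
    source = if ("source" %in% names(annotation)) annotation$source
             else "circena",
    gene_id = annotation$gene_id,
    transcript_id = annotation$transcript_id
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write a catalog (TSV) and its BED6 export
#'
#' @param catalog Catalog tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  readr::write_tsv(catalog, path)
  invisible(path)
}

#' @param bed_path Output BED path.
#' @rdname write_catalog
#' @export
write_catalog_bed <- function(catalog, bed_path) {
  readr::write_tsv(catalog_to_bed(catalog), bed_path, col_names = FALSE)
  invisible(bed_path)
}

#' Export a ceRNA network for graph viewers
#'
#' Writes the edge and node tables as TSV, a SIF file (`source
#' interaction target`) and a GraphML file (via igraph).
#'
#' @param network A `cerna_network`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Named vector of the paths written, invisibly.
#' @export
write_network <- function(network, dir, prefix = "cerna") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    edges = file.path(dir, paste0(prefix, "_edges.tsv")),
    nodes = file.path(dir, paste0(prefix, "_nodes.tsv")),
    sif = file.path(dir, paste0(prefix, ".sif")),
    graphml = file.path(dir, paste0(prefix, ".graphml"))
  )
  readr::write_tsv(network$edges, paths["edges"])
  readr::write_tsv(network$nodes, paths["nodes"])
  writeLines(sprintf("%s\t%s\t%s", network$edges$source,
                     network$edges$edge_type, network$edges$target),
             paths["sif"])
  g <- igraph::graph_from_data_frame(
    d = network$edges[, c("source", "target", "edge_type")],
    directed = TRUE,
    vertices = network$nodes
  )
  igraph::write_graph(g, paths["graphml"], format = "graphml")
  invisible(paths)
}

#' Write / read a complete synthetic study to/from a directory
#'
#' Serializes every pipeline input as the plain-text interchange formats
#' (counts TSV, sample sheet TSV, catalog TSV, GTF, FASTA, pathway TSV,
#' JASPAR PFM). The ground truth (when present) is written under `truth/`
#' for reference but is not read back.
#'
#' @param inputs A `cerna_inputs` bundle (e.g. [simulate_cerna_study()]).
#' @param dir Target directory.
#' @return `dir`, invisibly.
#' @export
write_cerna_inputs <- function(inputs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_counts(inputs$counts$circ, file.path(dir, "circ_counts.tsv"))
  write_counts(inputs$counts$mir, file.path(dir, "mir_counts.tsv"))
  write_counts(inputs$counts$mrna, file.path(dir, "mrna_counts.tsv"))
  write_sample_sheet(inputs$samples, file.path(dir, "samples.tsv"))
  write_catalog(inputs$catalog, file.path(dir, "catalog.tsv"))
  write_gtf(inputs$annotation, file.path(dir, "annotation.gtf"))
  write_fasta(inputs$sequences$mir, file.path(dir, "mir.fa"))
  write_fasta(inputs$sequences$circ, file.path(dir, "circ.fa"))
  write_fasta(inputs$sequences$utr, file.path(dir, "utr3.fa"))
  write_fasta(inputs$sequences$promoter, file.path(dir, "promoters.fa"))
  write_pathways(inputs$pathways, file.path(dir, "pathways.tsv"))
  write_pfm(inputs$motifs, file.path(dir, "motifs.pfm"))
  if (!is.null(inputs$truth$axes)) {
    tdir <- file.path(dir, "truth")
    if (!dir.exists(tdir)) dir.create(tdir)
    readr::write_tsv(inputs$truth$axes, file.path(tdir, "axes.tsv"))
    readr::write_tsv(inputs$truth$circ_class,
                     file.path(tdir, "circ_class.tsv"))
  }
  invisible(dir)
}

#' @rdname write_cerna_inputs
#' @export
read_cerna_inputs <- function(dir) {
  structure(
    list(
      counts = list(
        circ = read_counts(file.path(dir, "circ_counts.tsv")),
        mir = read_counts(file.path(dir, "mir_counts.tsv")),
        mrna = read_counts(file.path(dir, "mrna_counts.tsv"))
      ),
      samples = read_sample_sheet(file.path(dir, "samples.tsv")),
      catalog = readr::read_tsv(file.path(dir, "catalog.tsv"),
                                show_col_types = FALSE),
      annotation = read_gtf(file.path(dir, "annotation.gtf")),
      sequences = list(
        mir = read_fasta(file.path(dir, "mir.fa")),
        circ = read_fasta(file.path(dir, "circ.fa")),
        utr = read_fasta(file.path(dir, "utr3.fa")),
        promoter = read_fasta(file.path(dir, "promoters.fa"))
      ),
      pathways = read_pathways(file.path(dir, "pathways.tsv")),
      motifs = read_pfm(file.path(dir, "motifs.pfm")),
      truth = NULL
    ),
    class = "cerna_inputs"
  )
}
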