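test_that("merging collapses identical BSJs and sums per-sample reads", {
  recs <- tibble::tibble(
    sample = c("s1", "s2"),
    chrom = "1", start = 100L, end = 500L, reads = c(3L, 5L)
  )
  cat <- merge_catalog(recs, min_reads = 1, min_samples = 1)
  expect_identical(nrow(cat), 1L)
  expect_identical(cat$circ_id, "1:100|500")
  expect_identical(cat$s1, 3L)
  expect_identical(cat$s2, 5L)
  expect_identical(cat$span_length, 401L)
})

test_that("the detection filter drops records below the support thresholds", {
  recs <- tibble::tibble(
    sample = c("s1", "s1", "s2"),
    chrom = "1", start = c(100L, 900L, 900L), end = c(500L, 1200L, 1200L),
    reads = c(1L, 4L, 4L)
  )
  # min 2 reads in >= 2 samples: only the 900-1200 junction survives
  cat <- merge_catalog(recs, min_reads = 2, min_samples = 2)
  expect_identical(cat$circ_id, "1:900|1200")
  # seen in one sample only with min_samples = 2 -> dropped
  one <- merge_catalog(recs[1, ], min_reads = 1, min_samples = 2)
  expect_identical(nrow(one), 0L)
})

test_that("merge agrees with a brute-force set scan over random catalogs", {
  set.seed(77)
  coords <- tibble::tibble(chrom = "1", start = (1:50) * 1000L,
                           end = (1:50) * 1000L + 500L)
  recs <- purrr::map(sprintf("s%02d", 1:12), function(s) {
    keep <- runif(50) < 0.4
    tibble::tibble(sample = s, chrom = "1", start = coords$start[keep],
                   end = coords$end[keep],
                   reads = 1L + stats::rpois(sum(keep), 2))
  }) |> purrr::list_rbind()
  all_kept <- merge_catalog(recs, min_reads = 1, min_samples = 1)
  expect_identical(nrow(all_kept), length(unique(recs$start)))
  ubiq <- merge_catalog(recs, min_reads = 1, min_samples = 12)
  # brute force: starts present in all 12 samples
  truth <- names(which(table(unique(recs[c("sample", "start")])$start) == 12))
  expect_setequal(as.character(ubiq$start), truth)
})

test_that("merge is idempotent", {
  set.seed(5)
  recs <- tibble::tibble(
    sample = rep(c("a", "b"), each = 5),
    chrom = "2", start = rep((1:5) * 10L, 2), end = rep((1:5) * 10L + 5L, 2),
    reads = rpois(10, 4) + 1L
  )
  m1 <- merge_catalog(recs, min_reads = 1, min_samples = 1)
  m2 <- merge_catalog(catalog_to_records(m1), min_reads = 1, min_samples = 1)
  expect_identical(m1, m2)
})

test_that("conflicting strands for one junction raise an error", {
  recs <- tibble::tibble(
    sample = c("a", "b"), chrom = "1", start = 10L, end = 99L,
    reads = 1L, strand = c("+", "-")
  )
  expect_error(merge_catalog(recs), "conflicting strand")
})

test_that("classification follows the endpoint/exon rules", {
  ann <- tibble::tibble(
    chrom = "1", type = c("gene", "exon", "exon"),
    start = c(1000L, 1000L, 5000L), end = c(6000L, 2000L, 6000L),
    strand = "+", gene_id = "G1", transcript_id = c(NA, "G1.t1", "G1.t1")
  )
  cat <- tibble::tibble(
    circ_id = c("a", "b", "c"), chrom = "1",
    start = c(1500L, 2500L, 20000L), end = c(5500L, 4500L, 21000L)
  )
  cls <- classify_circ(cat, ann)
  expect_identical(cls$genomic_class, c("exonic", "intronic", "intergenic"))
  expect_identical(cls$parental_gene, c("G1", "G1", NA_character_))
})

test_that("parental-gene ties go to the gene covering more of the span", {
  ann <- tibble::tibble(
    chrom = "1", type = rep(c("gene", "exon"), 2),
    start = c(100L, 100L, 450L, 450L), end = c(500L, 500L, 2000L, 2000L),
    strand = "+", gene_id = rep(c("B", "A"), each = 2),
    transcript_id = c(NA, "B.t", NA, "A.t")
  )
  # span 400-1400: gene B covers 101 nt, gene A covers 951 nt -> A wins
  cls <- classify_circ(tibble::tibble(circ_id = "x", chrom = "1",
                                      start = 400L, end = 1400L), ann)
  expect_identical(cls$parental_gene, "A")
})

test_that("empty annotation classifies everything intergenic with a warning", {
  cat <- tibble::tibble(circ_id = "a", chrom = "1", start = 1L, end = 10L)
  expect_warning(cls <- classify_circ(cat, tibble::tibble()), "intergenic")
  expect_identical(cls$genomic_class, "intergenic")
})

test_that("class partition covers the catalog on simulated data", {
  inp <- simulate_cerna_study(small_config(seed = 3L))
  cls <- classify_circ(inp$catalog, inp$annotation)
  cc <- catalog_summaries(cls)$class_counts
  expect_identical(sum(cc$n), nrow(cls))
})

test_that("SRPBM implements reads / mapped * 1e9 and its invariances", {
  counts <- tibble::tibble(feature_id = c("x", "y"), s1 = c(10L, 0L),
                           s2 = c(4L, 8L))
  mapped <- c(s1 = 2e7, s2 = 1e7)
  out <- srpbm(counts, mapped)
  expect_equal(out$s1, c(500, 0))
  expect_equal(out$s2, c(400, 800))
  # joint scaling of counts and mapped totals changes nothing
  scaled <- srpbm(dplyr::mutate(counts, s1 = s1 * 3L, s2 = s2 * 3L),
                  mapped * 3)
  expect_equal(out$s1, scaled$s1)
  expect_equal(out$s2, scaled$s2)
  expect_error(srpbm(counts, c(s1 = 0, s2 = 1e7)), "positive")
})

test_that("detection and specific sets follow their definitions", {
  counts <- tibble::tibble(
    feature_id = c("only_th", "everywhere", "th_and_yh"),
    TH_1 = c(5L, 2L, 1L), TH_2 = c(0L, 1L, 0L),
    YH_1 = c(0L, 3L, 2L), YH_2 = c(0L, 1L, 0L)
  )
  samples <- tibble::tibble(sample = c("TH_1", "TH_2", "YH_1", "YH_2"),
                            group = c("TH", "TH", "YH", "YH"))
  d <- detection_sets(counts, samples)
  expect_setequal(d$detected$TH, c("only_th", "everywhere", "th_and_yh"))
  expect_identical(d$specific$TH, "only_th")
  expect_identical(d$specific$YH, character(0))
  expect_error(detection_sets(counts, samples, groups = c("TH", "TL")),
               "unknown group")
})

test_that("detection Venn counts match brute-force enumeration", {
  set.seed(42)
  mat <- matrix(rbinom(100 * 12, 1, 0.35), 100, 12,
                dimnames = list(sprintf("f%03d", 1:100),
                                paste0(rep(c("TH", "TL", "YH", "YL"), each = 3),
                                       "_", 1:3)))
  samples <- tibble::tibble(sample = colnames(mat),
                            group = rep(c("TH", "TL", "YH", "YL"), each = 3))
  d <- detection_sets(mat, samples)
  orc <- oracle_venn_counts(d$detected)
  got <- setNames(d$venn$n, d$venn$region)
  expect_identical(got[names(orc)], orc[names(orc)])
  # conservation: regions partition the union
  expect_identical(sum(d$venn$n),
                   length(unique(unlist(d$detected, use.names = FALSE))))
})

test_that("catalog summaries are internally consistent", {
  cat <- tibble::tibble(
    circ_id = sprintf("c%d", 1:4), chrom = c("1", "1", "1", "2"),
    start = c(10L, 50L, 100L, 9L), end = c(20L, 80L, 150L, 9L),
    genomic_class = c("exonic", "exonic", "intronic", "intergenic"),
    parental_gene = c("G1", "G1", "G2", NA)
  )
  s <- catalog_summaries(cat)
  expect_identical(setNames(s$chrom_counts$n, s$chrom_counts$chrom),
                   c("1" = 3L, "2" = 1L))
  expect_identical(sum(s$class_counts$n), 4L)
  # weighted sum of the per-gene histogram = number of gene-derived circRNAs
  expect_identical(sum(s$per_gene$circs_per_gene * s$per_gene$n_genes), 3L)
  expect_identical(s$lengths$span_length, c(11L, 31L, 51L, 1L))
})

test_that("BED export is 0-based half-open", {
  cat <- tibble::tibble(circ_id = "1:100|500", chrom = "1",
                        start = 100L, end = 500L, strand = "+")
  bed <- catalog_to_bed(cat)
  expect_identical(bed$start, 99L)
  expect_identical(bed$end, 500L)
})
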