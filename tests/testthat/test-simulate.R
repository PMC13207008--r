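# The generator is first-class: its planted structure is the ground truth
# every downstream test leans on, so its own contracts get tested hardest.

test_that("identical seeds reproduce every generated artifact bit-for-bit", {
  a <- simulate_cerna_study(small_config(seed = 11L))
  b <- simulate_cerna_study(small_config(seed = 11L))
  expect_identical(a$counts, b$counts)
  expect_identical(a$samples, b$samples)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$pathways, b$pathways)
  expect_identical(a$truth$axes, b$truth$axes)
  c <- simulate_cerna_study(small_config(seed = 12L))
  expect_false(identical(a$counts$circ, c$counts$circ))
})

test_that("a null configuration makes all features exchangeable across groups", {
  cfg <- simulation_config(n_circ = 400, n_mir = 2, n_mrna = 2,
                           planted_axes = list(), libsize_jitter = 0,
                           seed = 5L)
  cts <- simulate_counts(cfg)
  mat <- as.matrix(cts$counts$circ[-1])
  gm <- vapply(unique(cts$samples$group), function(g) {
    mean(mat[, cts$samples$sample[cts$samples$group == g]])
  }, numeric(1))
  ratios <- gm / mean(gm)
  expect_true(all(abs(ratios - 1) < 0.05))
})

test_that("planted axes shift group means by the configured fold change", {
  # 500 replicate planted features; circ x4 and miR /4 in the focal group
  n <- 500
  cfg <- simulation_config(
    n_circ = n, n_mir = n, n_mrna = n,
    planted_axes = purrr::map(seq_len(n), ~ planted_axis(.x, .x, .x,
                                                         direction = "circ_up")),
    baseline_mean = 100, planted_fold_change = 4, libsize_jitter = 0,
    class_fractions = c(exonic = 1, intronic = 0, intergenic = 0),
    seed = 21L)
  cts <- simulate_counts(cfg)
  foc <- cts$samples$sample[cts$samples$group == "TH"]
  oth <- cts$samples$sample[cts$samples$group != "TH"]
  circ <- as.matrix(cts$counts$circ[-1])
  mir <- as.matrix(cts$counts$mir[-1])
  expect_lt(abs(mean(circ[, foc]) / 400 - 1), 0.05)
  expect_lt(abs(mean(circ[, oth]) / 100 - 1), 0.05)
  expect_lt(abs(mean(mir[, foc]) / 25 - 1), 0.05)
  # method-of-moments recovery of the NB parameters from the decoy-free
  # non-focal block: mean within 5%, dispersion within 20%
  x <- as.vector(circ[, oth])
  m <- mean(x); v <- var(x)
  expect_lt(abs(m / 100 - 1), 0.05)
  expect_lt(abs(((v - m) / m^2) / 0.1 - 1), 0.20)
})

test_that("invalid configurations are rejected with explicit messages", {
  expect_error(simulation_config(nb_dispersion = 0), "positive")
  expect_error(simulation_config(nb_dispersion = -1), "positive")
  expect_error(simulation_config(baseline_mean = 0), "positive")
  expect_error(simulation_config(planted_fold_change = 0.5), ">= 1")
  expect_error(simulation_config(n_reps = 1), ">= 2")
  expect_error(simulation_config(n_circ = 2), "at least the number of planted")
  expect_error(simulation_config(utr_length = 5), "too short")
})

test_that("planted targets carry exactly the declared seed-match site", {
  inp <- simulate_cerna_study(small_config(seed = 31L, n_axes = 3))
  for (i in seq_len(nrow(inp$truth$axes))) {
    ax <- inp$truth$axes[i, ]
    mir <- inp$sequences$mir[[ax$mir_id]]
    # independent check: the reverse complement of seed positions 2-8
    # (or 2-7 + A) occurs at the recorded offset
    core <- switch(ax$site_type,
      "8mer" = paste0(orc_revcomp(substr(orc_norm(mir), 2, 8)), "A"),
      "7mer-m8" = orc_revcomp(substr(orc_norm(mir), 2, 8)),
      "7mer-A1" = paste0(orc_revcomp(substr(orc_norm(mir), 2, 7)), "A"))
    circ_seq <- inp$sequences$circ[[ax$circ_id]]
    utr_seq <- inp$sequences$utr[[ax$mrna_id]]
    expect_identical(substr(circ_seq, ax$circ_site_offset + 1,
                            ax$circ_site_offset + nchar(core)), core)
    expect_identical(substr(utr_seq, ax$utr_site_offset + 1,
                            ax$utr_site_offset + nchar(core)), core)
  }
})

test_that("decoy sequences carry no site for any planted miRNA", {
  inp <- simulate_cerna_study(small_config(seed = 41L, n_axes = 3))
  tru <- inp$truth$axes
  planted_mirs <- unique(tru$mir_id)
  decoy_circ <- setdiff(names(inp$sequences$circ), tru$circ_id)
  decoy_utr <- setdiff(names(inp$sequences$utr), tru$mrna_id)
  for (m in planted_mirs) {
    for (tg in decoy_circ) {
      expect_identical(nrow(oracle_seed_sites(inp$sequences$mir[[m]],
                                              inp$sequences$circ[[tg]],
                                              circular = TRUE)), 0L)
    }
    for (tg in decoy_utr) {
      expect_identical(nrow(oracle_seed_sites(inp$sequences$mir[[m]],
                                              inp$sequences$utr[[tg]])), 0L)
    }
  }
})

test_that("generated GTF reproduces the planted genomic classes exactly", {
  inp <- simulate_cerna_study(small_config(seed = 51L))
  cls <- classify_circ(inp$catalog, inp$annotation)
  truth <- inp$truth$circ_class
  got <- cls[match(truth$circ_id, cls$circ_id), ]
  expect_identical(got$genomic_class, truth$true_class)
  host_ok <- is.na(truth$host_gene) | got$parental_gene == truth$host_gene
  expect_true(all(host_ok))
  # intergenic circRNAs have no parental gene
  expect_true(all(is.na(got$parental_gene[got$genomic_class == "intergenic"])))
})

test_that("planted promoters score relative 1.0 at the planted offset", {
  inp <- simulate_cerna_study(small_config(seed = 61L))
  motif <- inp$motifs[[1]]
  pm <- inp$truth$promoter_motif
  hits <- scan_promoter(motif, inp$sequences$promoter[pm$gene_id],
                        threshold = 0.99)
  for (i in seq_len(nrow(pm))) {
    h <- hits[hits$sequence_id == pm$gene_id[i] & hits$strand == "+", ]
    expect_true(pm$planted_offset[i] %in% h$offset)
    expect_equal(h$relative_score[h$offset == pm$planted_offset[i]], 1.0,
                 tolerance = 1e-12)
  }
})

test_that("sample sheet and pathway table have the planted structure", {
  inp <- simulate_cerna_study(small_config(seed = 71L))
  expect_identical(nrow(inp$samples), 12L)
  expect_identical(as.integer(table(inp$samples$group)[c("TH", "TL", "YH", "YL")]),
                   rep(3L, 4))
  expect_true(all(inp$samples$mapped_reads > 0))
  hif <- inp$pathways$gene_id[inp$pathways$pathway_name ==
                                "HIF-1 signaling pathway"]
  hosts <- inp$truth$circ_class$host_gene[
    inp$truth$circ_class$circ_id %in% inp$truth$axes$circ_id]
  expect_true(all(hosts %in% hif))
  expect_true(all(inp$truth$axes$mrna_id %in% hif))
})
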