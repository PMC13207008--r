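test_that("focal selection implements unique-or-shared set algebra", {
  de <- list(TH_vs_YH = c("c1", "c2", "c3"), TH_vs_TL = c("c2", "c3", "c4"),
             TL_vs_YL = character(0), YH_vs_YL = character(0))
  f <- select_focal_circs(de, "TH_vs_YH", "TH_vs_TL")
  expect_setequal(f$circ_id, c("c1", "c2", "c3"))
  expect_identical(f$provenance[f$circ_id == "c1"], "unique_primary")
  expect_identical(f$provenance[f$circ_id == "c2"], "shared")
  expect_true(all(f$passes_gate))
  # unique_scope = "all": c1 also DE in TL_vs_YL stops being unique
  de2 <- de; de2$TL_vs_YL <- "c1"
  f2 <- select_focal_circs(de2, "TH_vs_YH", "TH_vs_TL", unique_scope = "all")
  expect_false("c1" %in% f2$circ_id)
  f3 <- select_focal_circs(de2, "TH_vs_YH", "TH_vs_TL", unique_scope = "pair")
  expect_true("c1" %in% f3$circ_id)
  expect_error(select_focal_circs(de[1], "TH_vs_YH", "TH_vs_TL"),
               "missing contrast")
})

test_that("the enrichment gate drops circRNAs with un-enriched hosts", {
  de <- list(A = c("c1", "c2"), B = c("c1", "c2"))
  hosts <- tibble::tibble(circ_id = c("c1", "c2"),
                          parental_gene = c("g_hif", "g_other"))
  pt <- tibble::tibble(gene_id = c("g_hif", "g_other", "g3", "g4"),
                       pathway_id = c("HIF", "OTH", "OTH", "OTH"),
                       pathway_name = c("HIF-1 signaling pathway", "other",
                                        "other", "other"))
  enr <- tibble::tibble(pathway_id = c("HIF", "OTH"),
                        pathway_name = c("HIF-1 signaling pathway", "other"),
                        enriched = c(TRUE, FALSE))
  f <- select_focal_circs(de, "A", "B", hosts = hosts, enrichment = enr,
                          pathway_table = pt,
                          hypoxia_pathways = "HIF-1 signaling pathway")
  expect_true(f$passes_gate[f$circ_id == "c1"])
  expect_false(f$passes_gate[f$circ_id == "c2"])
})

test_that("pearson_rows matches cor.test to near machine precision", {
  set.seed(202)
  for (i in 1:100) {
    n <- sample(4:15, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- pearson_rows(matrix(x, 1), matrix(y, 1))
    ct <- stats::cor.test(x, y)
    expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p, ct$p.value, tolerance = 1e-12)
  }
})

test_that("perfect correlations map to p = 0 and obey the sign filter", {
  x <- matrix(as.numeric(1:12), 1)
  down <- matrix(as.numeric(12:1), 1)
  expect_equal(pearson_rows(x, down)$r, -1)
  expect_equal(pearson_rows(x, down)$p, 0)
  expr <- list(circ = rbind(c1 = as.numeric(1:12)),
               mir = rbind(m1 = as.numeric(12:1), m2 = as.numeric(1:12)))
  colnames(expr$circ) <- colnames(expr$mir) <- paste0("s", 1:12)
  pairs <- tibble::tibble(source = "c1", target = c("m1", "m2"),
                          edge_type = "circ_mir")
  out <- correlation_filter(pairs, expr)
  expect_true(out$passes_sign_filter[out$target == "m1"])
  expect_false(out$passes_sign_filter[out$target == "m2"])  # r = +1 fails sign
})

test_that("zero-variance pairs are excluded with a warning", {
  expr <- list(circ = rbind(c1 = rep(5, 12)),
               mir = rbind(m1 = as.numeric(1:12)))
  colnames(expr$circ) <- colnames(expr$mir) <- paste0("s", 1:12)
  pairs <- tibble::tibble(source = "c1", target = "m1",
                          edge_type = "circ_mir")
  expect_warning(out <- correlation_filter(pairs, expr), "untestable")
  expect_identical(nrow(out), 0L)
})

make_toy_network <- function() {
  cm <- tibble::tibble(source = c("c1", "c1", "c2"),
                       target = c("m1", "m2", "m2"),
                       edge_type = "circ_mir",
                       pearson_r = -0.9, r_p_value = 1e-4,
                       passes_sign_filter = TRUE)
  mm <- tibble::tibble(source = c("m1", "m2"), target = c("g1", "g2"),
                       edge_type = "mir_mrna",
                       pearson_r = -0.8, r_p_value = 1e-3,
                       passes_sign_filter = TRUE)
  assemble_network(cm, mm)
}

test_that("network assembly keeps only nodes with surviving edges", {
  net <- make_toy_network()
  expect_setequal(net$nodes$id[net$nodes$type == "circ"], c("c1", "c2"))
  expect_setequal(net$nodes$id[net$nodes$type == "mir"], c("m1", "m2"))
  g <- glance(net)
  expect_identical(g$n_circ_mir_edges, 3L)
  expect_identical(g$n_mir_mrna_edges, 2L)
  # a filtered-out edge drops its orphan node
  cm2 <- tibble::tibble(source = "c9", target = "m9", edge_type = "circ_mir",
                        pearson_r = 0.9, r_p_value = 1e-4,
                        passes_sign_filter = FALSE)
  net2 <- assemble_network(cm2, tibble::tibble(
    source = character(), target = character(), edge_type = character(),
    pearson_r = numeric(), r_p_value = numeric(),
    passes_sign_filter = logical()))
  expect_identical(nrow(net2$nodes), 0L)
})

test_that("axis enumeration requires a shared miRNA and positive circ-mRNA r", {
  net <- make_toy_network()
  set.seed(7)
  base <- as.numeric(1:12)
  expr <- list(
    circ = rbind(c1 = base + rnorm(12, 0, 0.1), c2 = base + rnorm(12, 0, 0.1)),
    mir = rbind(m1 = rev(base), m2 = rev(base)),
    mrna = rbind(g1 = base + rnorm(12, 0, 0.1), g2 = rev(base))
  )
  for (m in names(expr)) colnames(expr[[m]]) <- paste0("s", 1:12)
  axes <- enumerate_axes(net, expr)
  # c1-m1-g1 passes (circ-mRNA positive); any axis to g2 fails (negative)
  expect_true("c1--m1--g1" %in% axes$axis)
  expect_false(any(axes$mrna_id == "g2"))
  expect_true(all(axes$circ_mir_r < 0 & axes$mir_mrna_r < 0 &
                    axes$circ_mrna_r > 0))
  # disjoint miRNAs support no axis
  cm <- tibble::tibble(source = "c1", target = "m1", edge_type = "circ_mir",
                       pearson_r = -0.9, r_p_value = 1e-4,
                       passes_sign_filter = TRUE)
  mm <- tibble::tibble(source = "m2", target = "g1", edge_type = "mir_mrna",
                       pearson_r = -0.9, r_p_value = 1e-4,
                       passes_sign_filter = TRUE)
  expect_identical(nrow(enumerate_axes(assemble_network(cm, mm), expr)), 0L)
})

test_that("subnetwork extraction induces genes, their miRs, their circs", {
  net <- make_toy_network()
  sub_all <- extract_subnetwork(net, c("g1", "g2"))
  expect_identical(sort(sub_all$nodes$id), sort(net$nodes$id))
  sub <- extract_subnetwork(net, "g2")
  # g2 <- m2 <- {c1, c2}: 1 mRNA + 1 miR + 2 circ
  counts <- attr(sub, "node_counts")
  expect_identical(as.integer(counts[c("circ", "mir", "mrna")]),
                   c(2L, 1L, 1L))
  expect_warning(empty <- extract_subnetwork(net, "nope"), "disjoint")
  expect_identical(nrow(empty$nodes), 0L)
  expect_error(extract_subnetwork(net, character(0)), "non-empty")
})

test_that("hub ranking counts distinct miRNA partners with stable ties", {
  cm <- tibble::tibble(
    source = c(rep("c_star", 5), "a_circ", "b_circ"),
    target = c(paste0("m", 1:5), "m1", "m1"),
    edge_type = "circ_mir", pearson_r = -0.9, r_p_value = 1e-4,
    passes_sign_filter = TRUE)
  net <- assemble_network(cm, tibble::tibble(
    source = "m1", target = "g1", edge_type = "mir_mrna",
    pearson_r = -0.9, r_p_value = 1e-3, passes_sign_filter = TRUE))
  h <- hub_ranking(net)
  expect_identical(h$circ_id[1], "c_star")
  expect_identical(h$n_mirs[1], 5L)
  expect_true(h$is_hub[1])
  expect_false(any(h$is_hub[-1]))
  # lexicographic tie-break between the two degree-1 circRNAs
  expect_identical(h$circ_id[2:3], c("a_circ", "b_circ"))
  # degrees equal an adjacency-count oracle on a random bipartite graph
  set.seed(31)
  cm2 <- tibble::tibble(
    source = sample(paste0("c", 1:8), 40, replace = TRUE),
    target = sample(paste0("m", 1:10), 40, replace = TRUE),
    edge_type = "circ_mir", pearson_r = -0.5, r_p_value = 0.01,
    passes_sign_filter = TRUE) |> dplyr::distinct()
  net2 <- assemble_network(cm2, tibble::tibble(
    source = character(), target = character(), edge_type = character(),
    pearson_r = numeric(), r_p_value = numeric(),
    passes_sign_filter = logical()))
  h2 <- hub_ranking(net2)
  orc <- table(cm2$source)
  expect_identical(setNames(h2$n_mirs, h2$circ_id)[names(orc)],
                   setNames(as.integer(orc), names(orc)))
})
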