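make_null_counts <- function(n_feat, mu = 200, disp = 0.2, seed = 1,
                             groups = c("TH", "YH")) {
  set.seed(seed)
  samples <- tibble::tibble(
    sample = paste0(rep(groups, each = 3), "_", 1:3),
    group = rep(groups, each = 3)
  )
  counts <- tibble::tibble(feature_id = sprintf("f%04d", seq_len(n_feat)))
  for (s in samples$sample) {
    counts[[s]] <- rnbinom(n_feat, mu = mu, size = 1 / disp)
  }
  list(counts = counts, samples = samples)
}

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_identical(bh_adjust(c(0.01, NA, 0.5))[2], NA_real_)
  # NAs are excluded from m: remaining values adjust as a length-2 vector
  expect_equal(bh_adjust(c(0.01, NA, 0.5))[c(1, 3)],
               p.adjust(c(0.01, 0.5), "BH"))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone transform: sorting by p sorts by adjusted p
  set.seed(9)
  p <- runif(100)
  expect_identical(order(bh_adjust(p)[order(p)]), 1:100)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("identical count vectors in both groups give log2FC 0", {
  x <- c(10L, 20L, 30L)
  counts <- tibble::tibble(feature_id = "f1",
                           TH_1 = x[1], TH_2 = x[2], TH_3 = x[3],
                           YH_1 = x[1], YH_2 = x[2], YH_3 = x[3])
  samples <- tibble::tibble(sample = names(counts)[-1],
                            group = rep(c("TH", "YH"), each = 3))
  res <- nb_test(counts, samples, c("TH", "YH"))
  expect_equal(res$log2FC, 0)
  expect_equal(res$stat, 0)
})

test_that("swapping the contrast negates log2FC and preserves p", {
  d <- make_null_counts(50, seed = 4)
  a <- nb_test(d$counts, d$samples, c("TH", "YH"))
  b <- nb_test(d$counts, d$samples, c("YH", "TH"))
  expect_equal(a$log2FC, -b$log2FC, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("input validation: non-integer counts and single replicates", {
  d <- make_null_counts(5)
  bad <- d$counts
  bad$TH_1 <- bad$TH_1 + 0.5
  expect_error(nb_test(bad, d$samples, c("TH", "YH")), "integer")
  smp <- d$samples[-c(1, 2), ]  # one TH replicate left
  expect_error(nb_test(d$counts, smp, c("TH", "YH")), "2 replicates")
  expect_error(nb_test(d$counts, d$samples, c("TH", "XX")), "absent")
})

test_that("all-zero features get NA p and are excluded from BH", {
  d <- make_null_counts(20, seed = 8)
  d$counts[1, -1] <- 0L
  res <- nb_test(d$counts, d$samples, c("TH", "YH"))
  expect_true(is.na(res$p_value[1]))
  expect_true(is.na(res$adj_p[1]))
  expect_identical(res$direction[1], "ns")
  expect_equal(res$adj_p[-1], bh_adjust(res$p_value[-1]))
})

test_that("zero-in-one-group features are flagged and use the 0.5 pseudocount", {
  d <- make_null_counts(10, seed = 2)
  d$counts[1, c("TH_1", "TH_2", "TH_3")] <- 0L
  res <- nb_test(d$counts, d$samples, c("TH", "YH"))
  expect_true(res$zero_in_group[1])
  sf <- attr(res, "size_factors")
  m2 <- mean(as.numeric(d$counts[1, c("YH_1", "YH_2", "YH_3")]) /
               sf[c("YH_1", "YH_2", "YH_3")])
  expect_equal(res$log2FC[1], log2(0.5 / (m2 + 0.5)))
  expect_false(any(res$zero_in_group[-1]))
})

test_that("type-I error is near nominal under the null", {
  d <- make_null_counts(2000, mu = 200, disp = 0.2, seed = 33)
  res <- nb_test(d$counts, d$samples, c("TH", "YH"))
  rate <- mean(res$p_value < 0.05, na.rm = TRUE)
  mc_se <- sqrt(0.05 * 0.95 / sum(!is.na(res$p_value)))
  expect_lt(abs(rate - 0.05), 3 * mc_se)
})

test_that("planted fold changes are detected with high power", {
  set.seed(12)
  n <- 200
  samples <- tibble::tibble(sample = paste0(rep(c("TH", "YH"), each = 3), "_", 1:3),
                            group = rep(c("TH", "YH"), each = 3))
  mu <- matrix(200, n, 6)
  planted <- 1:30
  mu[planted, 1:3] <- 800
  counts <- tibble::tibble(feature_id = sprintf("f%03d", 1:n))
  for (j in 1:6) counts[[samples$sample[j]]] <-
    rnbinom(n, mu = mu[, j], size = 10)
  res <- nb_test(counts, samples, c("TH", "YH"))
  calls <- call_de(res)
  hit <- mean(sprintf("f%03d", planted) %in% calls$up)
  expect_gte(hit, 0.9)
})

test_that("rescaling one sample is absorbed by the size factors", {
  d <- make_null_counts(300, seed = 6)
  a <- nb_test(d$counts, d$samples, c("TH", "YH"))
  scaled <- d$counts
  scaled$TH_1 <- scaled$TH_1 * 3L
  b <- nb_test(scaled, d$samples, c("TH", "YH"))
  expect_equal(a$log2FC, b$log2FC, tolerance = 1e-9)
  expect_identical(a$direction, b$direction)
  # after size-factor normalization the two runs differ only by one global
  # rescaling of the normalized counts
  sfa <- attr(a, "size_factors"); sfb <- attr(b, "size_factors")
  ma <- as.matrix(d$counts[names(sfa)])
  mb <- as.matrix(scaled[names(sfb)])
  na <- sweep(ma, 2, sfa, "/")
  nb <- sweep(mb, 2, sfb, "/")
  ratio <- nb[na > 0] / na[na > 0]
  expect_lt(diff(range(ratio)), 1e-9)
})

test_that("call_de applies the threshold boundary exactly", {
  res <- tibble::tibble(
    feature_id = c("a", "b", "c"),
    log2FC = c(0.99, -2, 1.5),
    adj_p = c(0.001, 0.01, 0.2)
  )
  calls <- call_de(res, lfc_threshold = 1, alpha = 0.05)
  expect_identical(calls$up, character(0))   # 0.99 misses the lfc cut
  expect_identical(calls$down, "b")
  expect_identical(calls$summary$n_de, 1L)
})

test_that("DE Venn regions equal brute-force enumeration", {
  expect_identical(
    setNames(de_venn(list(A = c("1", "2", "3"), B = c("2", "3", "4")))$n,
             de_venn(list(A = c("1", "2", "3"), B = c("2", "3", "4")))$region),
    c(A = 1L, B = 1L, `A&B` = 2L))
  set.seed(10)
  sets <- purrr::map(setNames(1:4, c("w", "x", "y", "z")),
                     ~ as.character(sample(1:40, 15)))
  v <- de_venn(sets)
  orc <- oracle_venn_counts(sets)
  expect_identical(setNames(v$n, v$region)[names(orc)], orc)
  disjoint <- de_venn(list(A = c("1", "2"), B = c("3", "4")))
  expect_identical(disjoint$n[disjoint$region == "A&B"], 0L)
})

test_that("tidy and glance summarise a DE fit", {
  d <- make_null_counts(30, seed = 14)
  res <- nb_test(d$counts, d$samples, c("TH", "YH"))
  td <- tidy(res)
  expect_false(inherits(td, "cerna_de"))
  expect_identical(nrow(td), 30L)
  g <- glance(res)
  expect_identical(g$contrast, "TH_vs_YH")
  expect_identical(g$n_features, 30L)
  expect_true(g$common_dispersion > 0)
})
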