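# Negative-binomial differential expression for a two-group contrast:
# median-of-ratios size factors, common-dispersion estimation with a
# Cox-Reid adjustment, a likelihood-ratio test on the group means, and
# Benjamini-Hochberg adjustment per contrast.

#' Median-of-ratios size factors
#'
#' DESeq-style size factors: the per-sample median of count ratios to the
#' per-feature geometric mean, computed over features with all-positive
#' counts. When no feature has all-positive counts the estimator falls back
#' to total-count scaling (column sums relative to their geometric mean).
#'
#' @param mat Count matrix (features x samples).
#' @return Named numeric vector of size factors.
#' @export
size_factors <- function(mat) {
  mat <- as.matrix(mat)
  pos <- rowSums(mat <= 0) == 0
  if (any(pos)) {
    logg <- rowMeans(log(mat[pos, , drop = FALSE]))
    sf <- apply(mat[pos, , drop = FALSE], 2, function(col) {
      exp(median(log(col) - logg))
    })
  } else {
    tot <- colSums(mat)
    if (any(tot == 0)) stop("cannot compute size factors: empty sample")
    sf <- tot / exp(mean(log(tot)))
  }
  setNames(sf, colnames(mat))
}

# Continuous extension of the NB log-likelihood (gamma-function form), valid
# for non-negative real x; mu = 0 is the point mass at zero.
nb_loglik <- function(x, mu, size) {
  size <- rep_len(size, length(x))  # row-aligned recycling for matrices
  out <- ifelse(x == 0, 0, -Inf)
  ok <- mu > 0
  if (any(ok)) {
    xo <- x[ok]; mo <- mu[ok]; so <- size[ok]
    out[ok] <- lgamma(xo + so) - lgamma(so) - lgamma(xo + 1) +
      so * log(so / (so + mo)) + xo * log(mo / (so + mo))
  }
  out
}

#' Common NB dispersion by Cox-Reid adjusted profile likelihood
#'
#' Maximizes, over a single dispersion shared by all features, the profile
#' likelihood of the normalized counts given per-feature per-group means,
#' with the Cox-Reid degree-of-freedom adjustment
#' `-0.5 * log(n / (mu * (1 + alpha * mu)))` per estimated mean. Pooling
#' across features makes the estimate precise enough that the downstream
#' test needs no per-feature dispersion moderation.
#'
#' @param mat Normalized count matrix (features x samples).
#' @param groups Group label per column.
#' @param interval Search interval for the dispersion.
#' @return The estimated dispersion (scalar).
#' @export
estimate_common_dispersion <- function(mat, groups,
                                       interval = c(1e-6, 10)) {
  mat <- as.matrix(mat)
  glist <- unique(groups)
  parts <- purrr::map(glist, function(g) {
    X <- mat[, groups == g, drop = FALSE]
    mu <- rowMeans(X)
    keep <- mu > 0
    list(X = X[keep, , drop = FALSE], mu = mu[keep], n = ncol(X))
  })
  profile <- function(a) {
    sz <- 1 / a
    sum(purrr::map_dbl(parts, function(p) {
      if (!nrow(p$X)) return(0)
      ll <- rowSums(nb_loglik(p$X, matrix(p$mu, nrow(p$X), ncol(p$X)), sz))
      cr <- 0.5 * log(p$n / (p$mu * (1 + a * p$mu)))
      sum(ll - cr)
    }))
  }
  optimize(profile, interval, maximum = TRUE)$maximum
}

# per-feature method-of-moments dispersion pooled across the two groups
mom_dispersion <- function(mat, groups, floor = 1e-8) {
  glist <- unique(groups)
  means <- vapply(glist, function(g) rowMeans(mat[, groups == g, drop = FALSE]),
                  numeric(nrow(mat)))
  vars <- vapply(glist, function(g) {
    apply(mat[, groups == g, drop = FALSE], 1, var)
  }, numeric(nrow(mat)))
  dfs <- vapply(glist, function(g) sum(groups == g) - 1, numeric(1))
  v_pool <- as.vector(vars %*% dfs / sum(dfs))
  m_pool <- rowMeans(means)
  pmax((v_pool - m_pool) / m_pool^2, floor)
}

#' Negative-binomial differential-expression test for one contrast
#'
#' Normalizes the two contrasted groups with median-of-ratios size factors,
#' estimates the NB dispersion (`variance = mean + dispersion * mean^2`),
#' and tests each feature for a group-mean difference with a
#' likelihood-ratio test (one degree of freedom) at the estimated
#' dispersion. `log2FC` is the log2 ratio of normalized group means with the
#' first-named group in the numerator; when one group's mean is zero the
#' reported fold change uses a 0.5 pseudocount and the feature is flagged
#' (`zero_in_group`), while the test itself uses no pseudocount. Features
#' with all-zero counts in both groups get `NA` p-values and are excluded
#' from the BH adjustment.
#'
#' @param counts Tibble (`feature_id` + sample columns) or integer matrix of
#'   raw counts (not normalized).
#' @param samples Sample sheet tibble with `sample` and `group`.
#' @param contrast Character 2-vector `(g1, g2)`; `log2FC > 0` means higher
#'   in `g1`.
#' @param dispersion `"common"` (Cox-Reid pooled estimate, default) or
#'   `"moments"` (per-feature method-of-moments, floored at `1e-8`).
#' @param lfc_threshold,alpha Thresholds used for the `direction` call
#'   (`up`/`down`/`ns`).
#' @return A `cerna_de` tibble: `feature_id`, `contrast`, `base_mean`,
#'   `log2FC`, `stat` (signed root of the LR deviance), `p_value`, `adj_p`,
#'   `direction`, `dispersion`, `zero_in_group`. Attributes carry the
#'   contrast, size factors and the dispersion estimate.
#' @export
nb_test <- function(counts, samples, contrast,
                    dispersion = c("common", "moments"),
                    lfc_threshold = 1, alpha = 0.05) {
  dispersion <- match.arg(dispersion)
  stopifnot(length(contrast) == 2L)
  mat <- if (is.data.frame(counts)) counts_matrix(counts) else as.matrix(counts)
  if (any(mat < 0) || any(mat != round(mat)))
    stop("counts must be non-negative integers")
  keep <- samples$group %in% contrast
  if (!all(contrast %in% samples$group))
    stop("contrast group absent from samples: ",
         paste(setdiff(contrast, samples$group), collapse = ", "))
  smp <- samples[keep, ]
  if (any(table(factor(smp$group, contrast)) < 2L))
    stop("each contrasted group needs >= 2 replicates")
  mat <- mat[, smp$sample, drop = FALSE]
  sf <- size_factors(mat)
  norm <- sweep(mat, 2, sf, "/")
  g1 <- smp$group == contrast[1]
  g2 <- smp$group == contrast[2]
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  m0 <- rowMeans(norm)
  testable <- m0 > 0

  alpha_common <- estimate_common_dispersion(norm, smp$group)
  disp <- if (dispersion == "common") rep(alpha_common, nrow(norm))
          else mom_dispersion(norm, smp$group)

  sz <- 1 / disp
  # deviance of the two-mean model against the common-mean model
  dev <- rep(NA_real_, nrow(norm))
  if (any(testable)) {
    idx <- which(testable)
    X1 <- norm[idx, g1, drop = FALSE]
    X2 <- norm[idx, g2, drop = FALSE]
    szi <- sz[idx]
    ll1 <- rowSums(nb_loglik(X1, matrix(m1[idx], length(idx), n1), szi))
    ll2 <- rowSums(nb_loglik(X2, matrix(m2[idx], length(idx), n2), szi))
    ll0 <- rowSums(nb_loglik(cbind(X1, X2),
                             matrix(m0[idx], length(idx), n1 + n2), szi))
    dev[idx] <- pmax(2 * (ll1 + ll2 - ll0), 0)
  }
  p <- ifelse(is.na(dev), NA_real_, pchisq(dev, df = 1, lower.tail = FALSE))

  zero_grp <- testable & (m1 == 0 | m2 == 0)
  lfc <- ifelse(zero_grp, log2((m1 + 0.5) / (m2 + 0.5)), log2(m1 / m2))
  lfc[!testable] <- NA_real_

  adj <- bh_adjust(p)
  res <- tibble(
    feature_id = rownames(mat),
    contrast = paste(contrast, collapse = "_vs_"),
    base_mean = unname(m0),
    log2FC = unname(lfc),
    stat = unname(sign(ifelse(is.na(lfc), 0, lfc)) *
                    sqrt(ifelse(is.na(dev), 0, dev))),
    p_value = unname(p),
    adj_p = unname(adj),
    dispersion = unname(disp),
    zero_in_group = unname(zero_grp)
  )
  res$direction <- dplyr::case_when(
    !is.na(res$adj_p) & res$adj_p < alpha & res$log2FC >= lfc_threshold ~ "up",
    !is.na(res$adj_p) & res$adj_p < alpha & res$log2FC <= -lfc_threshold ~ "down",
    TRUE ~ "ns"
  )
  structure(res, class = c("cerna_de", class(res)),
            contrast = contrast, size_factors = sf,
            common_dispersion = alpha_common,
            lfc_threshold = lfc_threshold, alpha = alpha)
}

#' Benjamini-Hochberg adjustment with NA pass-through
#'
#' Step-up BH on the non-missing p-values (`m` = number of non-missing);
#' `NA`s are returned as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Significant DE feature sets at the standard thresholds
#'
#' @param results A `cerna_de` tibble (or any tibble with `feature_id`,
#'   `log2FC`, `adj_p`).
#' @param lfc_threshold Absolute log2 fold-change cutoff (default 1).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return List with `up`, `down` (sorted id vectors), `de`
#'   (their union) and `summary` (one-row tibble of counts).
#' @export
call_de <- function(results, lfc_threshold = 1, alpha = 0.05) {
  ok <- !is.na(results$adj_p) & results$adj_p < alpha
  up <- sort(results$feature_id[ok & results$log2FC >= lfc_threshold])
  down <- sort(results$feature_id[ok & results$log2FC <= -lfc_threshold])
  list(up = up, down = down, de = sort(c(up, down)),
       summary = tibble(
         contrast = if ("contrast" %in% names(results))
           results$contrast[1] else NA_character_,
         n_up = length(up), n_down = length(down),
         n_de = length(up) + length(down)))
}

#' Venn overlaps of DE sets across contrasts
#'
#' @param contrast_sets Named list (one element per contrast) of DE feature
#'   id vectors.
#' @return Region tibble from [venn_regions()].
#' @export
de_venn <- function(contrast_sets) {
  venn_regions(contrast_sets)
}
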