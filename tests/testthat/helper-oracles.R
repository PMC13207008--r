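# Independent oracles used across the suite. These deliberately avoid the
# package's own string/scanning primitives: regex enumeration for seed
# sites, explicit loops for PWM scoring, closed-form sums for the
# hypergeometric tail, and set algebra for Venn regions.

orc_norm <- function(s) chartr("Uu", "Tt", toupper(s))

orc_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", orc_norm(s)), "")[[1]]),
        collapse = "")
}

# regex (lookahead) enumeration of canonical seed sites
oracle_seed_sites <- function(mir, target, circular = FALSE) {
  mir <- orc_norm(mir); target <- orc_norm(target)
  s7 <- orc_revcomp(substr(mir, 2, 8))
  s6 <- orc_revcomp(substr(mir, 2, 7))
  L <- nchar(target)
  scan <- if (circular && L >= 8) paste0(target, substr(target, 1, 7)) else target
  find <- function(pat) {
    st <- gregexpr(paste0("(?=", pat, ")"), scan, perl = TRUE)[[1]]
    st <- st[st > 0]
    as.integer(st - 1L)
  }
  o8 <- find(paste0(s7, "A"))
  o7 <- setdiff(find(s7), o8)
  oa <- setdiff(find(paste0(s6, "A")), o8 + 1L)
  if (circular && L >= 8) {
    o8 <- o8[o8 < L]; o7 <- o7[o7 < L]; oa <- oa[oa < L]
  }
  out <- rbind(
    if (length(o8)) data.frame(site_type = "8mer", start_offset = o8),
    if (length(o7)) data.frame(site_type = "7mer-m8", start_offset = o7),
    if (length(oa)) data.frame(site_type = "7mer-A1", start_offset = oa)
  )
  if (is.null(out)) out <- data.frame(site_type = character(),
                                      start_offset = integer())
  out[order(out$start_offset, out$site_type), , drop = FALSE]
}

# explicit-loop PWM scorer (both strands)
oracle_pwm_hits <- function(motif, seq, threshold) {
  w <- ncol(motif$counts)
  bg <- motif$background
  pc <- motif$pseudocount
  wt <- matrix(0, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(w)) {
    tot <- sum(motif$counts[, j])
    for (b in rownames(wt)) {
      wt[b, j] <- log2(((motif$counts[b, j] + pc * bg[b]) / (tot + pc)) / bg[b])
    }
  }
  smin <- sum(apply(wt, 2, min)); smax <- sum(apply(wt, 2, max))
  score_win <- function(chars) {
    s <- 0
    for (j in seq_len(w)) {
      b <- chars[j]
      s <- s + if (b %in% rownames(wt)) wt[b, j] else sum(bg * wt[, j])
    }
    s
  }
  hits <- list()
  add <- function(offset, strand, sc) {
    rel <- if (smax > smin) (sc - smin) / (smax - smin) else 1
    if (rel >= threshold) {
      hits[[length(hits) + 1L]] <<- data.frame(
        offset = offset, strand = strand, score = sc, relative_score = rel)
    }
  }
  chars <- strsplit(orc_norm(seq), "")[[1]]
  L <- length(chars)
  for (o in 0:(L - w)) add(o, "+", score_win(chars[(o + 1):(o + w)]))
  rch <- strsplit(orc_revcomp(seq), "")[[1]]
  for (o in 0:(L - w)) {
    add(L - w - o, "-", score_win(rch[(o + 1):(o + w)]))
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(offset = integer(), strand = character(),
               score = numeric(), relative_score = numeric())
  out[order(out$offset, out$strand), , drop = FALSE]
}

# closed-form hypergeometric upper tail
oracle_hyper_p <- function(k, K, n, N) {
  i <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# region counts by repeated set algebra
oracle_venn_counts <- function(sets) {
  nm <- names(sets)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1, , drop = FALSE]
  out <- integer(nrow(patterns))
  for (i in seq_len(nrow(patterns))) {
    pat <- unlist(patterns[i, ])
    inside <- Reduce(intersect, sets[nm[pat]])
    for (s in nm[!pat]) inside <- setdiff(inside, sets[[s]])
    out[i] <- length(unique(inside))
  }
  names(out) <- apply(patterns, 1, function(p) paste(nm[p], collapse = "&"))
  out
}

# small, fast simulation config for structural tests
small_config <- function(seed = 1L, n_axes = 2, ...) {
  simulation_config(
    n_circ = 20, n_mir = 20, n_mrna = 20,
    planted_axes = default_planted_axes(n_axes),
    circ_seq_length = 200, utr_length = 200, promoter_length = 300,
    seed = seed, ...
  )
}

axis_labels <- function(truth_axes) {
  paste(truth_axes$circ_id, truth_axes$mir_id, truth_axes$mrna_id, sep = "--")
}
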