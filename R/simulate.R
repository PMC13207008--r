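# Synthetic-data generator: every input the pipeline consumes, with known
# planted structure (ceRNA axes, genomic classes, pathway memberships,
# promoter motif instances) so downstream stages have exact ground truth.

#' Describe one planted ceRNA axis
#'
#' An axis ties together one circRNA, one miRNA and one mRNA: the circRNA
#' sequence and the mRNA 3'UTR each carry a seed-match site for the miRNA,
#' and expression means follow the sponge sign pattern in the focal group
#' (`circ_up`: circRNA and mRNA up, miRNA down; `circ_down` is the mirror).
#'
#' @param circ,mir,mrna 1-based feature slots (indices into the simulated
#'   circRNA / miRNA / mRNA feature sets).
#' @param direction `"circ_up"` or `"circ_down"` in the focal group.
#' @param site_type Canonical seed-site class planted in both targets.
#' @param focal_group Group label in which the axis is perturbed.
#' @return A `planted_axis` list.
#' @export
planted_axis <- function(circ, mir, mrna,
                         direction = c("circ_up", "circ_down"),
                         site_type = c("8mer", "7mer-m8", "7mer-A1"),
                         focal_group = "TH") {
  direction <- match.arg(direction)
  site_type <- match.arg(site_type)
  stopifnot(circ >= 1, mir >= 1, mrna >= 1)
  structure(
    list(circ = as.integer(circ), mir = as.integer(mir),
         mrna = as.integer(mrna), direction = direction,
         site_type = site_type, focal_group = focal_group),
    class = "planted_axis"
  )
}

#' Default set of planted axes
#'
#' Axes occupy the first `n` feature slots of each class, alternate between
#' `circ_up` and `circ_down`, and cycle through the three canonical site
#' classes.
#'
#' @param n Number of axes.
#' @param focal_group Focal group label.
#' @return List of [planted_axis()] objects.
#' @export
default_planted_axes <- function(n = 5, focal_group = "TH") {
  dirs <- rep(c("circ_up", "circ_down"), length.out = n)
  types <- rep(c("8mer", "7mer-m8", "7mer-A1"), length.out = n)
  purrr::map(seq_len(n), function(i) {
    planted_axis(i, i, i, direction = dirs[i], site_type = types[i],
                 focal_group = focal_group)
  })
}

#' Configuration for the synthetic ceRNA study
#'
#' Defaults emulate the study design the package is built around: four
#' groups (`TH`, `TL`, `YH`, `YL`) of three replicates; negative-binomial
#' counts with mean/dispersion parameterisation
#' `variance = mean + dispersion * mean^2` (i.e. `size = 1/dispersion` in
#' [stats::rnbinom()]); five planted axes at fold change 4 on a baseline
#' mean of 200 with dispersion 0.1; 2000-nt promoters; per-sample mapped
#' totals jittered uniformly by +/-20% around `mapped_reads_per_sample`.
#'
#' @param groups Group labels.
#' @param n_reps Replicates per group (>= 2).
#' @param n_circ,n_mir,n_mrna Feature counts per molecular class; must be at
#'   least the number of planted features of that class.
#' @param nb_dispersion NB dispersion (> 0).
#' @param baseline_mean Baseline NB mean (> 0).
#' @param planted_fold_change Fold change applied to planted features in the
#'   focal group (>= 1; 1 plants no effect).
#' @param planted_axes List of [planted_axis()]; may be empty.
#' @param seed Integer RNG seed; all generated artifacts are reproducible
#'   from it.
#' @param mapped_reads_per_sample Nominal per-sample mapped-read total.
#' @param libsize_jitter Half-width of the uniform relative jitter applied
#'   to mapped-read totals (in `[0, 1)`).
#' @param mir_length,circ_seq_length,utr_length,promoter_length Sequence
#'   lengths (nt).
#' @param class_fractions Named fractions for exonic/intronic/intergenic
#'   circRNA placement (planted circRNAs are always exonic so that they have
#'   a host gene).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(groups = c("TH", "TL", "YH", "YL"),
                              n_reps = 3,
                              n_circ = 55, n_mir = 55, n_mrna = 55,
                              nb_dispersion = 0.1,
                              baseline_mean = 200,
                              planted_fold_change = 4,
                              planted_axes = default_planted_axes(5),
                              seed = 1L,
                              mapped_reads_per_sample = 2e7,
                              libsize_jitter = 0.2,
                              mir_length = 22,
                              circ_seq_length = 400,
                              utr_length = 500,
                              promoter_length = 2000,
                              class_fractions = c(exonic = 0.90,
                                                  intronic = 0.05,
                                                  intergenic = 0.05)) {
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0)
    stop("nb_dispersion must be a positive real (variance = mean + dispersion * mean^2)")
  if (!is.numeric(baseline_mean) || baseline_mean <= 0)
    stop("baseline_mean must be positive")
  if (planted_fold_change < 1)
    stop("planted_fold_change must be >= 1")
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (length(groups) < 2 || anyDuplicated(groups))
    stop("need >= 2 distinct group labels")
  if (mapped_reads_per_sample <= 0) stop("mapped_reads_per_sample must be positive")
  if (libsize_jitter < 0 || libsize_jitter >= 1)
    stop("libsize_jitter must be in [0, 1)")
  stopifnot(setequal(names(class_fractions),
                     c("exonic", "intronic", "intergenic")),
            all(class_fractions >= 0), abs(sum(class_fractions) - 1) < 1e-8)
  axes <- purrr::map(planted_axes, function(a) {
    if (!inherits(a, "planted_axis")) stop("planted_axes must be planted_axis objects")
    if (!a$focal_group %in% groups)
      stop("focal_group '", a$focal_group, "' is not a configured group")
    a
  })
  need <- function(slot) if (length(axes)) max(purrr::map_int(axes, slot)) else 0L
  if (n_circ < need("circ") || n_mir < need("mir") || n_mrna < need("mrna"))
    stop("feature counts must be at least the number of planted features they contain")
  if (utr_length < 10 || circ_seq_length < 10)
    stop("target sequences too short to host a seed-match site")
  if (mir_length < 8) stop("mir_length must be >= 8")
  structure(
    list(groups = groups, n_reps = as.integer(n_reps),
         n_circ = as.integer(n_circ), n_mir = as.integer(n_mir),
         n_mrna = as.integer(n_mrna),
         nb_dispersion = nb_dispersion, baseline_mean = baseline_mean,
         planted_fold_change = planted_fold_change, planted_axes = axes,
         seed = as.integer(seed),
         mapped_reads_per_sample = mapped_reads_per_sample,
         libsize_jitter = libsize_jitter,
         mir_length = as.integer(mir_length),
         circ_seq_length = as.integer(circ_seq_length),
         utr_length = as.integer(utr_length),
         promoter_length = as.integer(promoter_length),
         class_fractions = class_fractions[c("exonic", "intronic", "intergenic")]),
    class = "simulation_config"
  )
}

# Evaluate code under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sample_sheet_from_config <- function(config) {
  tibble(
    sample = paste(rep(config$groups, each = config$n_reps),
                   seq_len(config$n_reps), sep = "_"),
    group = rep(config$groups, each = config$n_reps)
  )
}

# feature ids per class ------------------------------------------------------

circ_feature_layout <- function(config) {
  n <- config$n_circ
  planted <- if (length(config$planted_axes))
    unique(purrr::map_int(config$planted_axes, "circ")) else integer(0)
  n_intron <- round(config$class_fractions[["intronic"]] * n)
  n_inter <- round(config$class_fractions[["intergenic"]] * n)
  cls <- rep("exonic", n)
  decoys <- setdiff(seq_len(n), planted)
  take <- rev(decoys)  # last decoy slots become the minor classes
  if (n_intron + n_inter > length(decoys))
    stop("not enough decoy circRNAs for the requested class fractions")
  if (n_inter > 0) cls[take[seq_len(n_inter)]] <- "intergenic"
  if (n_intron > 0) cls[take[n_inter + seq_len(n_intron)]] <- "intronic"

  chrom <- as.character(((seq_len(n) - 1L) %% 6L) + 1L)
  block <- 100000L + 200000L * ((seq_len(n) - 1L) %/% 6L)
  start <- ifelse(cls == "intronic", block + 5000L, block + 500L)
  end <- dplyr::case_when(cls == "exonic" ~ block + 11000L,
                          cls == "intronic" ~ block + 9000L,
                          TRUE ~ block + 4500L)
  tibble(
    slot = seq_len(n),
    circ_id = sprintf("%s:%d|%d", chrom, start, end),
    chrom = chrom, start = start, end = end, strand = "+",
    block = block, true_class = cls,
    host_gene = ifelse(cls == "intergenic", NA_character_,
                       sprintf("CHOST%03d", seq_len(n)))
  )
}

mir_ids <- function(config) sprintf("sim-miR-%03d", seq_len(config$n_mir))
mrna_ids <- function(config) sprintf("GENE%03d", seq_len(config$n_mrna))

# per-feature group mean multipliers implied by the planted axes
axis_multipliers <- function(config) {
  fc <- config$planted_fold_change
  mult <- list(
    circ = matrix(1, config$n_circ, length(config$groups),
                  dimnames = list(NULL, config$groups)),
    mir = matrix(1, config$n_mir, length(config$groups),
                 dimnames = list(NULL, config$groups)),
    mrna = matrix(1, config$n_mrna, length(config$groups),
                  dimnames = list(NULL, config$groups))
  )
  for (a in config$planted_axes) {
    up <- a$direction == "circ_up"
    mult$circ[a$circ, a$focal_group] <- if (up) fc else 1 / fc
    mult$mir[a$mir, a$focal_group] <- if (up) 1 / fc else fc
    mult$mrna[a$mrna, a$focal_group] <- if (up) fc else 1 / fc
  }
  mult
}

#' Simulate junction/miRNA/mRNA count matrices
#'
#' Draws negative-binomial counts (`variance = mean + dispersion * mean^2`)
#' for the three molecular classes under the configured group design.
#' Planted features have their focal-group means multiplied (or divided) by
#' `planted_fold_change` according to each axis's sign pattern; all means
#' scale with the per-sample mapped-read totals, which are jittered around
#' `mapped_reads_per_sample`.
#'
#' @param config A [simulation_config()].
#' @return List with `counts` (named list of tibbles `feature_id` + one
#'   column per sample, for `circ`, `mir`, `mrna`), `samples` (tibble
#'   `sample`, `group`, `mapped_reads`) and `means` (the expected-count
#'   matrices actually used).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    sheet <- sample_sheet_from_config(config)
    ns <- nrow(sheet)
    sheet$mapped_reads <- round(config$mapped_reads_per_sample *
      runif(ns, 1 - config$libsize_jitter, 1 + config$libsize_jitter))
    libfac <- sheet$mapped_reads / config$mapped_reads_per_sample
    mult <- axis_multipliers(config)
    ids <- list(circ = circ_feature_layout(config)$circ_id,
                mir = mir_ids(config), mrna = mrna_ids(config))
    out <- purrr::imap(mult, function(m, class) {
      mu <- config$baseline_mean * m[, sheet$group, drop = FALSE] *
        rep(libfac, each = nrow(m))
      x <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                  nrow = nrow(mu))
      colnames(x) <- sheet$sample
      bind_cols(tibble(feature_id = ids[[class]]), as_tibble(x))
    })
    means <- purrr::imap(mult, function(m, class) {
      mu <- config$baseline_mean * m[, sheet$group, drop = FALSE] *
        rep(libfac, each = nrow(m))
      dimnames(mu) <- list(ids[[class]], sheet$sample)
      mu
    })
    list(counts = out, samples = sheet, means = means)
  })
}

# sequence generation --------------------------------------------------------

# number of seed-match sites a set of miRNAs (as precomputed seed-pattern
# lists) has in one target
n_planted_sites <- function(target_seq, pattern_list, circular) {
  if (!length(pattern_list)) return(0L)
  sum(purrr::map_int(pattern_list, function(pat) {
    so <- site_offsets(pat, target_seq, circular = circular)
    length(so$o8) + length(so$o7m8) + length(so$o7a1)
  }))
}

# random background free of any seed site for the given miRNAs
clean_background <- function(len, pattern_list, circular, max_tries = 200) {
  for (i in seq_len(max_tries)) {
    s <- random_dna(len)
    if (n_planted_sites(s, pattern_list, circular) == 0L) return(s)
  }
  stop("could not generate a decoy sequence free of planted seed sites")
}

# site string for a given class, plus boundary constraints
planted_site_chunk <- function(mir_seq, site_type) {
  pat <- seed_patterns(mir_seq)
  switch(site_type,
    "8mer" = list(site = pat$p8, prev_not = character(0), next_not = character(0)),
    "7mer-m8" = list(site = pat$p7m8, prev_not = character(0), next_not = "A"),
    "7mer-A1" = list(site = pat$p7a1,
                     prev_not = substr(pat$p7m8, 1L, 1L), next_not = character(0))
  )
}

# target sequence containing exactly the planted site for `own` (a miRNA
# sequence), and nothing for the other planted miRNAs (pattern lists)
planted_target <- function(len, own, site_type, other_patterns, circular,
                           max_tries = 200) {
  chunk <- planted_site_chunk(own, site_type)
  own_pat <- seed_patterns(own)
  w <- nchar(chunk$site)
  if (len < w + 4L) stop("sequence too short to host a seed-match site")
  for (i in seq_len(max_tries)) {
    offset <- sample(2:(len - w - 1L), 1L)  # keep one boundary char each side
    left <- random_dna(offset)
    right <- random_dna(len - offset - w)
    if (length(chunk$prev_not) && substr(left, offset, offset) %in% chunk$prev_not)
      next
    if (length(chunk$next_not) && nchar(right) &&
        substr(right, 1L, 1L) %in% chunk$next_not)
      next
    s <- paste0(left, chunk$site, right)
    so <- site_offsets(own_pat, s, circular = circular)
    hits <- list("8mer" = so$o8, "7mer-m8" = so$o7m8, "7mer-A1" = so$o7a1)
    n_own <- sum(lengths(hits))
    if (n_own != 1L || !identical(hits[[site_type]], offset))
      next
    if (n_planted_sites(s, other_patterns, circular) == 0L)
      return(list(seq = s, offset = offset))
  }
  stop("could not plant a unique seed-match site after ", max_tries, " tries")
}

# miRNA sequences whose 7-nt seeds are pairwise distinct for planted slots
draw_mir_sequences <- function(config) {
  n <- config$n_mir
  seqs <- character(n)
  seeds_seen <- character(0)
  planted <- if (length(config$planted_axes))
    unique(purrr::map_int(config$planted_axes, "mir")) else integer(0)
  for (i in seq_len(n)) {
    repeat {
      s <- random_dna(config$mir_length)
      sd7 <- substr(s, 2L, 8L)
      if (!(i %in% planted) || !(sd7 %in% seeds_seen)) break
    }
    if (i %in% planted) seeds_seen <- c(seeds_seen, substr(s, 2L, 8L))
    seqs[i] <- s
  }
  setNames(seqs, mir_ids(config))
}

default_pfm <- function() {
  consensus <- c("G", "G", "A", "C", "G", "T", "G", "C")
  counts <- matrix(5L, nrow = 4, ncol = length(consensus),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(consensus)) counts[consensus[j], j] <- 85L
  pwm_motif(counts, motif_id = "MA_SYN01", name = "HIF1A_SYNTH")
}

#' Simulate sequences, annotation, pathway table and motif
#'
#' Generates mature miRNA sequences, circRNA sequences, mRNA 3'UTRs and
#' promoters with the planted structure declared in the config: each planted
#' axis's circRNA and 3'UTR carry exactly one seed-match site of the
#' declared class for the axis miRNA, and no decoy target carries any site
#' for a planted miRNA (collisions are re-rolled). Promoters of planted
#' mRNAs carry the motif consensus exactly once at a recorded offset. The
#' GTF places circRNA intervals inside/outside genes so that the
#' exonic/intronic/intergenic labels are known by construction, and the
#' pathway table assigns the planted host genes and mRNAs to a synthetic
#' hypoxia (HIF-1-like) pathway.
#'
#' @param config A [simulation_config()].
#' @return List with `sequences` (named character vectors `mir`, `circ`,
#'   `utr`, `promoter`), `annotation` (exon/gene tibble), `catalog`
#'   (circRNA coordinate tibble), `pathways`, `motifs` (list with one
#'   [pwm_motif()]) and `truth` (planted offsets and classes).
#' @export
simulate_sequences <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed + 500009L, {
    layout <- circ_feature_layout(config)
    mirs <- draw_mir_sequences(config)
    axes <- config$planted_axes
    planted_slots <- if (length(axes)) unique(purrr::map_int(axes, "mir")) else integer(0)
    planted_patterns <- setNames(
      purrr::map(planted_slots, function(i) seed_patterns(mirs[[i]])),
      as.character(planted_slots))
    axis_by_circ <- setNames(axes, purrr::map_int(axes, "circ"))
    axis_by_mrna <- setNames(axes, purrr::map_int(axes, "mrna"))

    circ_seqs <- character(config$n_circ)
    circ_site <- rep(NA_integer_, config$n_circ)
    for (i in seq_len(config$n_circ)) {
      key <- as.character(i)
      if (key %in% names(axis_by_circ)) {
        a <- axis_by_circ[[key]]
        pl <- planted_target(config$circ_seq_length, mirs[[a$mir]],
                             a$site_type,
                             planted_patterns[names(planted_patterns) != a$mir],
                             circular = TRUE)
        circ_seqs[i] <- pl$seq
        circ_site[i] <- pl$offset
      } else {
        circ_seqs[i] <- clean_background(config$circ_seq_length,
                                         planted_patterns, circular = TRUE)
      }
    }
    names(circ_seqs) <- layout$circ_id

    utr_seqs <- character(config$n_mrna)
    utr_site <- rep(NA_integer_, config$n_mrna)
    for (i in seq_len(config$n_mrna)) {
      key <- as.character(i)
      if (key %in% names(axis_by_mrna)) {
        a <- axis_by_mrna[[key]]
        pl <- planted_target(config$utr_length, mirs[[a$mir]],
                             a$site_type,
                             planted_patterns[names(planted_patterns) != a$mir],
                             circular = FALSE)
        utr_seqs[i] <- pl$seq
        utr_site[i] <- pl$offset
      } else {
        utr_seqs[i] <- clean_background(config$utr_length,
                                        planted_patterns, circular = FALSE)
      }
    }
    names(utr_seqs) <- mrna_ids(config)

    motif <- default_pfm()
    cons <- motif_consensus(motif)
    planted_mrna <- if (length(axes)) unique(purrr::map_int(axes, "mrna")) else integer(0)
    prom_seqs <- character(config$n_mrna)
    prom_off <- rep(NA_integer_, config$n_mrna)
    w <- nchar(cons)
    for (i in seq_len(config$n_mrna)) {
      if (i %in% planted_mrna) {
        repeat {
          offset <- sample(0:(config$promoter_length - w), 1L)
          s <- random_dna(config$promoter_length)
          substr(s, offset + 1L, offset + w) <- cons
          fwd <- str_find_all(s, cons)
          rev_ <- str_find_all(reverse_complement(s), cons)
          if (identical(fwd, offset) && !length(rev_)) break
        }
        prom_seqs[i] <- s
        prom_off[i] <- offset
      } else {
        prom_seqs[i] <- random_dna(config$promoter_length)
      }
    }
    names(prom_seqs) <- mrna_ids(config)

    annotation <- build_annotation(config, layout)
    pathways <- build_pathways(config, layout)

    truth_axes <- purrr::map(axes, function(a) {
      tibble(circ_id = layout$circ_id[a$circ],
             mir_id = mir_ids(config)[a$mir],
             mrna_id = mrna_ids(config)[a$mrna],
             direction = a$direction, site_type = a$site_type,
             focal_group = a$focal_group,
             circ_site_offset = circ_site[a$circ],
             utr_site_offset = utr_site[a$mrna])
    }) |> purrr::list_rbind()

    list(
      sequences = list(mir = mirs, circ = circ_seqs, utr = utr_seqs,
                       promoter = prom_seqs),
      annotation = annotation,
      catalog = select(layout, "circ_id", "chrom", "start", "end", "strand"),
      pathways = pathways,
      motifs = list(motif),
      truth = list(
        axes = truth_axes,
        circ_class = select(layout, "circ_id", "true_class", "host_gene"),
        promoter_motif = tibble(gene_id = mrna_ids(config),
                                planted_offset = prom_off) |>
          filter(!is.na(.data$planted_offset))
      )
    )
  })
}

# GTF-shaped annotation implementing the planted genomic classes. Host genes
# for exonic circRNAs have two exons bracketing the BSJ endpoints; intronic
# hosts have terminal exons only; intergenic blocks carry no gene. mRNA
# genes are single-exon genes on separate chromosomes.
build_annotation <- function(config, layout) {
  rows <- list()
  for (i in seq_len(nrow(layout))) {
    cls <- layout$true_class[i]
    if (cls == "intergenic") next
    b <- layout$block[i]
    gene <- layout$host_gene[i]
    ex <- if (cls == "exonic") {
      tibble(start = c(b, b + 10000L), end = c(b + 2000L, b + 12000L))
    } else {
      tibble(start = c(b, b + 18000L), end = c(b + 2000L, b + 20000L))
    }
    rows[[length(rows) + 1L]] <- bind_rows(
      tibble(chrom = layout$chrom[i], source = "circena_sim", type = "gene",
             start = min(ex$start), end = max(ex$end), strand = "+",
             gene_id = gene, transcript_id = NA_character_),
      tibble(chrom = layout$chrom[i], source = "circena_sim", type = "exon",
             start = ex$start, end = ex$end, strand = "+",
             gene_id = gene, transcript_id = paste0(gene, ".t1"))
    )
  }
  for (j in seq_len(config$n_mrna)) {
    gene <- mrna_ids(config)[j]
    chrom <- as.character(7L + ((j - 1L) %% 6L))
    b <- 100000L + 50000L * ((j - 1L) %/% 6L)
    rows[[length(rows) + 1L]] <- bind_rows(
      tibble(chrom = chrom, source = "circena_sim", type = "gene",
             start = b, end = b + 3000L, strand = "+",
             gene_id = gene, transcript_id = NA_character_),
      tibble(chrom = chrom, source = "circena_sim", type = "exon",
             start = b, end = b + 3000L, strand = "+",
             gene_id = gene, transcript_id = paste0(gene, ".t1"))
    )
  }
  purrr::list_rbind(rows)
}

# Pathway membership: planted hosts + planted mRNAs (plus two decoy genes)
# form a synthetic hypoxia pathway; remaining genes fill decoy pathways.
build_pathways <- function(config, layout) {
  axes <- config$planted_axes
  planted_hosts <- unique(layout$host_gene[purrr::map_int(axes, "circ")])
  planted_hosts <- planted_hosts[!is.na(planted_hosts)]
  planted_genes <- unique(mrna_ids(config)[purrr::map_int(axes, "mrna")])
  all_genes <- sort(unique(c(layout$host_gene[!is.na(layout$host_gene)],
                             mrna_ids(config))))
  decoy_genes <- setdiff(all_genes, c(planted_hosts, planted_genes))
  hif_members <- c(planted_hosts, planted_genes, utils::head(decoy_genes, 2L))
  hif <- tibble(gene_id = hif_members, pathway_id = "ssc04066",
                pathway_name = "HIF-1 signaling pathway")
  rest <- tibble(
    gene_id = decoy_genes,
    pathway_id = sprintf("path%02d", ((seq_along(decoy_genes) - 1L) %% 10L) + 1L)
  ) |>
    mutate(pathway_name = sprintf("Synthetic pathway %s",
                                  sub("path", "", .data$pathway_id)))
  arrange(bind_rows(hif, rest), .data$pathway_id, .data$gene_id)
}

#' Simulate a complete synthetic ceRNA study
#'
#' Runs [simulate_counts()] and [simulate_sequences()] under one seed and
#' bundles every pipeline input together with the ground truth.
#'
#' @param config A [simulation_config()].
#' @return A `cerna_inputs` list: `counts`, `samples`, `catalog`,
#'   `annotation`, `sequences`, `pathways`, `motifs`, `truth` (which also
#'   records the expected-count matrices and the config).
#' @export
simulate_cerna_study <- function(config = simulation_config()) {
  cts <- simulate_counts(config)
  sq <- simulate_sequences(config)
  structure(
    list(counts = cts$counts, samples = cts$samples, catalog = sq$catalog,
         annotation = sq$annotation, sequences = sq$sequences,
         pathways = sq$pathways, motifs = sq$motifs,
         truth = c(sq$truth, list(means = cts$means, config = config))),
    class = "cerna_inputs"
  )
}

#' Randomly permute the group labels of a sample sheet
#'
#' Destroys any true group structure while keeping the design shape --
#' the negative control for planted-signal recovery.
#'
#' @param samples Sample sheet tibble with a `group` column.
#' @param seed Integer seed for the permutation.
#' @return The sample sheet with `group` permuted across samples.
#' @export
permute_sample_groups <- function(samples, seed) {
  with_seed(seed, {
    samples$group <- sample(samples$group)
    samples
  })
}

#' @export
print.cerna_inputs <- function(x, ...) {
  cfg <- x$truth$config
  cat("<cerna_inputs> synthetic ceRNA study\n")
  cat(sprintf("  %d groups x %d replicates (%s)\n", length(cfg$groups),
              cfg$n_reps, paste(cfg$groups, collapse = "/")))
  cat(sprintf("  features: %d circRNA, %d miRNA, %d mRNA; %d planted axes\n",
              cfg$n_circ, cfg$n_mir, cfg$n_mrna, nrow(x$truth$axes)))
  invisible(x)
}
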