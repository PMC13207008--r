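# JASPAR-format position frequency matrices, log-odds PWMs and both-strand
# promoter scanning with relative profile scores.

pwm_bases <- c("A", "C", "G", "T")

#' Build a position weight matrix from a count (PFM) matrix
#'
#' Converts a 4 x width position frequency matrix into a base-2 log-odds
#' weight matrix: `w(b, j) = log2(((count + pseudocount * bg_b) /
#' (column_total + pseudocount)) / bg_b)`. Score bounds are the column-wise
#' sums of minima/maxima, and the consensus sequence attains `score_max`
#' exactly.
#'
#' @param counts Numeric 4 x width matrix with rownames `A`, `C`, `G`, `T`
#'   and non-negative entries.
#' @param motif_id,name Motif identifier and name.
#' @param pseudocount Positive pseudocount, distributed by background.
#' @param background Named base probabilities summing to 1 (default uniform).
#' @return A `pwm_motif` object (counts, weights, bounds, consensus).
#' @export
pwm_motif <- function(counts, motif_id = "motif", name = motif_id,
                      pseudocount = 0.8,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L || is.null(rownames(counts)) ||
      !setequal(rownames(counts), pwm_bases))
    stop("counts must be a 4-row matrix with rownames A, C, G, T")
  counts <- counts[pwm_bases, , drop = FALSE]
  if (any(counts < 0)) stop("negative counts in PFM")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  background <- background[pwm_bases]
  if (anyNA(background) || abs(sum(background) - 1) > 1e-8)
    stop("background must be 4 probabilities (A, C, G, T) summing to 1")
  totals <- colSums(counts)
  if (any(totals <= 0)) stop("every PFM column needs a positive total")
  prob <- sweep(counts + pseudocount * background, 2, totals + pseudocount, "/")
  weights <- log2(prob / background)
  structure(
    list(motif_id = motif_id, name = name, counts = counts,
         pseudocount = pseudocount, background = background,
         weights = weights,
         score_min = sum(apply(weights, 2, min)),
         score_max = sum(apply(weights, 2, max)),
         width = ncol(counts)),
    class = "pwm_motif"
  )
}

#' @export
print.pwm_motif <- function(x, ...) {
  cat(sprintf("<pwm_motif> %s (%s), width %d, score range [%.3f, %.3f]\n",
              x$motif_id, x$name, x$width, x$score_min, x$score_max))
  cat("  consensus:", motif_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a motif (per-column count argmax)
#'
#' Ties are broken in `A < C < G < T` order.
#'
#' @param motif A [pwm_motif()].
#' @return Consensus string.
#' @export
motif_consensus <- function(motif) {
  stopifnot(inherits(motif, "pwm_motif"))
  paste(pwm_bases[apply(motif$counts, 2, which.max)], collapse = "")
}

#' Read JASPAR-format PFM text
#'
#' Parses the JASPAR 2016+ PFM text format: a `">ID NAME"` header followed
#' by four labelled rows, e.g. `A [ 10 5 2 ]` (brackets optional). Ragged
#' rows, negative counts or unknown base labels raise an error naming the
#' offending line.
#'
#' @param path File path, or a character vector of lines via `text`.
#' @param text Optional character vector of lines (overrides `path`).
#' @inheritParams pwm_motif
#' @return A list of [pwm_motif()] objects (one per record).
#' @export
read_pfm <- function(path = NULL, text = NULL, pseudocount = 0.8,
                     background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  lines <- if (!is.null(text)) text else readLines(path)
  lines <- lines[trimws(lines) != ""]
  headers <- grep("^>", lines)
  if (!length(headers)) stop("no '>' header found in PFM input")
  motifs <- list()
  bounds <- c(headers, length(lines) + 1L)
  for (h in seq_along(headers)) {
    head_line <- lines[headers[h]]
    fields <- strsplit(sub("^>\\s*", "", head_line), "\\s+")[[1]]
    motif_id <- fields[1]
    name <- if (length(fields) > 1) paste(fields[-1], collapse = " ") else motif_id
    body_idx <- (headers[h] + 1L):(bounds[h + 1L] - 1L)
    if (length(body_idx) != 4L)
      stop("motif '", motif_id, "' must have exactly 4 count rows (line ",
           headers[h], ")")
    rows <- list()
    for (i in body_idx) {
      ln <- gsub("\\[|\\]", " ", lines[i])
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      base <- toupper(parts[1])
      if (!base %in% pwm_bases)
        stop("unknown base label '", parts[1], "' at line ", i)
      vals <- suppressWarnings(as.numeric(parts[-1]))
      if (anyNA(vals)) stop("non-numeric count at line ", i)
      if (any(vals < 0)) stop("negative count at line ", i)
      if (base %in% names(rows)) stop("duplicated base row at line ", i)
      rows[[base]] <- vals
    }
    widths <- lengths(rows)
    if (length(unique(widths)) != 1L)
      stop("ragged count rows for motif '", motif_id, "' (lines ",
           min(body_idx), "-", max(body_idx), ")")
    counts <- do.call(rbind, rows[pwm_bases])
    rownames(counts) <- pwm_bases
    motifs[[motif_id]] <- pwm_motif(counts, motif_id = motif_id, name = name,
                                    pseudocount = pseudocount,
                                    background = background)
  }
  motifs
}

#' Write motifs in JASPAR PFM text format
#'
#' @param motifs A [pwm_motif()] or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(motifs, path) {
  if (inherits(motifs, "pwm_motif")) motifs <- list(motifs)
  lines <- purrr::map(motifs, function(m) {
    c(sprintf(">%s %s", m$motif_id, m$name),
      purrr::map_chr(pwm_bases, function(b) {
        sprintf("%s  [ %s ]", b, paste(format(m$counts[b, ]), collapse = " "))
      }))
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

# integer codes 1..4 for ACGT, 5 for anything ambiguous
encode_dna <- function(seq) {
  codes <- match(strsplit(seq, "")[[1]], pwm_bases)
  codes[is.na(codes)] <- 5L
  codes
}

# weights with a 5th row for ambiguous bases: background-weighted average
weights_with_ambiguity <- function(motif) {
  rbind(motif$weights, N = colSums(motif$weights * motif$background))
}

scan_one_strand <- function(codes, wts, width) {
  n_win <- length(codes) - width + 1L
  if (n_win < 1L) return(numeric(0))
  idx <- outer(seq_len(n_win) - 1L, seq_len(width), "+")
  sc <- wts[cbind(as.vector(codes[idx]), rep(seq_len(width), each = n_win))]
  rowSums(matrix(sc, nrow = n_win))
}

#' Scan promoter sequences with a PWM on both strands
#'
#' Scores every window on the forward and (by default) reverse strand and
#' reports hits whose relative profile score
#' `(score - score_min) / (score_max - score_min)` reaches `threshold`.
#' Minus-strand windows are scored on the reverse complement; their offsets
#' refer to the forward-strand coordinate of the window start. Ambiguous
#' bases contribute the background-weighted average weight of their column.
#' A degenerate flat motif (`score_max == score_min`) has relative score 1
#' everywhere by convention.
#'
#' @param motif A [pwm_motif()].
#' @param sequences Named character vector (or `XStringSet`) of promoter
#'   sequences, each at least as long as the motif.
#' @param threshold Relative-score threshold in `[0, 1]` (default 0.80).
#' @param both_strands Scan the reverse strand too?
#' @return Tibble of hits: `sequence_id`, `motif_id`, `offset` (0-based),
#'   `strand`, `matched_sequence` (as read on the hit strand), `score`,
#'   `relative_score`; sorted by sequence, offset, then strand (`+` first).
#' @export
scan_promoter <- function(motif, sequences, threshold = 0.80,
                          both_strands = TRUE) {
  stopifnot(inherits(motif, "pwm_motif"))
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  seqs <- as_named_seqs(sequences)
  if (any(nchar(seqs) == 0)) stop("empty sequence supplied")
  if (any(nchar(seqs) < motif$width))
    stop("sequence shorter than motif width")
  wts <- weights_with_ambiguity(motif)
  rng <- motif$score_max - motif$score_min
  rel <- function(s) if (rng <= 0) rep(1, length(s)) else (s - motif$score_min) / rng

  hits <- purrr::imap(seqs, function(s, id) {
    s <- normalize_seq(s)
    len <- nchar(s)
    fwd <- scan_one_strand(encode_dna(s), wts, motif$width)
    res <- tibble(offset = seq_along(fwd) - 1L, strand = "+", score = fwd)
    if (both_strands) {
      rc <- reverse_complement(s)
      rev_sc <- scan_one_strand(encode_dna(rc), wts, motif$width)
      res <- bind_rows(res, tibble(
        offset = len - motif$width - (seq_along(rev_sc) - 1L),
        strand = "-", score = rev_sc
      ))
    }
    res$relative_score <- rel(res$score)
    res <- filter(res, .data$relative_score >= threshold)
    if (!nrow(res)) return(NULL)
    window <- substr(rep(s, nrow(res)), res$offset + 1L, res$offset + motif$width)
    res$matched_sequence <- ifelse(res$strand == "+", window,
                                   reverse_complement(window))
    res$sequence_id <- id
    res
  }) |> purrr::list_rbind()
  if (is.null(hits) || !nrow(hits)) {
    hits <- tibble(sequence_id = character(), offset = integer(),
                   strand = character(), score = numeric(),
                   relative_score = numeric(), matched_sequence = character())
  }
  hits |>
    mutate(motif_id = motif$motif_id) |>
    arrange(.data$sequence_id, .data$offset, .data$strand) |>
    select("sequence_id", "motif_id", "offset", "strand",
           "matched_sequence", "score", "relative_score")
}

#' Best motif hit per gene
#'
#' Reduces a [scan_promoter()] hit table to one row per scanned gene: the
#' hit with the maximal relative score, ties broken by leftmost offset and
#' then the `+` strand. Genes with no hit get a sentinel row of `NA`s.
#'
#' @param hits Tibble from [scan_promoter()].
#' @param genes Character vector of all scanned gene/promoter ids (so that
#'   hit-free genes are reported); defaults to the ids present in `hits`.
#' @return Tibble: `gene_id`, `motif_id`, `best_score`,
#'   `best_relative_score`, `offset`, `strand`, `matched_sequence`.
#' @export
promoter_report <- function(hits, genes = NULL) {
  if (is.null(genes)) genes <- unique(hits$sequence_id)
  best <- hits |>
    mutate(.strand_rank = ifelse(.data$strand == "+", 0L, 1L)) |>
    arrange(dplyr::desc(.data$relative_score), .data$offset, .data$.strand_rank) |>
    group_by(.data$sequence_id) |>
    slice(1L) |>
    ungroup() |>
    select(gene_id = "sequence_id", "motif_id", best_score = "score",
           best_relative_score = "relative_score", "offset", "strand",
           "matched_sequence")
  missing <- setdiff(genes, best$gene_id)
  if (length(missing)) {
    best <- bind_rows(best, tibble(
      gene_id = missing, motif_id = NA_character_, best_score = NA_real_,
      best_relative_score = NA_real_, offset = NA_integer_,
      strand = NA_character_, matched_sequence = NA_character_
    ))
  }
  arrange(best, match(.data$gene_id, genes))
}
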