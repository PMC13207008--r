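# Canonical miRNA seed-match site detection (TargetScan-style site classes).
#
# The seed region is miRNA nucleotides 2-8. With S7 the reverse complement
# of positions 2-8 and S6 the reverse complement of positions 2-7:
#   8mer    = S7 followed by A
#   7mer-m8 = S7 not followed by A (else it is the 8mer)
#   7mer-A1 = S6 followed by A, not contained in an 8mer site
# Offsets are 0-based; overlapping occurrences are all reported.

site_type_levels <- c("8mer", "7mer-m8", "7mer-A1")

# Seed-derived match patterns for a miRNA (DNA alphabet).
seed_patterns <- function(mir_sequence) {
  mir <- normalize_seq(mir_sequence, allow_ambiguous = FALSE)
  if (nchar(mir) < 8L) stop("miRNA sequence must be at least 8 nt")
  s7 <- reverse_complement(substr(mir, 2L, 8L))
  s6 <- reverse_complement(substr(mir, 2L, 7L))
  list(p8 = paste0(s7, "A"), p7m8 = s7, p7a1 = paste0(s6, "A"))
}

# 0-based offsets of each site class in a target, with the class-partition
# exclusions applied; `pat` from seed_patterns(). The circular extension
# appends the first 7 nt so junction-spanning sites are seen.
site_offsets <- function(pat, target, circular = FALSE) {
  len <- nchar(target)
  scan_seq <- if (circular && len >= 8L) paste0(target, substr(target, 1L, 7L))
              else target
  o8 <- str_find_all(scan_seq, pat$p8)
  o7 <- setdiff(str_find_all(scan_seq, pat$p7m8), o8)
  oa <- setdiff(str_find_all(scan_seq, pat$p7a1), o8 + 1L)
  if (circular && len >= 8L) {
    o8 <- o8[o8 < len]; o7 <- o7[o7 < len]; oa <- oa[oa < len]
  }
  list(o8 = o8, o7m8 = o7, o7a1 = oa, scan_seq = scan_seq)
}

#' Find canonical miRNA seed-match sites in a target sequence
#'
#' Detects 8mer, 7mer-m8 and 7mer-A1 sites (perfect Watson-Crick complements
#' of the miRNA seed) in a target sequence. Site classes partition: an
#' occurrence is reported under exactly one type, with 8mer taking
#' precedence. For circRNA targets set `circular = TRUE` so that the
#' back-splice junction window (sites spanning the end/start boundary) is
#' also scanned.
#'
#' @param mir_sequence miRNA mature sequence (RNA or DNA spelling), length >= 8.
#' @param target_sequence Target sequence (circRNA or 3'UTR).
#' @param mir_id,target_id Identifiers carried into the output.
#' @param target_kind `"circRNA"` or `"3UTR"` (annotation only, except that
#'   `circular` defaults to `TRUE` for circRNAs).
#' @param circular Scan the junction-spanning window? Defaults by `target_kind`.
#' @return A tibble with one row per site: `mir_id`, `target_id`,
#'   `target_kind`, `site_type`, `start_offset` (0-based), `matched_sequence`,
#'   sorted by offset.
#' @export
#' @examples
#' seed_sites("UGGAAGACUAGUGAUUCUA", "AAGTCTTCCAAA")
seed_sites <- function(mir_sequence, target_sequence,
                       mir_id = "mir", target_id = "target",
                       target_kind = c("3UTR", "circRNA"),
                       circular = NULL) {
  target_kind <- match.arg(target_kind)
  if (is.null(circular)) circular <- target_kind == "circRNA"
  pat <- seed_patterns(mir_sequence)
  target <- normalize_seq(target_sequence, allow_ambiguous = FALSE)
  so <- site_offsets(pat, target, circular = circular)
  scan_seq <- so$scan_seq

  res <- tibble(
    site_type    = rep(site_type_levels,
                       c(length(so$o8), length(so$o7m8), length(so$o7a1))),
    start_offset = c(so$o8, so$o7m8, so$o7a1),
    width        = rep(c(8L, 7L, 7L),
                       c(length(so$o8), length(so$o7m8), length(so$o7a1)))
  )
  res <- res |>
    mutate(
      matched_sequence = substr(rep(scan_seq, n()), .data$start_offset + 1L,
                                .data$start_offset + .data$width),
      mir_id = mir_id, target_id = target_id, target_kind = target_kind
    ) |>
    arrange(.data$start_offset, match(.data$site_type, site_type_levels)) |>
    select("mir_id", "target_id", "target_kind", "site_type",
           "start_offset", "matched_sequence")
  res
}

#' Seed-match sites for every miRNA/target combination
#'
#' @param mirs Named character vector (or `Biostrings::XStringSet`) of mature
#'   miRNA sequences.
#' @param targets Named character vector of target sequences.
#' @param target_kind `"circRNA"` or `"3UTR"`, applied to all targets.
#' @return Row-bound [seed_sites()] tibble over all pairs.
#' @export
seed_sites_all <- function(mirs, targets, target_kind = c("3UTR", "circRNA")) {
  target_kind <- match.arg(target_kind)
  empty <- tibble(mir_id = character(), target_id = character(),
                  target_kind = character(), site_type = character(),
                  start_offset = integer(), matched_sequence = character())
  if (!length(mirs) || !length(targets)) return(empty)
  mirs <- as_named_seqs(mirs)
  targets <- as_named_seqs(targets)
  combos <- tidyr::expand_grid(mir_id = names(mirs), target_id = names(targets))
  res <- purrr::pmap(combos, function(mir_id, target_id) {
    seed_sites(mirs[[mir_id]], targets[[target_id]],
               mir_id = mir_id, target_id = target_id,
               target_kind = target_kind)
  }) |>
    purrr::list_rbind()
  if (!nrow(res)) empty else res
}

as_named_seqs <- function(x) {
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
    stop("sequences must be named")
  }
  as.list(x)
}

#' Build deduplicated interaction-pair tables gated by DE sets
#'
#' Retains a (miRNA, target) pair only when both endpoints are in their
#' respective differential-expression sets, then collapses sites to one row
#' per pair with a site count and the best site class
#' (8mer > 7mer-m8 > 7mer-A1).
#'
#' @param sites Tibble from [seed_sites_all()] (any mix of target kinds).
#' @param de_targets Character vector of DE target identifiers
#'   (circRNAs or mRNAs, matching `sites$target_id`).
#' @param de_mirs Character vector of DE miRNA identifiers.
#' @return Tibble: `mir_id`, `target_id`, `target_kind`, `site_count`,
#'   `best_site_type`, sorted by (`target_id`, `mir_id`).
#' @export
interaction_pairs <- function(sites, de_targets, de_mirs) {
  kept <- filter(sites, .data$mir_id %in% de_mirs,
                 .data$target_id %in% de_targets)
  if (!nrow(kept)) {
    return(tibble(mir_id = character(), target_id = character(),
                  target_kind = character(), site_count = integer(),
                  best_site_type = character()))
  }
  kept |>
    group_by(.data$mir_id, .data$target_id, .data$target_kind) |>
    summarise(
      site_count = dplyr::n(),
      best_site_type = site_type_levels[min(match(.data$site_type,
                                                  site_type_levels))],
      .groups = "drop"
    ) |>
    arrange(.data$target_id, .data$mir_id)
}
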