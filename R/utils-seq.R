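# Sequence utilities shared by the generator, the seed matcher and the
# PWM scanner. Sequences are handled internally as uppercase DNA (U -> T).

#' Normalize a nucleotide string to uppercase DNA
#'
#' RNA (`U`) and DNA (`T`) spellings are interchangeable throughout the
#' package; everything is normalized to DNA internally.
#'
#' @param x Character vector of nucleotide sequences.
#' @param allow_ambiguous Allow IUPAC ambiguity codes (e.g. `N`)? When
#'   `FALSE` only `ACGT` (after `U -> T`) is accepted.
#' @return Uppercase DNA character vector.
#' @export
normalize_seq <- function(x, allow_ambiguous = TRUE) {
  out <- chartr("u", "t", toupper(as.character(x)))
  out <- chartr("U", "T", out)
  alphabet <- if (allow_ambiguous) "ACGTRYSWKMBDHVN" else "ACGT"
  bad <- grepl(sprintf("[^%s]", alphabet), out)
  if (any(bad)) {
    stop("non-IUPAC characters in sequence(s): ",
         paste(utils::head(which(bad), 3L), collapse = ", "))
  }
  out
}

#' Reverse complement of DNA sequences
#'
#' @param x Character vector of DNA sequences (`U` accepted, treated as `T`;
#'   IUPAC ambiguity codes are complemented).
#' @return Reverse-complemented character vector.
#' @export
reverse_complement <- function(x) {
  x <- normalize_seq(x)
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# All start offsets (0-based) of `pattern` in `subject`, overlapping allowed.
# Vectorized sliding-window comparison (exact matching, no regex).
str_find_all <- function(subject, pattern) {
  w <- nchar(pattern)
  L <- nchar(subject)
  if (w == 0L || L < w) return(integer(0))
  idx <- seq_len(L - w + 1L)
  which(substring(subject, idx, idx + w - 1L) == pattern) - 1L
}

# Random DNA of length n from per-base probabilities.
random_dna <- function(n, prob = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(prob), n, replace = TRUE, prob = prob), collapse = "")
}
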