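# Exhaustive Venn-region bookkeeping shared by the catalog, DE and pathway
# modules.

#' Venn region counts for a collection of sets
#'
#' Enumerates every non-empty membership pattern over the input sets and
#' counts the elements falling exactly in each region. The region counts
#' always sum to the size of the union.
#'
#' @param sets Named list of character vectors.
#' @return Tibble with one row per possible region (2^n - 1 rows):
#'   `region` (set names joined by `&`), one logical membership column per
#'   set, `n`, and `items` (list column of the member ids, sorted).
#' @export
venn_regions <- function(sets) {
  if (length(sets) < 2L) stop("need at least two sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named")
  sets <- purrr::map(sets, function(s) sort(unique(as.character(s))))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 0L) {
    member <- matrix(logical(0), 0, length(sets),
                     dimnames = list(NULL, names(sets)))
  }
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1L, , drop = FALSE]
  colnames(patterns) <- names(sets)
  out <- purrr::map(seq_len(nrow(patterns)), function(i) {
    pat <- unlist(patterns[i, ])
    inside <- if (length(universe)) {
      apply(member, 1L, function(m) all(m == pat))
    } else logical(0)
    tibble(region = paste(names(sets)[pat], collapse = "&"),
           !!!as.list(pat), n = sum(inside),
           items = list(universe[inside]))
  }) |> purrr::list_rbind()
  out
}
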