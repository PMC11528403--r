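# Pairwise percent identity by global alignment, used to report the
# within-family identity spread (adjacent AARE paralogs share only 40-50%).

#' Global-alignment percent identity between two proteins
#'
#' Needleman-Wunsch global alignment (match +1, mismatch 0, linear gap
#' penalty) via [Biostrings::pairwiseAlignment()]; identity is the number of
#' identical aligned positions over the alignment length (gaps included),
#' times 100.
#'
#' @param a,b Protein sequences as single strings.
#' @param gap Linear per-residue gap penalty (positive number).
#' @return Percent identity in `[0, 100]`.
#' @examples
#' pairwise_identity("AAAA", "AATT") # 50
#' @export
pairwise_identity <- function(a, b, gap = 1) {
  a <- check_protein(a, "a"); b <- check_protein(b, "b")
  letters <- c(AA_ALPHABET, "X")
  sub <- matrix(0, length(letters), length(letters),
                dimnames = list(letters, letters))
  diag(sub) <- 1
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = sub,
    gapOpening = 0, gapExtension = gap
  )
  s1 <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s2 <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(s1 == s2 & s1 != "-") / length(s1)
}

#' Pairwise identity matrix for a set of proteins
#'
#' @param proteins Named character vector of protein sequences.
#' @inheritParams pairwise_identity
#' @return Tibble with columns `id1`, `id2`, `identity` for all unordered
#'   pairs.
#' @export
identity_table <- function(proteins, gap = 1) {
  ids <- names(proteins)
  if (is.null(ids)) abort("`proteins` must be a named character vector")
  if (length(ids) < 2L) {
    return(tibble(id1 = character(0), id2 = character(0), identity = numeric(0)))
  }
  pairs <- combn(ids, 2L)
  tibble(
    id1 = pairs[1, ], id2 = pairs[2, ],
    identity = map_dbl(seq_len(ncol(pairs)), function(i) {
      pairwise_identity(proteins[[pairs[1, i]]], proteins[[pairs[2, i]]], gap = gap)
    })
  )
}
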