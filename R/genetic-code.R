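# Genetic code as a tidy codon -> amino acid table. The standard code (NCBI
# translation table 1) is built in; alternative codes load from the NCBI-style
# five-line text format (AAs / Starts / Base1 / Base2 / Base3).

NUC_ALPHABET <- c("T", "C", "A", "G")

# NCBI translation table 1, in the canonical TCAG nesting order.
STANDARD_CODE_AAS <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

#' The standard genetic code as a tibble
#'
#' Returns the 64-codon table of translation table 1 (or a user-supplied
#' code), the substrate for all codon-graph operations. Codons use the DNA
#' alphabet; `U` on input is always accepted and canonicalised to `T`.
#'
#' @param aas Optional 64-character string of amino acids (with `*` for stop)
#'   in the canonical NCBI codon order (`TTT, TTC, TTA, TTG, CTT, ...`).
#'   Defaults to the standard code.
#' @return A tibble with columns `codon` (3-letter DNA string) and `aa`
#'   (1-letter amino acid, `*` = stop), 64 rows.
#' @examples
#' code <- genetic_code()
#' dplyr::filter(code, aa == "G") # the four glycine codons
#' @export
genetic_code <- function(aas = STANDARD_CODE_AAS) {
  if (!is.character(aas) || length(aas) != 1L || nchar(aas) != 64L) {
    abort("`aas` must be a single 64-character string.")
  }
  grid <- expand.grid(b3 = NUC_ALPHABET, b2 = NUC_ALPHABET, b1 = NUC_ALPHABET,
                      stringsAsFactors = FALSE)
  tibble(
    codon = paste0(grid$b1, grid$b2, grid$b3),
    aa    = strsplit(aas, "")[[1]]
  )
}

#' Read a genetic code from NCBI-style translation-table text
#'
#' Parses the five-line `AAs / Starts / Base1 / Base2 / Base3` block used by
#' NCBI to publish translation tables.
#'
#' @param path Path to a text file containing the block.
#' @return A 64-row codon table tibble, as [genetic_code()].
#' @export
read_translation_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key) {
    ln <- grep(paste0("^\\s*", key, "\\s*="), lines, value = TRUE)
    if (length(ln) != 1L) abort(paste0("expected exactly one `", key, " =` line"))
    gsub(paste0("^\\s*", key, "\\s*=\\s*"), "", ln)
  }
  aas <- get_field("AAs")
  b1 <- strsplit(get_field("Base1"), "")[[1]]
  b2 <- strsplit(get_field("Base2"), "")[[1]]
  b3 <- strsplit(get_field("Base3"), "")[[1]]
  if (nchar(aas) != 64L || length(b1) != 64L) abort("translation table must list 64 codons")
  codons <- canonical_codon(paste0(b1, b2, b3))
  tab <- tibble(codon = codons, aa = strsplit(aas, "")[[1]])
  # reorder into canonical TCAG nesting
  ref <- genetic_code()$codon
  tab <- tab[match(ref, tab$codon), ]
  if (anyNA(tab$aa)) abort("translation table does not cover all 64 codons")
  tab
}

canonical_codon <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- !grepl("^[ACGT]{3}$", x)
  if (any(bad)) {
    abort(paste0("invalid codon(s): ", paste(unique(x[bad]), collapse = ", ")))
  }
  x
}

codons_for <- function(aa, code = genetic_code()) {
  stopifnot(is.character(aa), length(aa) == 1L)
  aa <- toupper(aa)
  out <- code$codon[code$aa == aa]
  if (length(out) == 0L) {
    abort(paste0("amino acid `", aa, "` has no codon in this genetic code"))
  }
  out
}

#' Hamming distance between two codons
#'
#' Number of positions (0-3) at which two codons differ. `T` and `U` are
#' interchangeable. Vectorised over pairs.
#'
#' @param c1,c2 Character vectors of 3-letter codons.
#' @return Integer vector of distances in `0:3`.
#' @examples
#' codon_hamming("GGU", "GCU") # 1
#' @export
codon_hamming <- function(c1, c2) {
  c1 <- canonical_codon(c1)
  c2 <- canonical_codon(c2)
  if (length(c1) != length(c2)) {
    n <- max(length(c1), length(c2))
    c1 <- rep_len(c1, n); c2 <- rep_len(c2, n)
  }
  m1 <- matrix(unlist(strsplit(c1, "")), ncol = 3L, byrow = TRUE)
  m2 <- matrix(unlist(strsplit(c2, "")), ncol = 3L, byrow = TRUE)
  as.integer(rowSums(m1 != m2))
}
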