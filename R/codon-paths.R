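# Codon-graph analysis: the 64 codons form a graph with edges between
# Hamming-distance-1 neighbours. Distances and shortest mutational paths
# between amino acids explain why a catalytic Gly can drift to Ala or Ser in
# one nucleotide change while Thr needs two sequential changes (with Ala- or
# Ser-encoding intermediates, among others).

#' Minimum codon distance between two amino acids
#'
#' The smallest number of nucleotide substitutions converting some codon of
#' `aa_from` into some codon of `aa_to`. Gly to Ala and Gly to Ser are 1;
#' Gly to Thr is 2.
#'
#' @param aa_from,aa_to 1-letter amino acid codes.
#' @param code Codon table from [genetic_code()].
#' @return Integer scalar in `0:3`.
#' @examples
#' min_aa_codon_distance("G", "T") # 2
#' @export
min_aa_codon_distance <- function(aa_from, aa_to, code = genetic_code()) {
  c1 <- codons_for(aa_from, code)
  c2 <- codons_for(aa_to, code)
  grid <- expand.grid(a = c1, b = c2, stringsAsFactors = FALSE)
  min(codon_hamming(grid$a, grid$b))
}

#' Single-nucleotide codon pairs between two amino acids
#'
#' All ordered codon pairs `(from, to)` at Hamming distance 1 that realise an
#' `aa_from` to `aa_to` substitution, optionally restricted to a change at one
#' codon position. The Gly-to-Ser change at position 1 is possible from
#' exactly two Gly codons (GGT->AGT, GGC->AGC).
#'
#' @inheritParams min_aa_codon_distance
#' @param position Optional codon position (1, 2 or 3) at which the change
#'   must occur.
#' @return Tibble with columns `from_codon`, `to_codon`, `position`; zero rows
#'   if no single-step pair exists.
#' @examples
#' single_step_pairs("G", "S", position = 1)
#' @export
single_step_pairs <- function(aa_from, aa_to, code = genetic_code(),
                              position = NULL) {
  if (!is.null(position) && !position %in% 1:3) {
    abort("`position` must be 1, 2 or 3")
  }
  c1 <- codons_for(aa_from, code)
  c2 <- codons_for(aa_to, code)
  grid <- expand.grid(from_codon = c1, to_codon = c2, stringsAsFactors = FALSE)
  grid <- grid[codon_hamming(grid$from_codon, grid$to_codon) == 1L, , drop = FALSE]
  if (nrow(grid) > 0L) {
    pos <- map_int(seq_len(nrow(grid)), function(i) {
      which(strsplit(grid$from_codon[i], "")[[1]] != strsplit(grid$to_codon[i], "")[[1]])
    })
    grid$position <- pos
  } else {
    grid$position <- integer(0)
  }
  if (!is.null(position)) grid <- grid[grid$position == position, , drop = FALSE]
  as_tibble(grid[order(grid$from_codon, grid$to_codon), ])
}

#' Shortest mutational paths between two amino acids on the codon graph
#'
#' Enumerates every shortest codon path (each step a single nucleotide
#' substitution) from any codon of `aa_from` to any codon of `aa_to`, up to
#' `max_steps` substitutions, and annotates the amino acids encoded by
#' interior codons. Stop codons are excluded from the graph unless
#' `allow_stops = TRUE`.
#'
#' @inheritParams min_aa_codon_distance
#' @param max_steps Maximum number of substitutions to consider (>= 1).
#' @param allow_stops Admit stop codons as path interior nodes.
#' @return Tibble with one row per path: `path_id`, `length`, `path`
#'   (codons joined by `->`), `intermediate_codons`, `intermediate_aas`
#'   (comma-separated, empty for direct paths). Zero rows if no path exists
#'   within `max_steps`. Paths are ordered lexicographically by codon string.
#' @examples
#' mutational_paths("G", "T", max_steps = 2)
#' @export
mutational_paths <- function(aa_from, aa_to, max_steps = 3L,
                             code = genetic_code(), allow_stops = FALSE) {
  if (max_steps < 1L) abort("`max_steps` must be >= 1")
  start <- codons_for(aa_from, code)
  target <- codons_for(aa_to, code)
  nodes <- if (allow_stops) code$codon else code$codon[code$aa != "*"]
  # interior nodes come from `nodes`; endpoints are always admitted
  d <- min_aa_codon_distance(aa_from, aa_to, code)
  if (d > max_steps) return(empty_paths())

  # distance from each node to the nearest target codon, for pruning
  dist_to_target <- map_int(code$codon, function(cc) min(codon_hamming(rep(cc, length(target)), target)))
  names(dist_to_target) <- code$codon

  paths <- list()
  extend <- function(path, L) {
    last <- path[length(path)]
    steps_used <- length(path) - 1L
    if (last %in% target && steps_used == L) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    if (steps_used >= L) return(invisible())
    nb <- nodes[codon_hamming(rep(last, length(nodes)), nodes) == 1L]
    nb <- nb[dist_to_target[nb] <= L - steps_used - 1L]
    for (cc in sort(nb)) extend(c(path, cc), L)
  }
  if (d == 0L) {
    for (cc in sort(intersect(start, target))) paths[[length(paths) + 1L]] <- cc
  } else {
    # shortest viable length may exceed the raw codon distance when stop
    # codons are excluded as interior nodes; step up until paths appear
    for (L in seq(d, max_steps)) {
      for (cc in sort(start)) extend(cc, L)
      if (length(paths) > 0L) break
    }
  }
  if (length(paths) == 0L) return(empty_paths())

  tb <- map(paths, function(p) {
    interior <- if (length(p) > 2L) p[-c(1L, length(p))] else character(0)
    tibble(
      length = length(p) - 1L,
      path = paste(p, collapse = "->"),
      intermediate_codons = paste(interior, collapse = ","),
      intermediate_aas = paste(code$aa[match(interior, code$codon)], collapse = ",")
    )
  })
  out <- list_rbind(tb)
  out <- out[order(out$path), ]
  out$path_id <- seq_len(nrow(out))
  out[, c("path_id", "length", "path", "intermediate_codons", "intermediate_aas")]
}

empty_paths <- function() {
  tibble(path_id = integer(0), length = integer(0), path = character(0),
         intermediate_codons = character(0), intermediate_aas = character(0))
}

#' Codon-distance table for a set of amino acids
#'
#' Convenience wrapper tabulating [min_aa_codon_distance()] over all ordered
#' pairs, as used to compare candidate catalytic residues against Gly.
#'
#' @param aas Character vector of 1-letter amino acids.
#' @inheritParams min_aa_codon_distance
#' @return Tibble with columns `from`, `to`, `distance`.
#' @export
codon_distance_table <- function(aas = c("G", "A", "S", "T"),
                                 code = genetic_code()) {
  grid <- expand.grid(from = aas, to = aas, stringsAsFactors = FALSE)
  grid$distance <- map_int(seq_len(nrow(grid)),
                           function(i) min_aa_codon_distance(grid$from[i], grid$to[i], code))
  as_tibble(grid[order(grid$from, grid$to), ])
}
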