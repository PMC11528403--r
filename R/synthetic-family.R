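# Seeded generator for a GRE-like protein family with planted catalytic-
# residue classes. The ancestor carries the C-terminal fingerprint loop
# (R-V-x-G-[FWY]) and a mid-sequence catalytic Cys; each class descends from
# its own class ancestor (giving clade structure), with the planted Gly->
# Ala/Ser/Thr substitution in the catalytic slot. Random residues are drawn
# from a Cys-free alphabet so the planted catalytic Cys is the unique thiol
# and decoys can be made Cys-free deterministically; motif anchor positions
# and the Cys are immutable during descent.

RANDOM_AA <- setdiff(AA_ALPHABET, "C")

CATALYTIC_CODON <- c(G = "GGT", A = "GCT", S = "AGT", T = "ACT")

#' Specification for a synthetic GRE-like family
#'
#' Defaults mirror the discovery-scale class counts (17 ARE, 21 SRE, 71 TRE)
#' used throughout the package's demonstration runs.
#'
#' @param n_per_class Named integer vector of planted class counts over
#'   `GRE`, `ARE`, `SRE`, `TRE` (any subset).
#' @param n_decoy_nocys Planted decoys carrying the fingerprint but no Cys.
#' @param n_decoy_noae Planted decoys with fingerprint and Cys that will be
#'   emitted without an adjacent activase by [generate_neighborhoods()].
#' @param n_outgroup Distant NrdD-like outgroup sequences (fingerprint with
#'   catalytic Gly, Cys present, high divergence).
#' @param protein_length Sequence length (default 800, GRE scale).
#' @param mutation_rate_per_site Per-site substitution probability on each
#'   class branch; leaf branches use a third of it. Must be in (0, 0.3).
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(n_per_class = c(GRE = 0, ARE = 17, SRE = 21, TRE = 71),
                        n_decoy_nocys = 5,
                        n_decoy_noae = 5,
                        n_outgroup = 1,
                        protein_length = 800,
                        mutation_rate_per_site = 0.12,
                        seed = 1) {
  stopifnot(all(names(n_per_class) %in% c("GRE", "ARE", "SRE", "TRE")),
            all(n_per_class >= 0))
  if (!(mutation_rate_per_site > 0 && mutation_rate_per_site < 0.3)) {
    abort("`mutation_rate_per_site` must lie in (0, 0.3)")
  }
  if (protein_length < 60) abort("`protein_length` must be >= 60")
  structure(list(n_per_class = n_per_class, n_decoy_nocys = n_decoy_nocys,
                 n_decoy_noae = n_decoy_noae,
                 n_outgroup = n_outgroup, protein_length = as.integer(protein_length),
                 mutation_rate = mutation_rate_per_site, seed = as.integer(seed)),
            class = "family_spec")
}

# deterministic reverse translation; catalytic slot follows the minimal
# mutational path from the Gly codon GGT (Ala/Ser one change, Thr two)
reverse_translate <- function(protein, catalytic_position, code = genetic_code()) {
  chars <- strsplit(protein, "")[[1]]
  codons <- map_chr(seq_along(chars), function(i) {
    aa <- chars[i]
    if (i == catalytic_position && aa %in% names(CATALYTIC_CODON)) {
      return(CATALYTIC_CODON[[aa]])
    }
    codons_for(aa, code)[1]
  })
  paste(codons, collapse = "")
}

translate_cds <- function(cds, code = genetic_code()) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(code$aa[match(codons, code$codon)], collapse = "")
}

mutate_protein <- function(chars, rate, frozen) {
  n <- length(chars)
  hit <- which(stats::runif(n) < rate)
  hit <- setdiff(hit, frozen)
  if (length(hit) > 0L) {
    chars[hit] <- sample(RANDOM_AA, length(hit), replace = TRUE)
  }
  chars
}

#' Generate a synthetic GRE-like protein family
#'
#' Builds an ancestral sequence with the C-terminal fingerprint window
#' (catalytic residue five positions from the end) and a catalytic Cys at
#' mid-sequence, evolves one class ancestor per planted class (installing the
#' class's catalytic residue), then evolves leaves within each class.
#' Decoys carry the fingerprint but lack any Cys; outgroup sequences are
#' generated at threefold class-branch divergence. Coding sequences are
#' produced by deterministic reverse translation with the catalytic codon
#' chosen on the minimal mutational path from Gly (GGT -> GCT/AGT/ACT).
#'
#' @param spec A [family_spec()].
#' @return A list of class `synthetic_family`: `proteins` and `cds` (named
#'   character vectors) and `truth` (tibble `id`, `class`, `expected_class`,
#'   `catalytic_position`, `cys_position`).
#' @export
generate_family <- function(spec = family_spec()) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  L <- spec$protein_length
  rate <- spec$mutation_rate

  anc <- sample(RANDOM_AA, L, replace = TRUE)
  cat_pos <- L - 4L + 3L            # catalytic slot of the length-5 window at L-4..L
  motif_start <- L - 4L
  anc[motif_start] <- "R"; anc[motif_start + 1L] <- "V"
  anc[cat_pos] <- "G"
  anc[motif_start + 4L] <- sample(c("F", "W", "Y"), 1)
  cys_pos <- as.integer(round(0.5 * L))
  anc[cys_pos] <- "C"
  frozen <- c(motif_start, motif_start + 1L, cat_pos, motif_start + 4L, cys_pos)

  classes <- names(spec$n_per_class)[spec$n_per_class > 0]
  proteins <- character(0); truth <- list()

  emit <- function(chars, id, class, expected, cys_present) {
    proteins[[id]] <<- paste(chars, collapse = "")
    truth[[length(truth) + 1L]] <<- tibble(
      id = id, class = class, expected_class = expected,
      catalytic_position = cat_pos,
      cys_position = if (cys_present) cys_pos else NA_integer_
    )
  }

  for (cl in classes) {
    class_anc <- mutate_protein(anc, rate, frozen)
    class_anc[cat_pos] <- names(CLASS_BY_RESIDUE)[CLASS_BY_RESIDUE == cl]
    for (k in seq_len(spec$n_per_class[[cl]])) {
      leaf <- mutate_protein(class_anc, rate / 3, frozen)
      emit(leaf, sprintf("%s_%02d", cl, k), cl, cl, cys_present = TRUE)
    }
  }
  if (spec$n_decoy_nocys > 0) {
    for (k in seq_len(spec$n_decoy_nocys)) {
      dc <- mutate_protein(anc, rate, frozen)
      dc[cys_pos] <- sample(setdiff(RANDOM_AA, "C"), 1)  # remove the only Cys
      emit(dc, sprintf("decoy_nocys_%02d", k), "decoy_nocys", "fingerprint_only",
           cys_present = FALSE)
    }
  }
  if (spec$n_decoy_noae > 0) {
    residues <- rep(c("A", "S", "T"), length.out = spec$n_decoy_noae)
    for (k in seq_len(spec$n_decoy_noae)) {
      dc <- mutate_protein(anc, rate, frozen)
      dc[cat_pos] <- residues[k]
      emit(dc, sprintf("decoy_noae_%02d", k), "decoy_noae", "fingerprint_only",
           cys_present = TRUE)
    }
  }
  if (spec$n_outgroup > 0) {
    # NrdD-like outgroup: an authentic (distant) glycyl radical enzyme
    for (k in seq_len(spec$n_outgroup)) {
      og <- mutate_protein(anc, min(3 * rate, 0.6), frozen)
      emit(og, sprintf("NrdD_%02d", k), "outgroup", "GRE", cys_present = TRUE)
    }
  }

  empty_truth <- tibble(id = character(0), class = character(0),
                        expected_class = character(0),
                        catalytic_position = integer(0), cys_position = integer(0))
  truth <- if (length(truth) > 0L) list_rbind(truth) else empty_truth
  cds <- map_chr(truth$id, function(id) reverse_translate(proteins[[id]], cat_pos))
  names(cds) <- truth$id
  structure(list(proteins = unlist(proteins) %||% setNames(character(0), character(0)),
                 cds = cds, truth = truth,
                 spec = spec),
            class = "synthetic_family")
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat(sprintf("<synthetic_family> %d proteins (length %d), seed %d\n",
              length(x$proteins), x$spec$protein_length, x$spec$seed))
  print(count(x$truth, .data$class), ...)
  invisible(x)
}
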