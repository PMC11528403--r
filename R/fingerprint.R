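# Fingerprint-motif scanning. The GRE superfamily carries a conserved
# C-terminal catalytic-loop signature R-V-x-G-[FWY] housing the radical Gly;
# AARE candidates match the same anchored pattern with Ala, Ser or Thr in the
# catalytic slot. Scanning is an anchored position-pattern match over the
# residue string, with configurable anchors.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

CLASS_BY_RESIDUE <- c(G = "GRE", A = "ARE", S = "SRE", T = "TRE")

#' Fingerprint pattern configuration
#'
#' Describes the anchored catalytic-loop motif: fixed anchor residues at given
#' offsets, a wildcard slot, the allowed catalytic residues, and the aromatic
#' cap. Defaults encode R-V-x-\[GAST\]-\[FWY\], the generalisation of the GRE
#' fingerprint that admits Ala/Ser/Thr in the catalytic slot.
#'
#' @param anchors Named list mapping 0-based offsets (as character keys) to
#'   allowed residue sets at that offset.
#' @param catalytic_offset 0-based offset of the catalytic slot.
#' @param catalytic_residues Allowed catalytic residues.
#' @param cterminal_fraction Hits whose catalytic residue lies in the final
#'   `cterminal_fraction` of the sequence count as C-terminal.
#' @return A list of class `fingerprint_config`.
#' @export
fingerprint_config <- function(anchors = list(`0` = "R", `1` = "V", `4` = c("F", "W", "Y")),
                               catalytic_offset = 3L,
                               catalytic_residues = c("G", "A", "S", "T"),
                               cterminal_fraction = 0.25) {
  width <- max(as.integer(names(anchors)), catalytic_offset) + 1L
  structure(list(anchors = anchors,
                 catalytic_offset = as.integer(catalytic_offset),
                 catalytic_residues = catalytic_residues,
                 cterminal_fraction = cterminal_fraction,
                 width = width),
            class = "fingerprint_config")
}

check_protein <- function(sequence, id = "protein") {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L) {
    abort(paste0("sequence for `", id, "` must be a non-empty string"))
  }
  toupper(sequence)
}

#' Scan a protein for the catalytic-loop fingerprint motif
#'
#' Finds every match of the anchored fingerprint (default R-V-x-\[GAST\]-\[FWY\])
#' and reports the catalytic residue with its enzyme-class label (G -> GRE,
#' A -> ARE, S -> SRE, T -> TRE). Overlapping matches are all reported;
#' positions are 1-based. Case-insensitive.
#'
#' @param sequence Protein sequence (1-letter residues) as a single string.
#' @param config A [fingerprint_config()].
#' @param id Protein identifier carried into the result.
#' @return Tibble with columns `protein_id`, `position` (1-based index of the
#'   catalytic residue), `catalytic_residue`, `class_label`, `window` (the
#'   matched subsequence), `cterminal` (logical).
#' @examples
#' scan_fingerprint("MARVCTFQ") # one TRE hit at position 6
#' @export
scan_fingerprint <- function(sequence, config = fingerprint_config(),
                             id = "protein") {
  seq <- check_protein(sequence, id)
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  w <- config$width
  hits <- tibble(protein_id = character(0), position = integer(0),
                 catalytic_residue = character(0), class_label = character(0),
                 window = character(0), cterminal = logical(0))
  if (L < w) return(hits)
  starts <- seq_len(L - w + 1L)
  ok <- rep(TRUE, length(starts))
  for (off in names(config$anchors)) {
    ok <- ok & chars[starts + as.integer(off)] %in% config$anchors[[off]]
  }
  cat_res <- chars[starts + config$catalytic_offset]
  ok <- ok & cat_res %in% config$catalytic_residues
  starts <- starts[ok]
  if (length(starts) == 0L) return(hits)
  pos <- starts + config$catalytic_offset
  tibble(
    protein_id = id,
    position = pos,
    catalytic_residue = chars[pos],
    class_label = unname(CLASS_BY_RESIDUE[chars[pos]]),
    window = substring(seq, starts, starts + w - 1L),
    cterminal = pos / L > 1 - config$cterminal_fraction
  )
}

#' Locate candidate catalytic cysteines
#'
#' Positions of Cys residues in the central region of the protein, where the
#' thiyl-radical cysteine of GRE-family enzymes sits. The window is expressed
#' as a fraction of sequence length, default \[0.35, 0.70).
#'
#' @inheritParams scan_fingerprint
#' @param window Length-2 numeric, relative-position window `[low, high)`.
#' @return Integer vector of 1-based Cys positions inside the window.
#' @export
check_catalytic_cys <- function(sequence, window = c(0.35, 0.70),
                                id = "protein") {
  if (!(window[1] >= 0 && window[1] < window[2] && window[2] <= 1)) {
    abort("`window` must satisfy 0 <= low < high <= 1")
  }
  seq <- check_protein(sequence, id)
  chars <- strsplit(seq, "")[[1]]
  pos <- which(chars == "C")
  rel <- pos / length(chars)
  pos[rel >= window[1] & rel < window[2]]
}

#' Scan for the radical-SAM CX3CX2C cluster-binding motif
#'
#' All (possibly overlapping) start positions of the cysteine spacing motif
#' C-x(3)-C-x(2)-C that ligates the SAM-binding \[Fe4S4\] cluster of radical
#' SAM activating enzymes.
#'
#' @inheritParams scan_fingerprint
#' @return Integer vector of 1-based match start positions.
#' @examples
#' scan_rsam_motif("MCTTTCAAC") # 2
#' @export
scan_rsam_motif <- function(sequence, id = "protein") {
  seq <- check_protein(sequence, id)
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  if (L < 8L) return(integer(0))  # motif spans 8 residues: C xxx C xx C
  starts <- seq_len(L - 7L)
  starts[chars[starts] == "C" & chars[starts + 4L] == "C" & chars[starts + 7L] == "C"]
}

#' Classify a candidate from its assembled evidence
#'
#' Applies the discovery rule: a fingerprint hit is called by its catalytic
#' residue class (GRE/ARE/SRE/TRE) only when the candidate also retains the
#' central catalytic Cys and is encoded next to a radical-SAM activase;
#' otherwise it is reported as `fingerprint_only`.
#'
#' @param class_label Class from the fingerprint hit (`GRE`/`ARE`/`SRE`/`TRE`).
#' @param has_cys Logical, catalytic-Cys evidence present.
#' @param has_ae Logical, adjacent activase evidence present.
#' @return Character label.
#' @export
classify_candidate <- function(class_label, has_cys, has_ae) {
  n <- max(length(class_label), length(has_cys), length(has_ae))
  class_label <- rep_len(class_label, n)
  has_cys <- rep_len(has_cys, n)
  has_ae <- rep_len(has_ae, n)
  ifelse(!is.na(class_label) & has_cys & has_ae, class_label, "fingerprint_only")
}
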