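# File-format helpers: FASTA via Biostrings, two-column spectrum text, and
# YAML spin-system configs.

#' Read protein sequences from FASTA
#'
#' @param path Path to a (possibly aligned) protein FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Read nucleotide sequences from FASTA
#'
#' @param path Path to a DNA FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_dna_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param type `"AA"` or `"DNA"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::AAStringSet(seqs) else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a spectrum to two-column text
#'
#' Whitespace-delimited `field_mT intensity` pairs with a comment header
#' recording the mode.
#'
#' @param spectrum An [epr_spectrum()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# field_mT intensity mode=%s", spectrum_mode(spectrum)), con)
  writeLines(sprintf("%.8g %.10g", spectrum$field, spectrum$intensity), con)
  invisible(path)
}

#' Read a spectrum from two-column text
#'
#' @param path Path written by [write_spectrum()] (or any two-column
#'   field/intensity text; mode defaults to `first_derivative` when no header
#'   declares it).
#' @return An [epr_spectrum()] tibble.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#", lines, value = TRUE)
  mode <- "first_derivative"
  m <- regmatches(header, regexpr("mode=\\S+", header))
  if (length(m) > 0L) mode <- sub("mode=", "", m[[1]])
  body <- lines[!grepl("^#|^\\s*$", lines)]
  parts <- strsplit(trimws(body), "\\s+")
  epr_spectrum(field = as.numeric(map_chr(parts, 1)),
               intensity = as.numeric(map_chr(parts, 2)),
               mode = mode)
}

#' Read a spin system from a YAML config
#'
#' Keys: `g` (length-3 numeric), `couplings` (list of `{a_iso_mhz, n}`),
#' `mw_ghz`.
#'
#' @param path Path to the YAML file.
#' @return A [spin_system()].
#' @export
read_spin_system <- function(path) {
  cfg <- yaml::read_yaml(path)
  couplings <- map(cfg$couplings %||% list(), function(x) {
    # the YAML 1.1 parser reads a bare `n` key as boolean FALSE; undo that
    names(x)[names(x) %in% c("FALSE", "no")] <- "n"
    list(a_iso = x$a_iso_mhz, n = x$n)
  })
  spin_system(g = unlist(cfg$g), couplings = couplings, mw_ghz = cfg$mw_ghz)
}
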