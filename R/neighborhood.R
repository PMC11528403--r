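# Gene-neighborhood analysis: every authentic AARE is encoded next to a
# radical-SAM activating enzyme (AE). AREs and SREs pair one-to-one with an
# AE; TREs typically come as two TRE genes flanking a single shared TRE-AE.
# Coordinates are 1-based closed intervals (GFF3 convention); the intergenic
# distance between consecutive genes is start(next) - end(prev) - 1.

#' Pair fingerprint-bearing genes with adjacent radical-SAM activases
#'
#' For each gene in `genes` whose protein carries a fingerprint hit, finds the
#' nearest gene on the same contig whose protein contains the CX3CX2C
#' radical-SAM motif, subject to a maximum intergenic gap. Adjacency is
#' strand-agnostic by default. An activase claimed by two or more candidates
#' yields the atypical `two_candidates_one_ae` arrangement (as seen for TRE
#' pairs); otherwise `one_to_one`.
#'
#' @param genes Tibble of gene features with columns `contig_id`, `gene_id`,
#'   `start`, `end`, `strand`, `protein_id` (1-based closed intervals).
#' @param proteins Named character vector of protein sequences covering every
#'   `protein_id` in `genes`.
#' @param max_gap_bp Maximum intergenic distance in bp (default 500).
#' @param config Fingerprint pattern, see [fingerprint_config()].
#' @param require_coorientation If `TRUE`, only same-strand activases pair.
#' @return Tibble with columns `candidate_id` (protein id), `ae_id`,
#'   `gap_bp`, `arrangement`.
#' @export
find_ae_partners <- function(genes, proteins, max_gap_bp = 500,
                             config = fingerprint_config(),
                             require_coorientation = FALSE) {
  needed <- c("contig_id", "gene_id", "start", "end", "strand", "protein_id")
  if (!all(needed %in% names(genes))) {
    abort(paste0("`genes` must have columns: ", paste(needed, collapse = ", ")))
  }
  missing <- setdiff(genes$protein_id, names(proteins))
  if (length(missing) > 0L) {
    abort(paste0("unresolvable protein_id(s): ", paste(missing, collapse = ", ")))
  }
  genes <- arrange(genes, .data$contig_id, .data$start)
  is_candidate <- map_int(genes$protein_id,
                          function(p) nrow(scan_fingerprint(proteins[[p]], config, id = p))) > 0L
  is_ae <- map_int(genes$protein_id,
                   function(p) length(scan_rsam_motif(proteins[[p]], id = p))) > 0L

  gap_between <- function(i, j) {
    # intergenic bp between two features on the same contig
    if (genes$start[i] > genes$start[j]) { k <- i; i <- j; j <- k }
    max(genes$start[j] - genes$end[i] - 1L, 0L)
  }

  rows <- list()
  for (i in which(is_candidate)) {
    js <- which(is_ae & genes$contig_id == genes$contig_id[i] & seq_len(nrow(genes)) != i)
    if (require_coorientation) js <- js[genes$strand[js] == genes$strand[i]]
    if (length(js) == 0L) next
    gaps <- map_int(js, function(j) as.integer(gap_between(i, j)))
    best <- which.min(gaps)
    if (gaps[best] <= max_gap_bp) {
      rows[[length(rows) + 1L]] <- tibble(
        candidate_id = genes$protein_id[i],
        ae_id = genes$protein_id[js[best]],
        gap_bp = gaps[best]
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble(candidate_id = character(0), ae_id = character(0),
                  gap_bp = integer(0), arrangement = character(0)))
  }
  out <- list_rbind(rows)
  shared <- table(out$ae_id)
  out$arrangement <- unname(ifelse(shared[out$ae_id] >= 2L,
                                   "two_candidates_one_ae", "one_to_one"))
  out
}

#' Read gene features from a GFF3 file
#'
#' Thin wrapper over [rtracklayer::import()] returning the tidy gene table
#' used by [find_ae_partners()]. Features of type `gene` are kept; the
#' `protein_id` attribute (falling back to `ID`) identifies the product.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with columns `contig_id`, `gene_id`, `start`, `end`,
#'   `strand`, `protein_id`.
#' @export
read_gene_table <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  pid <- if ("protein_id" %in% names(mc)) as.character(mc$protein_id) else as.character(mc$ID)
  tibble(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    gene_id = as.character(mc$ID),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    protein_id = pid
  ) |> arrange(.data$contig_id, .data$start)
}

#' Write a gene table to GFF3
#'
#' @param genes Tibble as returned by [read_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$protein_id <- genes$protein_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
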