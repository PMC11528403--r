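# Seeded gene-neighborhood generator obeying the discovery's adjacency
# rules: GREs, AREs and SREs each sit next to their own radical-SAM activase
# (AE); TREs are emitted in pairs flanking a single shared AE (the atypical
# two-TREs-one-AE arrangement); decoys tagged `decoy_noae` get no AE gene.

AE_LENGTH <- 300L

random_ae_protein <- function(len = AE_LENGTH, motif_start = 30L) {
  chars <- sample(RANDOM_AA, len, replace = TRUE)
  chars[motif_start] <- "C"
  chars[motif_start + 4L] <- "C"
  chars[motif_start + 7L] <- "C"
  paste(chars, collapse = "")
}

#' Generate gene neighborhoods for a synthetic family
#'
#' Lays each candidate gene on its own contig together with (per the
#' arrangement rules) an adjacent activase gene whose protein carries the
#' CX3CX2C cluster-binding motif. TRE candidates are consumed in pairs
#' sharing one AE; an odd trailing TRE falls back to a one-to-one
#' arrangement. Gene coordinates are 1-based closed intervals with a fixed
#' intergenic gap.
#'
#' @param family A [generate_family()] result (or its `truth` tibble plus
#'   `proteins`).
#' @param gap_bp Intergenic distance between adjacent genes (default 100).
#' @param tre_order `"tre_ae_tre"` (AE between the two TREs) or
#'   `"tre_tre_ae"`.
#' @param seed Integer seed for the AE protein sequences.
#' @return List of class `synthetic_neighborhoods`: `genes` (tidy gene
#'   table), `ae_proteins` (named character vector), `arrangements` (tibble
#'   `id`, `ae_id`, `arrangement`; `NA` for candidates without AE).
#' @export
generate_neighborhoods <- function(family, gap_bp = 100,
                                   tre_order = c("tre_ae_tre", "tre_tre_ae"),
                                   seed = 1) {
  tre_order <- match.arg(tre_order)
  stopifnot(inherits(family, "synthetic_family"))
  set.seed(seed)
  truth <- family$truth
  prot_len <- nchar(family$proteins[truth$id])

  genes <- list(); ae_proteins <- character(0); arrangements <- list()
  contig_i <- 0L

  lay_contig <- function(ids, lens, pids) {
    contig_i <<- contig_i + 1L
    start <- 1L
    rows <- list()
    for (k in seq_along(ids)) {
      end <- start + lens[k] - 1L
      rows[[k]] <- tibble(contig_id = sprintf("contig_%03d", contig_i),
                          gene_id = ids[k], start = start, end = end,
                          strand = "+", protein_id = pids[k])
      start <- end + gap_bp + 1L
    }
    genes[[length(genes) + 1L]] <<- list_rbind(rows)
  }

  new_ae <- function(stem) {
    ae_id <- paste0(stem, "_AE")
    ae_proteins[[ae_id]] <<- random_ae_protein()
    ae_id
  }

  note <- function(id, ae_id, arrangement) {
    arrangements[[length(arrangements) + 1L]] <<-
      tibble(id = id, ae_id = ae_id, arrangement = arrangement)
  }

  gene_len <- function(id) 3L * nchar(family$proteins[[id]]) + 3L

  singles <- truth$id[truth$class %in% c("GRE", "ARE", "SRE", "outgroup", "decoy_nocys")]
  for (id in singles) {
    ae_id <- new_ae(id)
    lay_contig(c(id, ae_id), c(gene_len(id), 3L * AE_LENGTH + 3L), c(id, ae_id))
    note(id, ae_id, "one_to_one")
  }

  noae <- truth$id[truth$class == "decoy_noae"]
  for (id in noae) {
    lay_contig(id, gene_len(id), id)
    note(id, NA_character_, NA_character_)
  }

  tres <- truth$id[truth$class == "TRE"]
  n_pairs <- length(tres) %/% 2L
  for (p in seq_len(n_pairs)) {
    pair <- tres[c(2L * p - 1L, 2L * p)]
    ae_id <- new_ae(paste(pair, collapse = "_"))
    order_ids <- if (tre_order == "tre_ae_tre") c(pair[1], ae_id, pair[2]) else c(pair, ae_id)
    lay_contig(order_ids, map_int(order_ids, function(i) {
      if (i == ae_id) 3L * AE_LENGTH + 3L else gene_len(i)
    }), order_ids)
    note(pair[1], ae_id, "two_candidates_one_ae")
    note(pair[2], ae_id, "two_candidates_one_ae")
  }
  if (length(tres) %% 2L == 1L) {
    id <- tres[length(tres)]
    ae_id <- new_ae(id)
    lay_contig(c(id, ae_id), c(gene_len(id), 3L * AE_LENGTH + 3L), c(id, ae_id))
    note(id, ae_id, "one_to_one")
    warn(sprintf("odd TRE count: `%s` emitted with a one_to_one arrangement", id))
  }

  empty_genes <- tibble(contig_id = character(0), gene_id = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), protein_id = character(0))
  structure(list(genes = if (length(genes) > 0L) list_rbind(genes) else empty_genes,
                 ae_proteins = unlist(ae_proteins) %||% setNames(character(0), character(0)),
                 arrangements = if (length(arrangements) > 0L) list_rbind(arrangements) else
                   tibble(id = character(0), ae_id = character(0), arrangement = character(0))),
            class = "synthetic_neighborhoods")
}

#' All proteins of a synthetic family plus its neighborhood activases
#'
#' @param family A [generate_family()] result.
#' @param neighborhoods A [generate_neighborhoods()] result.
#' @return Named character vector of protein sequences.
#' @export
family_protein_db <- function(family, neighborhoods) {
  c(family$proteins, neighborhoods$ae_proteins)
}
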