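# End-to-end candidate screen: fingerprint scan + catalytic-Cys check +
# activase adjacency, combined into a per-protein classification. This is the
# in-silico discovery step that separates authentic GRE/ARE/SRE/TRE
# candidates from fingerprint-only lookalikes.

#' Screen a protein database for GRE/AARE candidates
#'
#' Runs the fingerprint scan over every protein, checks the central catalytic
#' Cys, pairs candidates with adjacent radical-SAM activases from the gene
#' table, and classifies each fingerprint-bearing protein. When several
#' fingerprint hits overlap, the most C-terminal one drives classification.
#'
#' @param proteins Named character vector of protein sequences.
#' @param genes Optional gene table (see [read_gene_table()]); without it no
#'   activase evidence is available and every hit classifies
#'   `fingerprint_only`.
#' @param config Fingerprint pattern configuration.
#' @param cys_window Relative-position window for the catalytic Cys.
#' @param max_gap_bp Maximum candidate-activase intergenic gap in bp.
#' @param require_cterminal Require the driving hit to lie in the C-terminal
#'   region defined by `config$cterminal_fraction`.
#' @return An object of class `aare_screen`: a tibble with one row per
#'   fingerprint-bearing protein and columns `protein_id`, `class`,
#'   `position`, `catalytic_residue`, `cys_position`, `ae_id`, `arrangement`,
#'   plus attributes recording the inputs.
#' @examples
#' screen_proteins(c(p1 = "MKLARVCGFAAKLM"))
#' @export
screen_proteins <- function(proteins, genes = NULL,
                            config = fingerprint_config(),
                            cys_window = c(0.35, 0.70),
                            max_gap_bp = 500,
                            require_cterminal = TRUE) {
  ids <- names(proteins)
  if (is.null(ids) && length(proteins) > 0L) {
    abort("`proteins` must be a named character vector")
  }

  partners <- if (!is.null(genes) && nrow(genes) > 0L) {
    find_ae_partners(genes, proteins, max_gap_bp = max_gap_bp, config = config)
  } else {
    tibble(candidate_id = character(0), ae_id = character(0),
           gap_bp = integer(0), arrangement = character(0))
  }

  rows <- map(ids, function(id) {
    hits <- scan_fingerprint(proteins[[id]], config, id = id)
    if (require_cterminal) hits <- hits[hits$cterminal, , drop = FALSE]
    if (nrow(hits) == 0L) return(NULL)
    hit <- hits[which.max(hits$position), ]
    cys <- check_catalytic_cys(proteins[[id]], window = cys_window, id = id)
    ae <- partners[partners$candidate_id == id, , drop = FALSE]
    tibble(
      protein_id = id,
      class = classify_candidate(hit$class_label,
                                 has_cys = length(cys) > 0L,
                                 has_ae = nrow(ae) > 0L),
      position = hit$position,
      catalytic_residue = hit$catalytic_residue,
      cys_position = if (length(cys) > 0L) cys[1] else NA_integer_,
      ae_id = if (nrow(ae) > 0L) ae$ae_id[1] else NA_character_,
      arrangement = if (nrow(ae) > 0L) ae$arrangement[1] else NA_character_
    )
  })
  out <- list_rbind(rows)
  if (is.null(out) || nrow(out) == 0L) {
    out <- tibble(protein_id = character(0), class = character(0),
                  position = integer(0), catalytic_residue = character(0),
                  cys_position = integer(0), ae_id = character(0),
                  arrangement = character(0))
  }
  structure(out, class = c("aare_screen", class(out)),
            n_proteins = length(ids))
}

#' @export
tidy.aare_screen <- function(x, ...) {
  as_tibble(unclass_screen(x))
}

#' @export
glance.aare_screen <- function(x, ...) {
  tb <- unclass_screen(x)
  counts <- table(factor(tb$class,
                         levels = c("GRE", "ARE", "SRE", "TRE", "fingerprint_only")))
  tibble(
    n_proteins = attr(x, "n_proteins"),
    n_hits = nrow(tb),
    n_gre = as.integer(counts[["GRE"]]),
    n_are = as.integer(counts[["ARE"]]),
    n_sre = as.integer(counts[["SRE"]]),
    n_tre = as.integer(counts[["TRE"]]),
    n_fingerprint_only = as.integer(counts[["fingerprint_only"]])
  )
}

unclass_screen <- function(x) {
  class(x) <- setdiff(class(x), "aare_screen")
  x
}

#' Precision and recall of a screen against a truth table
#'
#' Per-class precision and recall of the classified screen result against a
#' generator truth table (see [generate_family()]), treating
#' `fingerprint_only` as the negative class.
#'
#' @param screen An `aare_screen` result.
#' @param truth Tibble with columns `id` and `expected_class`.
#' @return Tibble with columns `class`, `n_true`, `n_called`, `tp`,
#'   `precision`, `recall`.
#' @export
screen_performance <- function(screen, truth) {
  tb <- unclass_screen(screen)
  joined <- left_join(truth, select(tb, protein_id, called = "class"),
                      by = c(id = "protein_id"))
  joined$called[is.na(joined$called)] <- "none"
  classes <- sort(unique(c(joined$expected_class, joined$called)))
  classes <- setdiff(classes, "none")
  if (length(classes) == 0L) {
    return(tibble(class = character(0), n_true = integer(0),
                  n_called = integer(0), tp = integer(0),
                  precision = numeric(0), recall = numeric(0)))
  }
  list_rbind(map(classes, function(cl) {
    n_true <- sum(joined$expected_class == cl)
    n_called <- sum(joined$called == cl)
    tp <- sum(joined$expected_class == cl & joined$called == cl)
    tibble(class = cl, n_true = n_true, n_called = n_called, tp = tp,
           precision = ifelse(n_called > 0, tp / n_called, NA_real_),
           recall = ifelse(n_true > 0, tp / n_true, NA_real_))
  }))
}

#' @export
print.aare_screen <- function(x, ...) {
  g <- glance.aare_screen(x)
  cat(sprintf("<aare_screen> %d fingerprint-bearing proteins of %d screened\n",
              g$n_hits, g$n_proteins))
  cat(sprintf("  GRE %d | ARE %d | SRE %d | TRE %d | fingerprint_only %d\n",
              g$n_gre, g$n_are, g$n_sre, g$n_tre, g$n_fingerprint_only))
  print(tidy.aare_screen(x), ...)
  invisible(x)
}
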