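test_that("scan_fingerprint finds the catalytic-loop motif and classifies it", {
  hits <- scan_fingerprint("MARVCGFQ")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$position, 6L)
  expect_equal(hits$catalytic_residue, "G")
  expect_equal(hits$class_label, "GRE")
  expect_equal(hits$window, "RVCGF")

  expect_equal(scan_fingerprint("MARVCTFQ")$class_label, "TRE")
  expect_equal(nrow(scan_fingerprint("MARVCPFQ")), 0)
  expect_error(scan_fingerprint(""), "non-empty")
})

test_that("fingerprint positions are stable under case folding", {
  s <- "mkllarvagwaa"
  expect_equal(scan_fingerprint(s), scan_fingerprint(toupper(s)))
})

test_that("custom anchors loosen the pattern", {
  cfg <- fingerprint_config(anchors = list(`0` = c("R", "K"), `1` = "V",
                                           `4` = c("F", "W", "Y")))
  expect_equal(nrow(scan_fingerprint("MAKVCGFQ", cfg)), 1)
  expect_equal(nrow(scan_fingerprint("MAKVCGFQ")), 0)
})

test_that("check_catalytic_cys applies the relative-position window", {
  s <- paste(c(rep("A", 49), "C", rep("A", 50)), collapse = "")
  expect_equal(check_catalytic_cys(s), 50L)
  expect_equal(check_catalytic_cys(paste(rep("A", 100), collapse = "")), integer(0))
  s2 <- paste(c(rep("A", 4), "C", rep("A", 95)), collapse = "")
  expect_equal(check_catalytic_cys(s2), integer(0))  # 0.05 outside [0.35, 0.70)
  expect_error(check_catalytic_cys("AAC", window = c(0.7, 0.3)))
})

test_that("scan_rsam_motif finds CX3CX2C starts, overlaps included", {
  expect_equal(scan_rsam_motif("MCTTTCAAC"), 2L)
  # exhaustive-scan oracle: the 8-wide motif fits a 10-residue poly-C at 1..3
  expect_equal(scan_rsam_motif("CCCCCCCCCC"), c(1L, 2L, 3L))
  expect_equal(scan_rsam_motif("MCTTTCAAA"), integer(0))
  expect_equal(scan_rsam_motif("SHORT"), integer(0))
})

test_that("classify_candidate demands full evidence for a class call", {
  expect_equal(classify_candidate("TRE", TRUE, TRUE), "TRE")
  expect_equal(classify_candidate("ARE", TRUE, FALSE), "fingerprint_only")
  expect_equal(classify_candidate("GRE", FALSE, TRUE), "fingerprint_only")
  expect_equal(classify_candidate(c("GRE", "SRE"), c(TRUE, TRUE), c(TRUE, TRUE)),
               c("GRE", "SRE"))
})

test_that("pairwise_identity matches hand alignments and is symmetric", {
  expect_equal(pairwise_identity("MKVL", "MKVL"), 100)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0)
  expect_equal(pairwise_identity("AAAA", "AATT"), 50)
  set.seed(2)
  for (k in 1:5) {
    a <- paste(sample(c("A", "G", "K", "L", "M"), 30, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "G", "K", "L", "M"), 25, replace = TRUE), collapse = "")
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
    expect_lt(pairwise_identity(a, b), 100)
  }
})

test_that("find_ae_partners applies the gap rule and arrangements", {
  cand <- paste(c(rep("A", 40), "C", rep("A", 40), "RVAGF"), collapse = "")
  ae <- paste(c("M", "C", "A", "A", "A", "C", "A", "A", "C", rep("A", 20)), collapse = "")
  plain <- paste(rep("A", 30), collapse = "")
  proteins <- c(cand = cand, ae = ae, cand2 = cand, far_ae = ae, plain = plain)

  genes <- tibble::tibble(
    contig_id = c("c1", "c1", "c2", "c2"),
    gene_id = c("g1", "g2", "g3", "g4"),
    start = c(1L, 401L, 1L, 20001L),
    end = c(300L, 700L, 300L, 20300L),
    strand = c("+", "-", "+", "+"),
    protein_id = c("cand", "ae", "cand2", "far_ae")
  )
  out <- find_ae_partners(genes, proteins, max_gap_bp = 500)
  expect_equal(nrow(out), 1)
  expect_equal(out$candidate_id, "cand")
  expect_equal(out$ae_id, "ae")
  expect_equal(out$gap_bp, 100L)  # 401 - 300 - 1
  expect_equal(out$arrangement, "one_to_one")

  # two candidates flanking one AE -> atypical arrangement
  genes2 <- tibble::tibble(
    contig_id = "c1", gene_id = c("t1", "a", "t2"),
    start = c(1L, 401L, 801L), end = c(300L, 700L, 1100L),
    strand = "+", protein_id = c("cand", "ae", "cand2")
  )
  out2 <- find_ae_partners(genes2, proteins, max_gap_bp = 500)
  expect_equal(nrow(out2), 2)
  expect_true(all(out2$arrangement == "two_candidates_one_ae"))

  expect_error(find_ae_partners(genes2, proteins[-2], 500), "unresolvable.*ae")
})

test_that("co-orientation flag restricts partners to the same strand", {
  cand <- paste(c(rep("A", 40), "C", rep("A", 40), "RVAGF"), collapse = "")
  ae <- paste(c("M", "C", "A", "A", "A", "C", "A", "A", "C", rep("A", 20)), collapse = "")
  proteins <- c(cand = cand, ae = ae)
  genes <- tibble::tibble(contig_id = "c1", gene_id = c("g1", "g2"),
                          start = c(1L, 401L), end = c(300L, 700L),
                          strand = c("+", "-"), protein_id = c("cand", "ae"))
  expect_equal(nrow(find_ae_partners(genes, proteins)), 1)
  expect_equal(nrow(find_ae_partners(genes, proteins, require_coorientation = TRUE)), 0)
})

test_that("screen_proteins ties the evidence together", {
  # candidate with Cys + motif + AE on one contig
  cand <- paste(c(rep("A", 40), "C", rep("A", 40), "RVAGF"), collapse = "")
  nocys <- paste(c(rep("A", 81), "RVATW"), collapse = "")
  ae <- paste(c("M", "C", "A", "A", "A", "C", "A", "A", "C", rep("A", 20)), collapse = "")
  proteins <- c(p1 = cand, p2 = nocys, ae1 = ae)
  genes <- tibble::tibble(
    contig_id = c("c1", "c1", "c2"),
    gene_id = c("g1", "g2", "g3"),
    start = c(1L, 401L, 1L), end = c(300L, 700L, 300L),
    strand = "+", protein_id = c("p1", "ae1", "p2")
  )
  scr <- screen_proteins(proteins, genes)
  tb <- tidy(scr)
  expect_equal(tb$class[tb$protein_id == "p1"], "GRE")
  expect_equal(tb$class[tb$protein_id == "p2"], "fingerprint_only")
  g <- glance(scr)
  expect_equal(g$n_gre, 1)
  expect_equal(g$n_fingerprint_only, 1)
})
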