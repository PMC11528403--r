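test_that("generate_family is seed-deterministic and honours class counts", {
  f1 <- generate_family(small_family_spec(seed = 3))
  f2 <- generate_family(small_family_spec(seed = 3))
  expect_identical(f1$proteins, f2$proteins)
  expect_identical(f1$cds, f2$cds)
  expect_identical(f1$truth, f2$truth)
  f3 <- generate_family(small_family_spec(seed = 4))
  expect_false(identical(f1$proteins, f3$proteins))

  counts <- table(f1$truth$class)
  expect_equal(as.integer(counts[c("GRE", "ARE", "SRE", "TRE")]), c(2, 2, 2, 4))
  expect_equal(as.integer(counts["decoy_nocys"]), 2)
  expect_equal(as.integer(counts["decoy_noae"]), 2)
})

test_that("every emitted CDS back-translates to its protein", {
  fam <- generate_family(small_family_spec())
  code <- genetic_code()
  for (id in names(fam$cds)) {
    cds <- fam$cds[[id]]
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    expect_identical(paste(code$aa[match(codons, code$codon)], collapse = ""),
                     unname(fam$proteins[[id]]), label = id)
  }
})

test_that("planted catalytic codons follow minimal mutational paths from Gly", {
  fam <- generate_family(small_family_spec())
  for (k in seq_len(nrow(fam$truth))) {
    row <- fam$truth[k, ]
    if (!row$class %in% c("GRE", "ARE", "SRE", "TRE")) next
    cds <- fam$cds[[row$id]]
    cat_codon <- substring(cds, 3 * (row$catalytic_position - 1) + 1,
                           3 * row$catalytic_position)
    expected_steps <- c(GRE = 0L, ARE = 1L, SRE = 1L, TRE = 2L)[[row$class]]
    expect_equal(codon_hamming(cat_codon, "GGT"), expected_steps, label = row$id)
  }
})

test_that("vanishing mutation rate leaves descendants at the ancestor", {
  sp <- family_spec(n_per_class = c(ARE = 3), n_decoy_nocys = 0, n_decoy_noae = 0,
                    n_outgroup = 0, protein_length = 100,
                    mutation_rate_per_site = 1e-9, seed = 8)
  fam <- generate_family(sp)
  expect_equal(length(unique(unname(fam$proteins))), 1)  # identical up to the planted residue
  p <- strsplit(fam$proteins[[1]], "")[[1]]
  expect_equal(p[fam$truth$catalytic_position[1]], "A")
})

test_that("neighborhoods obey the arrangement rules", {
  fam <- generate_family(small_family_spec())
  nb <- generate_neighborhoods(fam, seed = 2)
  arr <- nb$arrangements
  # 4 TREs -> 2 AE-sharing pairs
  tre <- arr[grepl("^TRE", arr$id), ]
  expect_true(all(tre$arrangement == "two_candidates_one_ae"))
  expect_equal(length(unique(tre$ae_id)), 2)
  # singles one-to-one; noae decoys get nothing
  expect_true(all(arr$arrangement[grepl("^ARE|^SRE|^GRE", arr$id)] == "one_to_one"))
  expect_true(all(is.na(arr$ae_id[grepl("^decoy_noae", arr$id)])))
  # every AE protein carries the rSAM motif
  for (ae in names(nb$ae_proteins)) {
    expect_gt(length(scan_rsam_motif(nb$ae_proteins[[ae]])), 0)
  }
  # deterministic given the seed
  nb2 <- generate_neighborhoods(fam, seed = 2)
  expect_identical(nb$genes, nb2$genes)
  expect_identical(nb$ae_proteins, nb2$ae_proteins)
})

test_that("an odd TRE count falls back to one_to_one with a warning", {
  sp <- family_spec(n_per_class = c(TRE = 3), n_decoy_nocys = 0, n_decoy_noae = 0,
                    n_outgroup = 0, protein_length = 100,
                    mutation_rate_per_site = 0.05, seed = 1)
  fam <- generate_family(sp)
  expect_warning(nb <- generate_neighborhoods(fam), "odd TRE")
  expect_equal(sum(nb$arrangements$arrangement == "one_to_one"), 1)
  expect_equal(sum(nb$arrangements$arrangement == "two_candidates_one_ae"), 2)
})

test_that("miner round-trips the truth table on a small planted database", {
  fam <- generate_family(small_family_spec())
  nb <- generate_neighborhoods(fam, seed = 5)
  scr <- screen_proteins(family_protein_db(fam, nb), genes = nb$genes)
  perf <- screen_performance(scr, fam$truth)
  expect_true(all(perf$precision == 1))
  expect_true(all(perf$recall == 1))
  # decoys all land in fingerprint_only
  tb <- tidy(scr)
  decoys <- tb[grepl("^decoy", tb$protein_id), ]
  expect_true(all(decoys$class == "fingerprint_only"))
})

test_that("generate_spectrum is seeded and respects the zero-fraction limit", {
  sys <- radical_spin_system("glycyl")
  g1 <- generate_spectrum(sys, 0.2, snr = 50, cfg = fast_cfg(), seed = 6)
  g2 <- generate_spectrum(sys, 0.2, snr = 50, cfg = fast_cfg(), seed = 6)
  expect_identical(g1$sample$intensity, g2$sample$intensity)
  g0 <- generate_spectrum(sys, 0, snr = 50, cfg = fast_cfg(), seed = 6)
  expect_lt(abs(spin_fraction(g0$sample, g0$standard)), 0.02)
})

test_that("spin_fraction recovers a planted fraction from a noisy spectrum", {
  gen <- generate_spectrum(radical_spin_system("serinyl"), planted_fraction = 0.28,
                           snr = 50, cfg = fast_cfg(n_points = 1024), seed = 12)
  est <- spin_fraction(gen$sample, gen$standard)
  expect_equal(est, 0.28, tolerance = 0.02 / 0.28)
})
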