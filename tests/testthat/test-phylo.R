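test_that("p_distance counts differing sites over comparable sites", {
  aln <- c(a = "AAAA", b = "AATT", c = "AAAA")
  D <- p_distance(aln)
  expect_equal(D["a", "b"], 0.5)
  expect_equal(D["a", "c"], 0)
  expect_equal(D, t(D))
  # gap masking: only ungapped columns compare
  Dg <- p_distance(c(x = "AA--", y = "AATT"))
  expect_equal(Dg["x", "y"], 0)
  expect_error(p_distance(c(x = "--AA", y = "TT--")), "no comparable sites")
  expect_error(p_distance(c(x = "AA")), "at least 2")
})

test_that("poisson_correct is the -log(1-p) map", {
  expect_equal(poisson_correct(0), 0)
  expect_equal(poisson_correct(0.5), log(2))
  p <- seq(0, 0.9, by = 0.1)
  expect_true(all(diff(poisson_correct(p)) > 0))
  expect_error(poisson_correct(1), "\\[0, 1\\)")
})

test_that("nj_tree solves the 3-taxon star exactly", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["a"]], 0.5)   # (2 + 3 - 4) / 2
  expect_equal(lens[["b"]], 1.5)
  expect_equal(lens[["c"]], 2.5)
})

test_that("nj_tree recovers the generating topology of additive matrices", {
  # hand-built additive 4-taxon matrix for ((A,B),(C,D))
  d <- matrix(c(0, 3, 7, 8,
                3, 0, 8, 9,
                7, 8, 0, 5,
                8, 9, 5, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  # split keys canonicalise to the side away from the smallest label ("A")
  expect_equal(tree_bipartitions(nj_tree(d)), "C,D")

  # random additive matrices from random topologies, n up to 8
  for (n in 5:8) {
    for (seed in 1:3) {
      ref <- random_additive(n, seed = 100 * n + seed)
      tr <- nj_tree(ref$d[ref$tree$tip.label, ref$tree$tip.label])
      expect_equal(split_set(tr), split_set(ref$tree),
                   label = sprintf("n=%d seed=%d", n, seed))
      # independent cross-check: ape's NJ gives the same splits
      expect_equal(split_set(tr), split_set(ape::nj(ref$d)))
    }
  }
})

test_that("nj_tree validates input and clamps negative branch lengths", {
  bad <- matrix(c(0, 1, 2, 9, 0, 1, 2, 1, 0), 3, 3)
  expect_error(nj_tree(bad), "symmetric")
  # strongly non-additive random matrices induce negative estimates; every
  # returned length must be clamped to >= 0 with a warning
  set.seed(1)
  saw_clamp <- FALSE
  for (k in 1:30) {
    m <- matrix(runif(25, 0.1, 1), 5, 5)
    m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(letters[1:5], letters[1:5])
    w <- NULL
    tr <- withCallingHandlers(nj_tree(m), warning = function(cnd) {
      w <<- cnd; invokeRestart("muffleWarning")
    })
    expect_true(all(tr$edge.length >= 0))
    if (!is.null(w)) {
      saw_clamp <- TRUE
      expect_match(conditionMessage(w), "clamped")
      expect_gt(attr(tr, "clamped_deficit"), 0)
    }
  }
  expect_true(saw_clamp)
})

test_that("bootstrap support is deterministic and bounded by replicate count", {
  set.seed(42)
  cols <- replicate(40, sample(c("A", "C", "D", "E"), 1))
  aln <- c(s1 = paste(cols, collapse = ""),
           s2 = paste(cols, collapse = ""),
           s3 = paste(rev(cols), collapse = ""),
           s4 = paste(sample(c("A", "C", "D", "E"), 40, replace = TRUE), collapse = ""),
           s5 = paste(sample(c("A", "C", "D", "E"), 40, replace = TRUE), collapse = ""))
  aln <- vapply(seq_along(aln), function(i) {
    s <- strsplit(aln[[i]], "")[[1]]
    if (i > 1) s[sample(40, 5)] <- "G"
    paste(s, collapse = "")
  }, "", USE.NAMES = FALSE)
  names(aln) <- paste0("s", 1:5)
  b1 <- bootstrap_support(aln, n_reps = 25, seed = 9)
  b2 <- bootstrap_support(aln, n_reps = 25, seed = 9)
  expect_identical(b1$support, b2$support)
  b3 <- bootstrap_support(aln, n_reps = 1, seed = 9)
  expect_true(all(b3$support$support %in% c(0, 1)))
  expect_true(all(b1$support$support >= 0 & b1$support$support <= 1))
})

test_that("clade structure in a planted family is recovered with high support", {
  fam <- generate_family(small_family_spec())
  ids <- fam$truth$id[fam$truth$class %in% c("GRE", "ARE", "SRE", "TRE", "outgroup")]
  boot <- bootstrap_support(fam$proteins[ids], n_reps = 50, seed = 4)
  out <- fam$truth$id[fam$truth$class == "outgroup"][1]
  for (cl in c("ARE", "SRE", "TRE")) {
    members <- fam$truth$id[fam$truth$class == cl]
    expect_true(is_monophyletic(boot$tree, members, out), label = cl)
    expect_gte(clade_support(boot, members, out), 0.9)
  }
})

test_that("is_monophyletic roots on the outgroup and tests exact clades", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(is_monophyletic(tr, c("A", "B"), outgroup = "D"))
  expect_false(is_monophyletic(tr, c("A", "C"), outgroup = "D"))
  expect_true(is_monophyletic(tr, "A", outgroup = "D"))
  expect_error(is_monophyletic(tr, c("A", "Z"), outgroup = "D"), "unknown")
})
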