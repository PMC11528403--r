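# Shared fixtures and independent oracles, built in code at test time.

# small family for fast unit tests
small_family_spec <- function(seed = 11) {
  family_spec(n_per_class = c(GRE = 2, ARE = 2, SRE = 2, TRE = 4),
              n_decoy_nocys = 2, n_decoy_noae = 2, n_outgroup = 1,
              protein_length = 120, mutation_rate_per_site = 0.1, seed = seed)
}

fast_cfg <- function(n_orientations = 500, n_points = 512, ...) {
  sim_config(n_orientations = n_orientations, n_points = n_points, ...)
}

# brute-force oracle: minimum Hamming distance between codon sets, computed
# independently of the package's codon-graph code
oracle_min_codon_distance <- function(aa1, aa2, code = genetic_code()) {
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  c1 <- code$codon[code$aa == aa1]
  c2 <- code$codon[code$aa == aa2]
  min(vapply(c1, function(a) min(vapply(c2, function(b) ham(a, b), 0)), 0))
}

# explicit 2^n spin-state enumeration for n equivalent protons; returns the
# merged (offset, weight) table independent of stick_pattern()
oracle_sticks <- function(couplings) {
  ms <- list(numeric(0))
  spins <- unlist(lapply(couplings, function(cp) rep(cp$a_iso, cp$n)))
  grid <- expand.grid(rep(list(c(-0.5, 0.5)), length(spins)))
  offsets <- as.matrix(grid) %*% spins
  tab <- table(round(offsets, 9))
  data.frame(offset = as.numeric(names(tab)), weight = as.vector(tab) / min(tab))
}

# random additive distance matrix from a random topology (ape is the
# independent tree machinery here)
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.5, 2))
  tr$tip.label <- paste0("t", seq_len(n))
  list(tree = tr, d = cophenetic(tr))
}

split_set <- function(tree) sort(tree_bipartitions(tree))
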