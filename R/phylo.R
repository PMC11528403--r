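# Distance-based phylogenetics: Poisson-corrected p-distances, an in-package
# neighbor-joining implementation with deterministic tie-breaking, column
# bootstrap with bipartition support, and outgroup-rooted monophyly tests.
# NJ + bootstrap stands in for maximum-likelihood inference at desk scale.

#' Alignment from a named character vector
#'
#' Validates an aligned set of sequences (equal lengths, unique ids, gap
#' character `-`) and returns the internal character-matrix form.
#'
#' @param seqs Named character vector of aligned sequences.
#' @return Character matrix (taxa x sites) with rownames set to ids.
#' @export
as_alignment <- function(seqs) {
  if (is.matrix(seqs)) return(seqs)
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids)) abort("sequences must have unique names")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) abort("aligned sequences must all have equal length")
  m <- matrix(unlist(strsplit(toupper(seqs), "")), nrow = length(seqs),
              byrow = TRUE, dimnames = list(ids, NULL))
  m
}

#' Pairwise p-distances from an alignment
#'
#' Proportion of differing sites over sites where neither sequence is gapped.
#' A pair with zero comparable sites is an error.
#'
#' @param aln Named character vector of aligned sequences, or the matrix from
#'   [as_alignment()].
#' @return Symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
p_distance <- function(aln) {
  m <- as_alignment(aln)
  n <- nrow(m)
  if (n < 2L) abort("need at least 2 sequences")
  notgap <- m != "-"
  # crossprod over per-letter indicators: matches[i,j] = #sites equal (non-gap)
  letters_used <- setdiff(unique(as.vector(m)), "-")
  NG <- tcrossprod(notgap * 1)           # comparable sites per pair
  MM <- matrix(0, n, n)
  for (a in letters_used) {
    Xa <- (m == a) * 1
    MM <- MM + tcrossprod(Xa)
  }
  if (any(NG[upper.tri(NG)] == 0)) {
    bad <- which(NG == 0 & upper.tri(NG), arr.ind = TRUE)[1, ]
    abort(paste0("no comparable sites between `", rownames(m)[bad[1]],
                 "` and `", rownames(m)[bad[2]], "`"))
  }
  D <- (NG - MM) / NG
  diag(D) <- 0
  dimnames(D) <- list(rownames(m), rownames(m))
  D
}

#' Poisson correction of a p-distance
#'
#' `-log(1 - p)`, the Poisson multiple-hit correction. Saturated distances
#' (`p >= 1`) are an error.
#'
#' @param p Proportion(s) of differing sites in `[0, 1)`.
#' @return Corrected distance(s).
#' @export
poisson_correct <- function(p) {
  if (any(p < 0 | p >= 1)) abort("`p` must lie in [0, 1)")
  -log(1 - p)
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining with deterministic behaviour: ties in
#' the Q-criterion are broken by the lowest index pair, and negative branch
#' lengths are clamped to zero (the clamped deficit is attached as the
#' `clamped_deficit` attribute and raised as a warning).
#'
#' @param d Symmetric distance matrix with dimnames (ids), >= 3 taxa.
#' @return An [ape::phylo] unrooted tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) abort("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) abort("distance matrix must be symmetric")
  ids <- rownames(d)
  n_tip <- nrow(d)

  # node bookkeeping: tips 1..n_tip, internal nodes appended
  active <- seq_len(n_tip)          # node ids of active clusters
  D <- d
  edges <- matrix(integer(0), ncol = 2)
  lens <- numeric(0)
  next_node <- n_tip + 1L
  clamped <- 0

  add_edge <- function(parent, child, len) {
    if (len < 0) { clamped <<- clamped - len; len <- 0 }
    edges <<- rbind(edges, c(parent, child))
    lens <<- c(lens, len)
  }

  while (length(active) > 2L) {
    r <- length(active)
    rs <- rowSums(D)
    Q <- (r - 2) * D - outer(rs, rs, `+`)
    diag(Q) <- Inf
    # lowest-index pair among ties (column-major order of which())
    ij <- which(Q == min(Q), arr.ind = TRUE)
    ij <- ij[order(pmin(ij[, 1], ij[, 2]), pmax(ij[, 1], ij[, 2])), , drop = FALSE]
    i <- min(ij[1, ]); j <- max(ij[1, ])
    li <- 0.5 * D[i, j] + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    u <- next_node; next_node <- next_node + 1L
    add_edge(u, active[i], li)
    add_edge(u, active[j], lj)
    du <- 0.5 * (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du), c(du, 0))
    active <- c(active[keep], u)
  }
  # join the last two clusters with a single edge
  add_edge(active[2], active[1], D[1, 2])

  n_node <- next_node - 1L - n_tip
  # ape wants internal nodes numbered n_tip+1.. with the root first; renumber
  # so the last-created node (the tree's open end) is the root
  internal_old <- seq(n_tip + 1L, by = 1L, length.out = n_node)
  internal_new <- setNames(rev(internal_old), internal_old)
  remap <- function(v) ifelse(v > n_tip, internal_new[as.character(v)], v)
  edges_m <- cbind(remap(edges[, 1]), remap(edges[, 2]))
  # orient edges away from the root
  tr <- list(edge = edges_m, edge.length = lens, tip.label = ids,
             Nnode = n_node)
  class(tr) <- "phylo"
  tr <- ape::read.tree(text = ape::write.tree(reorient_phylo(tr, n_tip + 1L)))
  attr(tr, "clamped_deficit") <- clamped
  if (clamped > 0) warn(sprintf("negative NJ branch lengths clamped (total deficit %.4g)", clamped))
  tr
}

# orient an undirected edge list away from `root` (parent in column 1)
reorient_phylo <- function(tr, root) {
  edge <- tr$edge; lens <- tr$edge.length
  n_edge <- nrow(edge)
  adj <- vector("list", max(edge))
  for (k in seq_len(n_edge)) {
    a <- edge[k, 1]; b <- edge[k, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, k))
    adj[[b]] <- rbind(adj[[b]], c(a, k))
  }
  new_edge <- matrix(0L, n_edge, 2)
  new_len <- numeric(n_edge)
  seen <- logical(n_edge)
  stack <- root
  visited <- logical(max(edge))
  visited[root] <- TRUE
  m <- 0L
  while (length(stack) > 0L) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    nb <- adj[[v]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      k <- nb[r, 2]
      if (seen[k]) next
      seen[k] <- TRUE
      w <- nb[r, 1]
      m <- m + 1L
      new_edge[m, ] <- c(v, w)
      new_len[m] <- lens[k]
      if (!visited[w]) { visited[w] <- TRUE; stack <- c(stack, w) }
    }
  }
  tr$edge <- new_edge
  tr$edge.length <- new_len
  tr
}

#' Unrooted bipartitions of a tree
#'
#' Each internal edge splits the leaves in two; splits are canonicalised as
#' the side not containing the first tip label and serialised as a sorted,
#' comma-joined label string. Trivial (single-leaf) splits are dropped.
#'
#' @param tree An [ape::phylo].
#' @return Character vector of canonical split keys.
#' @export
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  n_tip <- length(tips)
  anchor <- min(tips)
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    side <- tips[p]
    other <- setdiff(tips, side)
    canon <- if (anchor %in% side) other else side
    if (length(canon) >= 2L && length(canon) <= n_tip - 2L) {
      keys <- c(keys, paste(sort(canon), collapse = ","))
    }
  }
  unique(keys)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the NJ tree from (optionally Poisson-corrected) p-distances, then
#' resamples alignment columns with replacement `n_reps` times, rebuilds the
#' tree per replicate, and scores each internal bipartition of the original
#' tree by the fraction of replicates containing it. Fully reproducible from
#' the seed.
#'
#' @param aln Named character vector of aligned sequences (or matrix).
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer RNG seed.
#' @param correction `"poisson"` (default) or `"p"` for raw p-distances.
#' @return An object of class `nj_boot`: list with elements `tree`
#'   ([ape::phylo] with `node.label` support values in `[0,1]`), `support`
#'   (tibble `split`, `support`), `n_reps`, `seed`.
#' @export
bootstrap_support <- function(aln, n_reps = 100, seed = 1,
                              correction = c("poisson", "p")) {
  correction <- match.arg(correction)
  if (n_reps < 1) abort("`n_reps` must be >= 1")
  m <- as_alignment(aln)
  dist_fun <- function(mat) {
    D <- p_distance(mat)
    if (correction == "poisson") D <- poisson_correct(pmin(D, 0.9999)) else D
  }
  tree <- suppressWarnings(nj_tree(dist_fun(m)))
  splits <- tree_bipartitions(tree)
  hits <- setNames(numeric(length(splits)), splits)

  rng <- local({ set.seed(seed); function(n) sample.int(ncol(m), n, replace = TRUE) })
  for (rep in seq_len(n_reps)) {
    cols <- rng(ncol(m))
    bt <- suppressWarnings(nj_tree(dist_fun(m[, cols, drop = FALSE])))
    bs <- tree_bipartitions(bt)
    found <- splits %in% bs
    hits[found] <- hits[found] + 1
  }
  support <- tibble(split = splits, support = unname(hits) / n_reps)
  tree_sup <- annotate_supports(tree, support)
  structure(list(tree = tree_sup, support = support,
                 n_reps = n_reps, seed = seed),
            class = "nj_boot")
}

annotate_supports <- function(tree, support) {
  tips <- tree$tip.label
  n_tip <- length(tips)
  labs <- rep("", tree$Nnode)
  anchor <- min(tips)
  parts <- ape::prop.part(tree)
  for (node in seq(n_tip + 1L, n_tip + tree$Nnode)) {
    clade <- tips[unlist(parts[[node - n_tip]])]
    other <- setdiff(tips, clade)
    canon <- if (anchor %in% clade) other else clade
    key <- paste(sort(canon), collapse = ",")
    k <- match(key, support$split)
    if (!is.na(k)) labs[node - n_tip] <- format(support$support[k], digits = 3)
  }
  tree$node.label <- labs
  tree
}

#' @export
tidy.nj_boot <- function(x, ...) x$support

#' @export
glance.nj_boot <- function(x, ...) {
  tibble(n_tips = length(x$tree$tip.label),
         n_splits = nrow(x$support),
         mean_support = mean(x$support$support),
         min_support = min(x$support$support),
         n_reps = x$n_reps)
}

#' @export
print.nj_boot <- function(x, ...) {
  g <- glance.nj_boot(x)
  cat(sprintf("<nj_boot> NJ tree, %d tips, %d internal splits, %d bootstrap replicates\n",
              g$n_tips, g$n_splits, x$n_reps))
  cat(sprintf("  mean support %.3f, min %.3f\n", g$mean_support, g$min_support))
  invisible(x)
}

#' Test whether a label set is monophyletic under outgroup rooting
#'
#' Roots the tree on the outgroup leaf and asks whether `labels` form exactly
#' one clade. Singletons are trivially monophyletic.
#'
#' @param tree An [ape::phylo] (or an `nj_boot` object).
#' @param labels Character vector of tip labels to test.
#' @param outgroup Tip label used to root the tree.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, labels, outgroup) {
  if (inherits(tree, "nj_boot")) tree <- tree$tree
  unknown <- setdiff(c(labels, outgroup), tree$tip.label)
  if (length(unknown) > 0L) {
    abort(paste0("unknown tip label(s): ", paste(unknown, collapse = ", ")))
  }
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ape::is.monophyletic(rooted, labels)
}

#' Mean bootstrap support of the edges defining a clade
#'
#' The support value attached to the smallest clade containing exactly
#' `labels` in the outgroup-rooted tree; `NA` if the set is not monophyletic.
#'
#' @inheritParams is_monophyletic
#' @param boot An `nj_boot` object.
#' @return Numeric support in `[0, 1]`, or `NA`.
#' @export
clade_support <- function(boot, labels, outgroup) {
  stopifnot(inherits(boot, "nj_boot"))
  if (!is_monophyletic(boot$tree, labels, outgroup)) return(NA_real_)
  if (length(labels) < 2L) return(1)
  tips <- boot$tree$tip.label
  other <- setdiff(tips, labels)
  canon <- if (min(tips) %in% labels) sort(other) else sort(labels)
  key <- paste(canon, collapse = ",")
  k <- match(key, boot$support$split)
  if (is.na(k)) NA_real_ else boot$support$support[k]
}
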