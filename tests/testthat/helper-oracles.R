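# Independent oracles used across the suite.  They deliberately share no
# code with the package: plain recursive enumeration of alignment paths,
# and graph-surgery bipartition enumeration for clans.

defaultScheme <- scoringScheme()

# exhaustive global (Needleman-Wunsch) score by unmemoized recursion over
# all alignment paths with affine gap state; gap of length L costs
# open + L * ext
bruteGlobalScore <- function(a, b, S, open, ext) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  rec <- function(i, j, state) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      v <- rec(i - 1L, j - 1L, "M") + S[av[i], bv[j]]
      if (v > best) best <- v
    }
    if (i > 0L) {
      v <- rec(i - 1L, j, "U") - ext - if (state == "U") 0 else open
      if (v > best) best <- v
    }
    if (j > 0L) {
      v <- rec(i, j - 1L, "L") - ext - if (state == "L") 0 else open
      if (v > best) best <- v
    }
    best
  }
  rec(length(av), length(bv), "M")
}

# exhaustive local (Smith-Waterman) score: best alignment ending at any
# cell with a free start anywhere; floor at 0 (empty alignment)
bruteLocalScore <- function(a, b, S, open, ext) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  rec <- function(i, j, state) {
    # best score of an alignment ending with a_i ~ b_j (state M) or a
    # gap, starting anywhere earlier
    best <- -Inf
    if (state == "M") {
      if (i < 1L || j < 1L) return(-Inf)
      sub <- S[av[i], bv[j]]
      best <- sub  # start the alignment here
      for (st in c("M", "U", "L")) {
        v <- rec(i - 1L, j - 1L, st)
        if (is.finite(v) && v + sub > best) best <- v + sub
      }
    } else if (state == "U") {
      if (i < 1L) return(-Inf)
      for (st in c("M", "U")) {
        v <- rec(i - 1L, j, st)
        pen <- ext + if (st == "U") 0 else open
        if (is.finite(v) && v - pen > best) best <- v - pen
      }
    } else {
      if (j < 1L) return(-Inf)
      for (st in c("M", "L")) {
        v <- rec(i, j - 1L, st)
        pen <- ext + if (st == "L") 0 else open
        if (is.finite(v) && v - pen > best) best <- v - pen
      }
    }
    best
  }
  best <- 0
  for (i in seq_along(av))
    for (j in seq_along(bv)) {
      v <- rec(i, j, "M")
      if (v > best) best <- v
    }
  best
}

# all bipartitions of a tree's leaves obtained by deleting each edge in
# an igraph copy of the tree (independent of the package's traversal)
bruteClans <- function(tree) {
  skip_if_not_installed("igraph")
  nt <- ape::Ntip(tree)
  g <- igraph::graph_from_edgelist(tree$edge, directed = FALSE)
  out <- list()
  for (k in seq_len(nrow(tree$edge))) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, tree$edge[k, ]))
    comp <- igraph::components(g2)$membership
    for (side in unique(comp)) {
      leaves <- sort(tree$tip.label[which(comp == side & seq_along(comp) <= nt)])
      if (length(leaves)) out[[length(out) + 1L]] <- leaves
    }
  }
  unique(out)
}

randomSeq <- function(n, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# additive distance matrix from a random tree with positive branch lengths
randomAdditiveMatrix <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
  D <- ape::cophenetic.phylo(tr)
  D <- D[sort(rownames(D)), sort(rownames(D))]
  list(tree = tr, D = D)
}

# quick family fixture: an archetype and diverged copies
makeFamily <- function(n, length = 150, t = 0.1, cys = 6, prefix = "s") {
  arch <- simulateArchetype(length, cys)
  copies <- vapply(seq_len(n), function(i)
    evolveProtein(arch$sequence, t, arch$cysPositions)$sequence, "")
  names(copies) <- paste0(prefix, seq_len(n))
  list(archetype = arch, copies = copies)
}
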