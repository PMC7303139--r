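# Bootstrap support for NJ trees: columns of the multiple alignment are
# resampled with replacement, the distance+NJ tree is rebuilt, and each
# internal edge of the original tree gets the percentage of replicates
# containing the same bipartition.

# aligned AAStringSet / character matrix -> character matrix
.alnMatrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  if (is(msa, "AAStringSet")) {
    w <- Biostrings::width(msa)
    if (length(unique(w)) != 1L) stop("alignment rows differ in width")
    m <- do.call(rbind, strsplit(as.character(msa), ""))
    rownames(m) <- names(msa)
    return(m)
  }
  stop("msa must be an aligned AAStringSet or a character matrix")
}

#' Poisson distances between the rows of a multiple alignment
#'
#' For each pair of rows, p is the mismatch fraction over the columns
#' where both rows hold a residue; the distance is
#' \eqn{-\ln(1 - \min(p, 0.95))}.  Pairs sharing fewer than
#' \code{minShared} columns get the capped maximum distance: a handful
#' of chance matches over a vanishing overlap would otherwise fake a
#' small distance and destabilise the tree.
#'
#' @param msa aligned \code{AAStringSet} or character matrix.
#' @param minShared minimum residue-residue column count for a distance
#'   estimate (default 30).
#' @return a symmetric labelled distance matrix.
#' @export
alignmentDistances <- function(msa, minShared = 30L) {
  m <- .alnMatrix(msa)
  n <- nrow(m)
  labs <- rownames(m)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  gap <- m == "-"
  cap <- -log(1 - 0.95)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- !gap[i, ] & !gap[j, ]
      ns <- sum(shared)
      d <- if (ns < max(1L, minShared)) cap
           else -log(1 - min(sum(m[i, shared] != m[j, shared]) / ns, 0.95))
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

# canonical key of the bipartition induced by a leaf set: the side not
# containing the alphabetically first leaf
.splitKey <- function(side, tips) {
  ref <- min(tips)
  s <- if (ref %in% side) sort(setdiff(tips, side)) else sort(side)
  paste(s, collapse = "\r")
}

# keys of all internal (non-pendant, non-trivial) splits of a tree
.internalSplits <- function(tree) {
  cl <- treeClans(tree)
  cl <- cl[cl$side == "child", , drop = FALSE]
  nt <- ape::Ntip(tree)
  keep <- cl$size >= 2L & cl$size <= nt - 2L
  cl <- cl[keep, , drop = FALSE]
  data.frame(edge = cl$edge,
             key = vapply(cl$leaves, .splitKey, "", tips = tree$tip.label),
             stringsAsFactors = FALSE)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the NJ tree from the alignment-based Poisson distances, then
#' resamples alignment columns with replacement \code{nReps} times,
#' rebuilds the tree and records, for every internal edge of the
#' original tree, the percentage of replicates whose tree contains the
#' same bipartition.  Supports are attached as internal node labels
#' (label of the child node of each edge), the convention
#' [readNewickUnrooted()] and [smallestClan()] use.
#'
#' @param msa aligned \code{AAStringSet} or character matrix with at
#'   least 4 rows.
#' @param nReps number of bootstrap replicates (>= 1); 1,000 for
#'   publication-grade supports, fewer for quick checks.
#' @param seed integer seed; the resampling is fully reproducible.
#' @param minShared saturation guard passed to [alignmentDistances()].
#' @return the unrooted NJ \code{phylo} with \code{node.label} carrying
#'   the supports (percent).
#' @export
bootstrapSupport <- function(msa, nReps = 1000L, seed = 1L,
                             minShared = 30L) {
  if (nReps < 1L) stop("nReps must be at least 1")
  m <- .alnMatrix(msa)
  if (nrow(m) < 4L) stop("need at least 4 aligned sequences")
  tree <- njTree(alignmentDistances(m, minShared = minShared))
  splits <- .internalSplits(tree)
  counts <- stats::setNames(rep(0L, nrow(splits)), splits$key)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  L <- ncol(m)
  for (r in seq_len(nReps)) {
    cols <- sample.int(L, L, replace = TRUE)
    bt <- njTree(alignmentDistances(m[, cols, drop = FALSE],
                                    minShared = minShared))
    bk <- unique(.internalSplits(bt)$key)
    hit <- bk[bk %in% names(counts)]
    counts[hit] <- counts[hit] + 1L
  }

  support <- 100 * counts / nReps
  nt <- ape::Ntip(tree)
  labels <- rep("", tree$Nnode)
  for (i in seq_len(nrow(splits))) {
    ch <- tree$edge[splits$edge[i], 2L]
    labels[ch - nt] <- format(support[[splits$key[i]]], trim = TRUE)
  }
  tree$node.label <- labels
  tree
}
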