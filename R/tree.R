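# Distance computation and neighbor joining.  The bundled tree builder
# is distance + NJ (externally computed maximum-likelihood trees can be
# imported with readNewickUnrooted()); the analysis the package cares
# about is the clan test on the resulting unrooted topologies.

#' Poisson-corrected distance between two proteins
#'
#' Aligns the pair (semi-global, terminal gaps trimmed), takes the
#' fraction p of differing shared columns and returns
#' \eqn{d = -\ln(1 - p)}, with p capped at 0.95 so the distance stays
#' finite (cap \eqn{-\ln 0.05 \approx 3.0}).
#'
#' @param a,b single sequences.
#' @param scheme a [ScoringScheme-class].
#' @param minShared pairs sharing fewer residue-residue columns than
#'   this are assigned the capped maximum distance: a vanishing overlap
#'   carries no usable signal and a chance match over a handful of
#'   columns would otherwise fake a small distance.
#' @return a non-negative distance; 0 iff the shared columns are
#'   identical.
#' @export
poissonDistance <- function(a, b, scheme, minShared = 1L) {
  aln <- trimTerminalGaps(globalAlign(a, b, scheme))
  ca <- strsplit(aln@rowA, "")[[1L]]
  cb <- strsplit(aln@rowB, "")[[1L]]
  shared <- ca != "-" & cb != "-"
  if (!any(shared)) stop("no shared columns between sequences")
  if (sum(shared) < minShared) return(-log(1 - 0.95))
  p <- sum(ca[shared] != cb[shared]) / sum(shared)
  -log(1 - min(p, 0.95))
}

#' Pairwise Poisson distance matrix
#'
#' @param seqs a named \code{AAStringSet} or named character vector of at
#'   least 2 sequences.
#' @param scheme a [ScoringScheme-class].
#' @param minShared saturation guard passed to [poissonDistance()];
#'   the default (30 columns) caps pairs whose alignments barely
#'   overlap.
#' @return a symmetric distance matrix with zero diagonal, labelled by
#'   sequence name.
#' @export
proteinDistances <- function(seqs, scheme, minShared = 30L) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences")
  labs <- names(seqs)
  if (is.null(labs) || anyDuplicated(labs))
    stop("sequences must carry unique names")
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  sq <- as.character(seqs)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- poissonDistance(sq[i], sq[j], scheme,
                                            minShared = minShared)
  D
}

# Core NJ agglomeration.  Clusters are represented by their
# lexicographically smallest member label; Q-criterion ties are broken
# by the sorted pair of representatives, which makes the result
# invariant under permutations of the input order.  Returns the unrooted
# tree as a newick string plus the merge schedule (used as the guide
# order for progressive MSA).
.njCore <- function(D) {
  labs <- rownames(D)
  frag <- as.list(stats::setNames(labs, labs))  # newick fragment per cluster
  joins <- list()
  d <- D
  eps <- 1e-12

  pickPair <- function(Q, reps) {
    qmin <- min(Q)
    cand <- which(Q <= qmin + eps * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij)
      paste(sort(c(reps[ij[1L]], reps[ij[2L]])), collapse = "\r"))
    cand[order(keys)[1L], ]
  }
  fmt <- function(x) sprintf("%.12g", max(x, 0))

  while (nrow(d) > 3L) {
    n <- nrow(d)
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- pickPair(Q, rownames(d))
    i <- ij[1L]; j <- ij[2L]
    bi <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    ri <- rownames(d)[i]; rj <- rownames(d)[j]
    newFrag <- sprintf("(%s:%s,%s:%s)", frag[[ri]], fmt(bi),
                       frag[[rj]], fmt(bj))
    rep <- min(ri, rj)
    joins[[length(joins) + 1L]] <- c(ri, rj)
    newd <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    rownames(d2) <- colnames(d2) <- c(rownames(d)[keep], rep)
    d <- d2
    frag[[ri]] <- NULL; frag[[rj]] <- NULL
    frag[[rep]] <- newFrag
  }

  reps <- rownames(d)
  if (nrow(d) == 3L) {
    bx <- 0.5 * (d[1, 2] + d[1, 3] - d[2, 3])
    by <- 0.5 * (d[1, 2] + d[2, 3] - d[1, 3])
    bz <- 0.5 * (d[1, 3] + d[2, 3] - d[1, 2])
    nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                   frag[[reps[1L]]], fmt(bx), frag[[reps[2L]]], fmt(by),
                   frag[[reps[3L]]], fmt(bz))
    ord <- order(reps)
    first <- reps[ord[1L]]; second <- reps[ord[2L]]; third <- reps[ord[3L]]
    joins[[length(joins) + 1L]] <- c(first, second)
    joins[[length(joins) + 1L]] <- c(min(first, second), third)
  } else if (nrow(d) == 2L) {
    h <- d[1, 2] / 2
    nwk <- sprintf("(%s:%s,%s:%s);", frag[[reps[1L]]], fmt(h),
                   frag[[reps[2L]]], fmt(h))
    joins[[length(joins) + 1L]] <- c(reps[1L], reps[2L])
  } else stop("need at least 2 clusters")
  list(newick = nwk, joins = joins)
}

.checkDistanceMatrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("distance matrix must be square")
  labs <- rownames(D)
  if (is.null(labs) || !identical(labs, colnames(D)) ||
      anyDuplicated(labs))
    stop("distance matrix needs unique matching row/column labels")
  if (any(!is.finite(D))) stop("distance matrix has non-finite entries")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be 0")
  if (any(grepl("[(),:;\\s]", labs)))
    stop("labels must not contain newick metacharacters or whitespace")
  invisible(labs)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining with the Q criterion.  Ties are
#' broken by the lexicographically smallest pair of cluster labels, so
#' the topology does not depend on the input row order.  Negative branch
#' lengths arising from the NJ formulas are clamped to 0.  Additive
#' distance matrices are reconstructed exactly.
#'
#' @param D symmetric distance matrix with zero diagonal and unique
#'   labels (at least 3).
#' @return an unrooted \pkg{ape} \code{phylo}.
#' @export
njTree <- function(D) {
  labs <- .checkDistanceMatrix(D)
  if (length(labs) < 3L) stop("need at least 3 taxa")
  core <- .njCore(D)
  readNewickUnrooted(text = core$newick)
}
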