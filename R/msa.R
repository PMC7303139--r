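# Progressive multiple sequence alignment: NJ guide order on pairwise
# Poisson distances, profile-profile merges with affine gaps and free
# terminal gaps.  A desk-scale stand-in for an external aligner; the
# downstream clan analysis accepts any aligned input.

# character alignment matrix -> integer codes (0..20, -1 for gap)
.encodeAlnMatrix <- function(mat) {
  out <- matrix(-1L, nrow(mat), ncol(mat))
  idx <- match(mat, .AA21)
  out[] <- ifelse(is.na(idx), -1L, idx - 1L)
  out
}

#' Progressive multiple sequence alignment
#'
#' Computes all pairwise Poisson distances, derives a neighbor-joining
#' guide order and merges sequence profiles in that order with
#' affine-gap profile-profile alignment (average-of-pairs column scores,
#' free terminal gaps).  With two sequences this reduces exactly to
#' [globalAlign()].  The column count never falls below the longest
#' input.
#'
#' @param seqs a named \code{AAStringSet} or named character vector.
#' @param scheme a [ScoringScheme-class].
#' @return an \code{AAStringSet} of equal-width gapped rows, in the
#'   input order.
#' @export
progressiveMSA <- function(seqs, scheme) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  labs <- names(seqs)
  if (is.null(labs) || anyDuplicated(labs))
    stop("sequences must carry unique names")
  if (length(seqs) == 1L) return(seqs)

  sq <- as.character(seqs)
  mats <- lapply(seq_along(sq), function(i) {
    m <- matrix(strsplit(sq[i], "")[[1L]], nrow = 1L)
    rownames(m) <- labs[i]
    m
  })
  names(mats) <- labs

  joins <- if (length(seqs) == 2L) list(c(labs[1L], labs[2L]))
           else .njCore(proteinDistances(seqs, scheme))$joins

  clusters <- mats
  for (jn in joins) {
    A <- clusters[[jn[1L]]]
    B <- clusters[[jn[2L]]]
    res <- .profile_align(.encodeAlnMatrix(A), .encodeAlnMatrix(B),
                          scheme@matrix, scheme@gapOpen, scheme@gapExtend)
    L <- length(res$a_col)
    merged <- matrix("-", nrow(A) + nrow(B), L)
    rownames(merged) <- c(rownames(A), rownames(B))
    aHit <- res$a_col > 0L
    bHit <- res$b_col > 0L
    merged[seq_len(nrow(A)), aHit] <- A[, res$a_col[aHit], drop = FALSE]
    merged[nrow(A) + seq_len(nrow(B)), bHit] <-
      B[, res$b_col[bHit], drop = FALSE]
    rep <- min(jn)
    clusters[[jn[1L]]] <- NULL
    clusters[[jn[2L]]] <- NULL
    clusters[[rep]] <- merged
  }
  final <- clusters[[1L]]
  final <- final[labs, , drop = FALSE]
  out <- Biostrings::AAStringSet(apply(final, 1L, paste, collapse = ""))
  names(out) <- labs
  out
}
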