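# Gene-family copy-number calling under three thresholds (E-value,
# target coverage, percent similarity), cross-family deduplication,
# tandem-array detection on per-scaffold gene order, and exon/intron
# size conservation between copies.

#' Count the copies of one family across the proteome
#'
#' The family's top forward-screen hit is used as the query and aligned
#' against every proteome member; a member counts as a copy when the hit
#' passes all three thresholds: E-value at most \code{cutoff}, aligned
#' span covering at least \code{minCoverage} of the target, and percent
#' similarity at least \code{minSimilarity}.  The query itself always
#' qualifies.  E-values use the summed proteome residue count as the
#' database size.
#'
#' @param queryId id of the family's top hit (must be in the proteome).
#' @param family family label.
#' @param proteome an \code{AAStringSet}.
#' @param scheme a [ScoringScheme-class].
#' @param models optional [GeneModelSet-class] used to derive the
#'   scaffold set; copies without a gene model get scaffold \code{NA}
#'   with a warning.
#' @param cutoff E-value threshold (default \code{1e-5}).
#' @param minCoverage minimum aligned-span coverage of the target
#'   (default 0.5).  With \code{coverageMode = "length_ratio"} the
#'   literal query/target length ratio is used instead.
#' @param minSimilarity minimum percent similarity over aligned columns
#'   (default 70).  With \code{similarityMode = "identity"} percent
#'   identity is thresholded instead.
#' @param coverageMode \code{"target_span"} (default) or
#'   \code{"length_ratio"}.
#' @param similarityMode \code{"similarity"} (default) or
#'   \code{"identity"}.
#' @return a \code{list} of class \code{"CopyNumberResult"}:
#'   \code{family}, \code{query_id}, \code{copies} (ids),
#'   \code{n_copies}, \code{scaffolds} (unique known scaffolds),
#'   \code{hits} (per-copy hit table with bit scores, used by
#'   [dedupeCopies()]), \code{assignments_dropped}.
#' @export
countCopies <- function(queryId, family, proteome, scheme, models = NULL,
                        cutoff = 1e-5, minCoverage = 0.5,
                        minSimilarity = 70,
                        coverageMode = c("target_span", "length_ratio"),
                        similarityMode = c("similarity", "identity")) {
  coverageMode <- match.arg(coverageMode)
  similarityMode <- match.arg(similarityMode)
  if (!queryId %in% names(proteome))
    stop("query '", queryId, "' is not in the proteome")
  qseq <- as.character(proteome[[queryId]])
  m <- nchar(qseq)
  n <- sum(Biostrings::width(proteome))
  ids <- names(proteome)
  hits <- lapply(seq_along(proteome), function(i) {
    h <- smithWaterman(stats::setNames(qseq, queryId),
                       stats::setNames(as.character(proteome[[i]]), ids[i]),
                       scheme, m = m, n = n)
    h$target_len <- Biostrings::width(proteome)[i]
    h
  })
  hits <- do.call(rbind, hits)
  cov <- if (coverageMode == "target_span") hits$tcov
         else m / hits$target_len
  sim <- if (similarityMode == "similarity") hits$psim else hits$pident
  ok <- hits$evalue <= cutoff & cov >= minCoverage & sim >= minSimilarity
  ok[hits$sseqid == queryId] <- TRUE
  copies <- hits$sseqid[ok]
  chits <- hits[ok, , drop = FALSE]
  scaffolds <- character()
  if (length(copies)) {
    if (is.null(models)) {
      warning("no gene models supplied; scaffolds unknown for family ",
              family)
      scaffolds <- NA_character_
    } else {
      sc <- scaffoldOf(models, copies)
      if (anyNA(sc))
        warning("no gene model for: ",
                paste(copies[is.na(sc)], collapse = ", "),
                "; their scaffold is counted once as unknown")
      scaffolds <- unique(sc)
    }
  }
  structure(list(family = family, query_id = queryId, copies = copies,
                 n_copies = length(copies), scaffolds = scaffolds,
                 hits = chits,
                 assignments_dropped = data.frame(
                   protein_id = character(), losing_family = character(),
                   winning_family = character(), stringsAsFactors = FALSE)),
            class = "CopyNumberResult")
}

#' @export
print.CopyNumberResult <- function(x, ...) {
  cat(sprintf("CopyNumberResult: %s, %d copies on %d scaffold(s) [query %s]\n",
              x$family, x$n_copies, length(x$scaffolds[!is.na(x$scaffolds)]),
              x$query_id))
  invisible(x)
}

#' Deduplicate copy assignments across families
#'
#' Several anticoagulant families share similar compositions, so one
#' protein can qualify as a copy of more than one family.  Each protein
#' is assigned to exactly one family: the one whose query hits it with
#' the highest bit score (ties: lower E-value, then lexicographically
#' first family name).  Losing assignments are recorded in
#' \code{assignments_dropped}.
#'
#' @param results a list of \code{CopyNumberResult}s (one per family).
#' @param models optional [GeneModelSet-class] to recompute scaffold sets
#'   after deduplication.
#' @return the list with \code{copies}, \code{n_copies},
#'   \code{scaffolds} and \code{assignments_dropped} updated.
#' @export
dedupeCopies <- function(results, models = NULL) {
  claims <- do.call(rbind, lapply(results, function(r)
    if (r$n_copies)
      data.frame(protein_id = r$copies, family = r$family,
                 bitscore = r$hits$bitscore, evalue = r$hits$evalue,
                 stringsAsFactors = FALSE)))
  if (is.null(claims) || nrow(claims) == 0L) return(results)
  claims <- claims[order(claims$protein_id, -claims$bitscore,
                         claims$evalue, claims$family), , drop = FALSE]
  winner <- claims[!duplicated(claims$protein_id), , drop = FALSE]
  winOf <- stats::setNames(winner$family, winner$protein_id)
  lapply(results, function(r) {
    keep <- winOf[r$copies] == r$family
    dropped <- r$copies[!keep]
    r$assignments_dropped <- data.frame(
      protein_id = dropped, losing_family = rep(r$family, length(dropped)),
      winning_family = unname(winOf[dropped]), stringsAsFactors = FALSE)
    r$copies <- r$copies[keep]
    r$hits <- r$hits[keep, , drop = FALSE]
    r$n_copies <- length(r$copies)
    if (!is.null(models)) {
      r$scaffolds <- if (r$n_copies) unique(scaffoldOf(models, r$copies))
                     else character()
    } else if (r$n_copies == 0L) r$scaffolds <- character()
    r
  })
}

#' Detect tandem arrays of family copies
#'
#' A tandem array is a maximal run of two or more same-family copies at
#' consecutive per-scaffold gene order positions; \code{maxGap} relaxes
#' adjacency (neighbours may differ by up to \code{maxGap + 1} gene
#' index positions).
#'
#' @param result a \code{CopyNumberResult}.
#' @param models a [GeneModelSet-class].
#' @param maxGap allowed number of intervening genes (default 0:
#'   strictly adjacent).
#' @return a \code{data.frame} with one row per array: \code{scaffold_id},
#'   \code{family}, \code{members} (comma-joined ids in gene order),
#'   \code{first_index}, \code{last_index}, \code{length}.
#' @export
detectTandem <- function(result, models, maxGap = 0L) {
  copies <- result$copies
  sc <- scaffoldOf(models, copies)
  gi <- geneIndexOf(models, copies)
  keep <- !is.na(sc) & !is.na(gi)
  copies <- copies[keep]; sc <- sc[keep]; gi <- gi[keep]
  out <- list()
  for (s in unique(sc)) {
    i <- sc == s
    ord <- order(gi[i])
    ids <- copies[i][ord]
    idx <- gi[i][ord]
    if (length(idx) < 2L) next
    grp <- cumsum(c(1L, diff(idx) > maxGap + 1L))
    for (g in unique(grp)) {
      members <- ids[grp == g]
      span <- idx[grp == g]
      if (length(members) >= 2L)
        out[[length(out) + 1L]] <- data.frame(
          scaffold_id = s, family = result$family,
          members = paste(members, collapse = ","),
          first_index = span[1L], last_index = span[length(span)],
          length = length(members), stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(scaffold_id = character(), family = character(),
                  members = character(), first_index = integer(),
                  last_index = integer(), length = integer(),
                  stringsAsFactors = FALSE)
}

# pairwise size-conservation score of two length vectors: positions are
# paired in order, unpaired positions score 0, denominator max(#a, #b)
.sizeConservation <- function(a, b) {
  ka <- length(a); kb <- length(b)
  if (ka == 0L && kb == 0L) return(NA_real_)
  k <- min(ka, kb)
  scores <- if (k > 0L)
    1 - abs(a[seq_len(k)] - b[seq_len(k)]) / pmax(a[seq_len(k)], b[seq_len(k)])
  else numeric()
  sum(scores) / max(ka, kb)
}

.conservationClass <- function(x) {
  if (is.na(x)) NA_character_
  else if (x >= 0.9) "strong"
  else if (x < 0.6) "low"
  else "mixed"
}

#' Exon and intron size conservation between family copies
#'
#' Exon-length vectors of every pair of copies are compared positionally
#' (genomic order); each paired position scores
#' \code{1 - |a - b| / max(a, b)}, unpaired positions score 0, and the
#' pair mean uses the larger exon count as denominator.  The family value
#' is the mean over all copy pairs, classed \code{strong} (>= 0.9),
#' \code{low} (< 0.6) or \code{mixed} in between.  Introns are scored
#' the same way, separately.
#'
#' @param models a [GeneModelSet-class].
#' @param ids ids of the modeled copies (at least 2).
#' @return a list: \code{exon_conservation}, \code{exon_class},
#'   \code{intron_conservation}, \code{intron_class}, \code{n_copies};
#'   or an empty list when fewer than two copies have models.
#' @export
exonIntronConservation <- function(models, ids) {
  ids <- ids[ids %in% models@anno$protein_id]
  if (length(ids) < 2L) return(list())
  exv <- lapply(ids, function(id) exonLengths(models, id))
  inv <- lapply(ids, function(id) intronLengths(models, id))
  pairScores <- function(v) {
    ps <- c()
    for (i in seq_len(length(v) - 1L))
      for (j in (i + 1L):length(v))
        ps <- c(ps, .sizeConservation(v[[i]], v[[j]]))
    if (all(is.na(ps))) NA_real_ else mean(ps, na.rm = TRUE)
  }
  ex <- pairScores(exv)
  it <- pairScores(inv)
  list(exon_conservation = ex, exon_class = .conservationClass(ex),
       intron_conservation = it, intron_class = .conservationClass(it),
       n_copies = length(ids))
}
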