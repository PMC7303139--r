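# Pairwise affine-gap alignment (desk-scale stand-in for BLASTp) and
# ranked database search with Karlin-Altschul statistics.

# Run the Gotoh DP and assemble gapped rows plus per-column indices.
# type: "local", "overlap" (semi-global, free terminal gaps), "global".
.alignRaw <- function(qseq, tseq, scheme, type) {
  mode <- match(type, c("local", "overlap", "global")) - 1L
  qi <- .encodeAA(qseq, "query")
  ti <- .encodeAA(tseq, "target")
  res <- .gotoh_align(qi, ti, scheme@matrix, scheme@gapOpen,
                      scheme@gapExtend, mode)
  qch <- strsplit(toupper(qseq), "")[[1L]]
  tch <- strsplit(toupper(tseq), "")[[1L]]
  rowA <- ifelse(res$a_pos > 0L, qch[pmax(res$a_pos, 1L)], "-")
  rowB <- ifelse(res$b_pos > 0L, tch[pmax(res$b_pos, 1L)], "-")
  list(score = res$score, rowA = paste(rowA, collapse = ""),
       rowB = paste(rowB, collapse = ""),
       aPos = res$a_pos, bPos = res$b_pos,
       qStart = res$q_start, qEnd = res$q_end,
       sStart = res$s_start, sEnd = res$s_end)
}

# Column statistics over an alignment given as index vectors.
.alignColumnStats <- function(aPos, bPos, qch, tch, S) {
  len <- length(aPos)
  shared <- aPos > 0L & bPos > 0L
  a <- qch[aPos[shared]]
  b <- tch[bPos[shared]]
  ident <- sum(a == b)
  pos <- sum(a == b | S[cbind(a, b)] > 0)
  gapRuns <- function(v) {
    r <- rle(v == 0L)
    sum(r$values)
  }
  list(length = len, nShared = sum(shared), nIdentical = ident,
       nPositive = pos, mismatch = sum(shared) - ident,
       gapOpenings = gapRuns(aPos) + gapRuns(bPos))
}

#' Optimal local alignment of two proteins (Smith-Waterman)
#'
#' Affine-gap local alignment under the Gotoh recurrences with a fixed
#' traceback tie order (diagonal, then up, then left) so results are
#' reproducible bit for bit.  Identity and similarity percentages are
#' computed over all aligned columns (gap columns included, as in BLAST
#' tabular output); similarity counts identical residues plus
#' positive-scoring substitutions.
#'
#' @param query,target single sequences (character, \code{AAString} or
#'   length-1 \code{AAStringSet}); names are used as ids when present.
#' @param scheme a [ScoringScheme-class].
#' @param m,n search-space sizes for the E-value; default to the two
#'   sequence lengths.  [searchProteins()] passes the summed database
#'   length as \code{n}.
#' @return a one-row \code{data.frame} with columns \code{qseqid},
#'   \code{sseqid}, \code{rawscore}, \code{bitscore}, \code{evalue},
#'   \code{pident}, \code{psim}, \code{length}, \code{mismatch},
#'   \code{gapopen}, \code{qstart}, \code{qend}, \code{sstart},
#'   \code{send}, \code{tcov} (aligned target span / target length).
#' @examples
#' sc <- scoringScheme()
#' smithWaterman(c(q = "HEAGAWGHEE"), c(t = "PAWHEAE"), sc)
#' @export
smithWaterman <- function(query, target, scheme,
                          m = NULL, n = NULL) {
  q <- .seqAndId(query, "query")
  t <- .seqAndId(target, "target")
  al <- .alignRaw(q$seq, t$seq, scheme, "local")
  qch <- strsplit(toupper(q$seq), "")[[1L]]
  tch <- strsplit(toupper(t$seq), "")[[1L]]
  st <- .alignColumnStats(al$aPos, al$bPos, qch, tch, scheme@matrix)
  if (is.null(m)) m <- length(qch)
  if (is.null(n)) n <- length(tch)
  bits <- bitScore(al$score, scheme)
  data.frame(
    qseqid = q$id, sseqid = t$id,
    rawscore = al$score, bitscore = bits,
    evalue = expectValue(bits, m, n),
    pident = if (st$length > 0) 100 * st$nIdentical / st$length else 0,
    psim = if (st$length > 0) 100 * st$nPositive / st$length else 0,
    length = st$length, mismatch = st$mismatch, gapopen = st$gapOpenings,
    qstart = al$qStart, qend = al$qEnd,
    sstart = al$sStart, send = al$sEnd,
    tcov = if (al$sEnd >= al$sStart && al$sStart > 0)
      (al$sEnd - al$sStart + 1) / length(tch) else 0,
    stringsAsFactors = FALSE)
}

#' Search a protein database with one query
#'
#' Aligns the query against every database member, attaches E-values
#' computed over the whole search space (n = summed residue count of the
#' database) and returns the hits at or below the E-value cutoff, ranked
#' by ascending E-value with ties broken by descending bit score and then
#' by target id.
#'
#' @param query a single sequence (named character or \code{AAStringSet}
#'   of length 1).
#' @param db an \code{AAStringSet} (or named character vector) of database
#'   sequences.
#' @param scheme a [ScoringScheme-class].
#' @param evalueCutoff report hits with \code{evalue <= evalueCutoff}
#'   (default \code{1e-5}, the screening cutoff).
#' @return a \code{data.frame} of hits in [smithWaterman()] layout; zero
#'   rows when nothing passes the cutoff.
#' @export
searchProteins <- function(query, db, scheme, evalueCutoff = 1e-5) {
  if (is.character(db)) db <- Biostrings::AAStringSet(db)
  if (length(db) == 0L) stop("database is empty")
  if (is.null(names(db)) || any(!nzchar(names(db))))
    stop("database sequences must be named")
  q <- .seqAndId(query, "query")
  m <- nchar(q$seq)
  n <- sum(Biostrings::width(db))
  hits <- lapply(seq_along(db), function(i) {
    smithWaterman(stats::setNames(q$seq, q$id),
                  stats::setNames(as.character(db[[i]]), names(db)[i]),
                  scheme, m = m, n = n)
  })
  hits <- do.call(rbind, hits)
  hits <- hits[hits$evalue <= evalueCutoff, , drop = FALSE]
  hits <- hits[order(hits$evalue, -hits$bitscore, hits$sseqid), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write a hit table in the canonical 12-column tabular format
#'
#' Emits the classic tab-separated columns \code{qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore} for
#' interoperability with other tooling.
#'
#' @param hits a hit \code{data.frame} from [smithWaterman()] or
#'   [searchProteins()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeHitTable <- function(hits, path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  out <- hits[, cols, drop = FALSE]
  out$pident <- sprintf("%.3f", out$pident)
  out$evalue <- sprintf("%.2e", out$evalue)
  out$bitscore <- sprintf("%.1f", out$bitscore)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
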