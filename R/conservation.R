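# Pairwise candidate-vs-archetype conservation reports: semi-global
# alignment, terminal-gap truncation, shared-site similarity, cysteine
# conservation, indel spans and homopolymer runs.

#' Global (semi-global) alignment of two proteins
#'
#' Needleman-Wunsch alignment with affine gaps and free terminal gaps, so
#' that leading and lagging overhangs appear as terminal gap columns that
#' [trimTerminalGaps()] can truncate -- mirroring an align-then-truncate
#' workflow.  Traceback tie order is diagonal, then up, then left.
#'
#' @param a,b single sequences; by convention \code{a} is the candidate
#'   and \code{b} the archetype.
#' @param scheme a [ScoringScheme-class].
#' @param type \code{"overlap"} (default: free terminal gaps) or
#'   \code{"global"} (terminal gaps charged).
#' @return an [AlignedPair-class].
#' @examples
#' sc <- scoringScheme()
#' aln <- globalAlign(c(new = "ACDEFG"), c(ref = "ACFG"), sc)
#' conservationStats(trimTerminalGaps(aln), sc)
#' @export
globalAlign <- function(a, b, scheme, type = c("overlap", "global")) {
  type <- match.arg(type)
  sa <- .seqAndId(a, "a")
  sb <- .seqAndId(b, "b")
  al <- .alignRaw(sa$seq, sb$seq, scheme, type)
  new("AlignedPair", idA = sa$id, idB = sb$id,
      rowA = al$rowA, rowB = al$rowB, score = al$score,
      type = type, trimmed = FALSE)
}

#' Truncate terminal gap columns from a pairwise alignment
#'
#' Columns are removed from both ends of the alignment while either row
#' carries a gap there; internal gaps (true indels) are untouched.  The
#' result is flagged \code{trimmed} and is the basis of every
#' conservation statistic.
#'
#' @param aln an [AlignedPair-class].
#' @return the trimmed [AlignedPair-class].
#' @export
trimTerminalGaps <- function(aln) {
  stopifnot(is(aln, "AlignedPair"))
  ca <- strsplit(aln@rowA, "")[[1L]]
  cb <- strsplit(aln@rowB, "")[[1L]]
  gap <- ca == "-" | cb == "-"
  keep <- which(!gap)
  if (length(keep) == 0L)
    stop("degenerate alignment: no column has residues in both rows")
  from <- keep[1L]
  to <- keep[length(keep)]
  new("AlignedPair", idA = aln@idA, idB = aln@idB,
      rowA = paste(ca[from:to], collapse = ""),
      rowB = paste(cb[from:to], collapse = ""),
      score = aln@score, type = aln@type, trimmed = TRUE)
}

# maximal runs of TRUE in a logical vector -> data.frame(start, length)
.runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], length = r$lengths[r$values])
}

# longest homopolymer run of an ungapped sequence
.maxHomopolymer <- function(chars) {
  chars <- chars[chars != "-"]
  if (length(chars) == 0L)
    return(list(residue = NA_character_, length = 0L))
  r <- rle(chars)
  i <- which.max(r$lengths)
  list(residue = r$values[i], length = as.integer(r$lengths[i]))
}

#' Conservation statistics of a trimmed pairwise alignment
#'
#' Shared columns are the columns holding a residue in both rows (gaps
#' not counted); identity and similarity percentages use shared columns
#' as the denominator, similarity adding positive-scoring substitutions.
#' Cysteine conservation counts the archetype (row B) cysteines whose
#' column holds C in both rows.  Indel spans are the maximal internal gap
#' runs per row; homopolymers are the longest single-residue runs of each
#' ungapped sequence.
#'
#' @param aln a trimmed [AlignedPair-class] (see [trimTerminalGaps()]).
#' @param scheme a [ScoringScheme-class] (defines which substitutions
#'   count as positive).
#' @return a list with elements \code{pctIdentityShared},
#'   \code{pctSimilarityShared}, \code{nSharedColumns},
#'   \code{cysInArchetype}, \code{cysConserved}, \code{indelSpans}
#'   (data.frame \code{row} in a/b, \code{start}, \code{length}) and
#'   \code{maxHomopolymer} (data.frame \code{row}, \code{residue},
#'   \code{length}).
#' @export
conservationStats <- function(aln, scheme) {
  stopifnot(is(aln, "AlignedPair"))
  if (!aln@trimmed)
    stop("conservation statistics are defined on trimmed alignments; ",
         "call trimTerminalGaps() first")
  ca <- strsplit(aln@rowA, "")[[1L]]
  cb <- strsplit(aln@rowB, "")[[1L]]
  shared <- ca != "-" & cb != "-"
  n <- sum(shared)
  if (n == 0L) stop("no shared columns: statistics undefined")
  a <- ca[shared]
  b <- cb[shared]
  ident <- a == b
  positive <- ident | scheme@matrix[cbind(a, b)] > 0
  cysArch <- sum(cb == "C")
  cysCons <- sum(ca == "C" & cb == "C")
  spans <- rbind(
    if (any(ca == "-")) cbind(row = "a", .runs(ca == "-")),
    if (any(cb == "-")) cbind(row = "b", .runs(cb == "-")))
  if (is.null(spans))
    spans <- data.frame(row = character(), start = integer(),
                        length = integer())
  ha <- .maxHomopolymer(ca)
  hb <- .maxHomopolymer(cb)
  list(
    pctIdentityShared = 100 * sum(ident) / n,
    pctSimilarityShared = 100 * sum(positive) / n,
    nSharedColumns = n,
    cysInArchetype = cysArch,
    cysConserved = cysCons,
    indelSpans = spans,
    maxHomopolymer = data.frame(
      row = c("a", "b"),
      residue = c(ha$residue, hb$residue),
      length = c(ha$length, hb$length),
      stringsAsFactors = FALSE))
}

#' Write aligned pairs to aligned FASTA
#'
#' @param alns a list of [AlignedPair-class] objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAlignedFasta <- function(alns, path) {
  if (is(alns, "AlignedPair")) alns <- list(alns)
  lines <- unlist(lapply(alns, function(a)
    c(paste0(">", a@idA), a@rowA, paste0(">", a@idB), a@rowB)))
  writeLines(lines, path)
  invisible(path)
}
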