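#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib hirumine, .registration = TRUE
NULL

# Alphabet used throughout: the 20 canonical amino acids plus X.
# Any other letter (ambiguity codes B, Z, J, U, O, *) is rejected on input.
.AA21 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Scoring scheme for protein alignment and search statistics
#'
#' Bundles a symmetric substitution matrix over the 20 canonical amino
#' acids plus X, affine gap costs (a gap of length L costs
#' \code{gapOpen + L * gapExtend}) and the Karlin-Altschul parameters
#' lambda and K used to convert raw alignment scores into bit scores and
#' E-values.
#'
#' @slot matrix symmetric numeric substitution matrix with identical row
#'   and column names drawn from the 21-letter alphabet.
#' @slot gapOpen positive gap opening cost.
#' @slot gapExtend positive gap extension cost, at most \code{gapOpen}.
#' @slot lambda positive Karlin-Altschul scale parameter.
#' @slot K positive Karlin-Altschul search-space constant.
#' @seealso [scoringScheme()], [bitScore()], [expectValue()]
#' @exportClass ScoringScheme
setClass("ScoringScheme",
  representation(matrix = "matrix", gapOpen = "numeric",
                 gapExtend = "numeric", lambda = "numeric", K = "numeric"))

setValidity("ScoringScheme", function(object) {
  m <- object@matrix
  msgs <- character()
  if (nrow(m) != ncol(m) || is.null(rownames(m)) ||
      !identical(rownames(m), colnames(m)))
    msgs <- c(msgs, "substitution matrix must be square with matching dimnames")
  else if (!isSymmetric(unname(m)))
    msgs <- c(msgs, "substitution matrix must be symmetric")
  if (length(object@gapOpen) != 1L || object@gapOpen <= 0)
    msgs <- c(msgs, "gapOpen must be a single positive number")
  if (length(object@gapExtend) != 1L || object@gapExtend <= 0)
    msgs <- c(msgs, "gapExtend must be a single positive number")
  if (length(object@gapExtend) == 1L && length(object@gapOpen) == 1L &&
      object@gapExtend > object@gapOpen)
    msgs <- c(msgs, "gapExtend must not exceed gapOpen")
  if (length(object@lambda) != 1L || object@lambda <= 0)
    msgs <- c(msgs, "lambda must be positive")
  if (length(object@K) != 1L || object@K <= 0)
    msgs <- c(msgs, "K must be positive")
  if (length(msgs)) msgs else TRUE
})

#' A pairwise alignment of two protein sequences
#'
#' Two equal-length gapped rows plus bookkeeping.  Produced by
#' [globalAlign()] (semi-global, free terminal gaps) and consumed by
#' [trimTerminalGaps()] and [conservationStats()].
#'
#' @slot idA,idB sequence identifiers (by convention A is the candidate
#'   and B the archetype).
#' @slot rowA,rowB equal-length gapped strings (\code{-} for gaps).
#' @slot score numeric alignment score.
#' @slot type alignment type, one of \code{"overlap"}, \code{"local"},
#'   \code{"global"}.
#' @slot trimmed \code{TRUE} once terminal gap columns were removed.
#' @exportClass AlignedPair
setClass("AlignedPair",
  representation(idA = "character", idB = "character",
                 rowA = "character", rowB = "character",
                 score = "numeric", type = "character",
                 trimmed = "logical"))

setValidity("AlignedPair", function(object) {
  msgs <- character()
  if (nchar(object@rowA) != nchar(object@rowB))
    msgs <- c(msgs, "aligned rows must have equal length")
  ca <- strsplit(object@rowA, "")[[1L]]
  cb <- strsplit(object@rowB, "")[[1L]]
  if (any(ca == "-" & cb == "-"))
    msgs <- c(msgs, "no column may be a gap in both rows")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn AlignedPair-class compact display of the alignment
#' @param object an \code{AlignedPair}
#' @export
setMethod("show", "AlignedPair", function(object) {
  cat(sprintf("AlignedPair (%s%s): %s vs %s, %d columns, score %.1f\n",
              object@type, if (object@trimmed) ", trimmed" else "",
              object@idA, object@idB, nchar(object@rowA), object@score))
  w <- min(60L, nchar(object@rowA))
  cat(" A: ", substr(object@rowA, 1L, w),
      if (nchar(object@rowA) > w) "..." else "", "\n", sep = "")
  cat(" B: ", substr(object@rowB, 1L, w),
      if (nchar(object@rowB) > w) "..." else "", "\n", sep = "")
  invisible(NULL)
})

#' Panel of archetypal anticoagulant proteins
#'
#' Each entry is a previously characterised anticoagulant used as the
#' search archetype for its family: a name, a controlled family label, a
#' source accession, the species of origin, the amino-acid sequence
#' (optionally left empty for user-supplied entries), the number of
#' cysteines expected in the archetype and a set of lower-cased synonyms
#' used to judge whether a reciprocal-search hit description is related
#' to the family.
#'
#' @slot entries a \code{data.frame} with columns \code{name},
#'   \code{family}, \code{accession}, \code{species}, \code{sequence},
#'   \code{known_cys_count}, \code{synonyms} (list column of lower-cased
#'   character vectors).
#' @seealso [readPanel()], [panelFamilies()], [familyMembers()]
#' @exportClass ArchetypePanel
setClass("ArchetypePanel", representation(entries = "data.frame"))

setValidity("ArchetypePanel", function(object) {
  e <- object@entries
  need <- c("name", "family", "accession", "species", "sequence",
            "known_cys_count", "synonyms")
  msgs <- character()
  if (!all(need %in% names(e)))
    msgs <- c(msgs, paste("missing panel columns:",
                          paste(setdiff(need, names(e)), collapse = ", ")))
  else {
    if (any(!nzchar(e$family)))
      msgs <- c(msgs, "every panel entry needs a non-empty family")
    if (anyDuplicated(e$name))
      msgs <- c(msgs, "panel entry names must be unique")
    bad <- nzchar(e$sequence) &
      !grepl(paste0("^[", paste(.AA21, collapse = ""), "]+$"), e$sequence)
    if (any(bad))
      msgs <- c(msgs, paste("invalid amino-acid letters in panel sequence:",
                            paste(e$name[bad], collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ArchetypePanel-class one-line summary per family
#' @param object an \code{ArchetypePanel}
#' @export
setMethod("show", "ArchetypePanel", function(object) {
  e <- object@entries
  cat(sprintf("ArchetypePanel: %d entries, %d families\n",
              nrow(e), length(unique(e$family))))
  for (f in unique(e$family)) {
    i <- e$family == f
    cat(sprintf("  %-20s %s\n", f, paste(e$name[i], collapse = ", ")))
  }
  invisible(NULL)
})

#' Gene models linked to predicted proteins
#'
#' One record per mRNA/protein: scaffold, strand, genomic span, the
#' per-scaffold gene order index (0-based, by ascending start coordinate,
#' strand ignored so that tandem-array detection works in genomic order)
#' and the ordered exon table.  Coordinates are 1-based inclusive
#' throughout, as in GFF3; intron k has length
#' \code{start[k + 1] - end[k] - 1}.
#'
#' @slot anno data.frame with columns \code{protein_id}, \code{gene_id},
#'   \code{scaffold_id}, \code{strand}, \code{start}, \code{end},
#'   \code{gene_index}.
#' @slot exons named list (by protein id) of two-column integer matrices
#'   \code{start}, \code{end}, sorted and non-overlapping.
#' @seealso [readGeneModels()], [exonLengths()], [intronLengths()]
#' @exportClass GeneModelSet
setClass("GeneModelSet",
  representation(anno = "data.frame", exons = "list"))

setValidity("GeneModelSet", function(object) {
  a <- object@anno
  msgs <- character()
  need <- c("protein_id", "gene_id", "scaffold_id", "strand", "start",
            "end", "gene_index")
  if (!all(need %in% names(a)))
    return(paste("missing annotation columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (anyDuplicated(a$protein_id))
    msgs <- c(msgs, "duplicate protein ids in gene models")
  if (!setequal(names(object@exons), a$protein_id))
    msgs <- c(msgs, "exon list names must match annotation protein ids")
  for (id in names(object@exons)) {
    ex <- object@exons[[id]]
    if (any(ex[, 1L] > ex[, 2L]))
      msgs <- c(msgs, paste0("exon with start > end in ", id))
    if (nrow(ex) > 1L) {
      if (is.unsorted(ex[, 1L], strictly = TRUE))
        msgs <- c(msgs, paste0("exons not sorted by start in ", id))
      else if (any(ex[-1L, 1L] <= ex[-nrow(ex), 2L]))
        msgs <- c(msgs, paste0("overlapping exons in ", id))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn GeneModelSet-class summary of scaffolds and gene counts
#' @param object a \code{GeneModelSet}
#' @export
setMethod("show", "GeneModelSet", function(object) {
  a <- object@anno
  cat(sprintf("GeneModelSet: %d gene models on %d scaffolds\n",
              nrow(a), length(unique(a$scaffold_id))))
  invisible(NULL)
})

#' Synthetic genome bundle with planted gene families
#'
#' Everything [plantGenome()] emits: a proteome, matching gene models, a
#' panel of simulated archetypes, signal-peptide annotations and the
#' machine-readable truth table that records what was planted where.
#'
#' @slot proteome \code{AAStringSet} of planted copies and decoys.
#' @slot models \code{GeneModelSet} for every protein.
#' @slot panel \code{ArchetypePanel} of the simulated archetypes.
#' @slot truth data.frame; one row per protein with its family (or
#'   \code{"decoy"}), scaffold, gene index, tandem array id, realized
#'   substitution fraction, indel spans and cysteine positions.
#' @slot signal data.frame of signal-peptide annotations.
#' @slot config the [simConfig()] list the bundle was generated from.
#' @seealso [plantGenome()], [writeSimBundle()]
#' @exportClass SimBundle
setClass("SimBundle",
  representation(proteome = "ANY", models = "GeneModelSet",
                 panel = "ArchetypePanel", truth = "data.frame",
                 signal = "data.frame", config = "list"))

#' @describeIn SimBundle-class summary of planted content
#' @param object a \code{SimBundle}
#' @export
setMethod("show", "SimBundle", function(object) {
  tr <- object@truth
  cat(sprintf(
    "SimBundle: %d proteins (%d planted in %d families, %d decoys), seed %d\n",
    nrow(tr), sum(tr$class != "decoy"),
    length(unique(tr$family[tr$class != "decoy"])),
    sum(tr$class == "decoy"), object@config$seed))
  invisible(NULL)
})
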