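# Forward + reciprocal screening: the decision procedure that turns hit
# lists into orthologue candidacy calls.  A proteome is screened against
# the archetype panel at the E-value cutoff; the top hit per family is
# then searched against one or more "global" reference databases, and a
# candidate is rejected when a clearly better reciprocal hit lands on a
# protein unrelated to the family.

# Descriptions that can never trigger a rejection: hits against
# unannotated proteins carry no evidence of unrelatedness.
.UNINFORMATIVE <- c("hypothetical protein", "uncharacterized protein",
                    "unnamed protein product")

#' Forward screen of a proteome against the archetype panel
#'
#' Aligns every proteome member against every panel archetype and, per
#' family, ranks the members whose best hit against any family member
#' reaches the E-value cutoff.  E-values are computed over the full panel
#' search space (n = summed panel residue count).
#'
#' @param proteome an \code{AAStringSet} (see [readProteome()]).
#' @param panel an [ArchetypePanel-class] with sequences.
#' @param scheme a [ScoringScheme-class].
#' @param cutoff E-value cutoff (default \code{1e-5}).
#' @return a named list (one element per family) of hit
#'   \code{data.frame}s with columns \code{protein_id}, \code{archetype},
#'   \code{evalue}, \code{bitscore}, \code{rawscore}, \code{pident},
#'   \code{psim}, \code{tcov}, \code{top} (logical; best hit of the
#'   family), ranked by ascending E-value.  Families without hits map to
#'   zero-row frames.
#' @export
forwardScreen <- function(proteome, panel, scheme, cutoff = 1e-5) {
  pseqs <- panelSequences(panel)
  if (length(pseqs) == 0L) stop("panel carries no sequences")
  fams <- panelFamilies(panel)
  famOf <- S4Vectors::mcols(pseqs)$family
  n <- sum(Biostrings::width(pseqs))
  ids <- names(proteome)
  seqs <- as.character(proteome)

  rows <- vector("list", length(ids) * length(pseqs))
  k <- 0L
  for (i in seq_along(ids)) {
    m <- nchar(seqs[i])
    for (j in seq_along(pseqs)) {
      hit <- smithWaterman(stats::setNames(seqs[i], ids[i]),
                           stats::setNames(as.character(pseqs[[j]]),
                                           names(pseqs)[j]),
                           scheme, m = m, n = n)
      k <- k + 1L
      hit$family <- famOf[j]
      rows[[k]] <- hit
    }
  }
  all <- do.call(rbind, rows)
  out <- lapply(fams, function(f) {
    h <- all[all$family == f & all$evalue <= cutoff, , drop = FALSE]
    if (nrow(h) == 0L)
      return(data.frame(protein_id = character(), archetype = character(),
                        evalue = numeric(), bitscore = numeric(),
                        rawscore = numeric(), pident = numeric(),
                        psim = numeric(), tcov = numeric(),
                        top = logical()))
    # best archetype hit per proteome member
    h <- h[order(h$evalue, -h$bitscore, h$sseqid), , drop = FALSE]
    h <- h[!duplicated(h$qseqid), , drop = FALSE]
    h <- h[order(h$evalue, -h$bitscore, h$qseqid), , drop = FALSE]
    data.frame(protein_id = h$qseqid, archetype = h$sseqid,
               evalue = h$evalue, bitscore = h$bitscore,
               rawscore = h$rawscore, pident = h$pident, psim = h$psim,
               tcov = h$tcov,
               top = seq_len(nrow(h)) == 1L,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  names(out) <- fams
  out
}

#' Reciprocal search of one candidate against global reference databases
#'
#' @param candidate a single named sequence.
#' @param globalDbs a named list of \code{AAStringSet} databases
#'   (descriptions in \code{mcols(db)$description} are reported; the
#'   sequence names are used otherwise).
#' @param scheme a [ScoringScheme-class].
#' @param cutoff reporting cutoff for the best hit (default 10, i.e.
#'   report whatever is found; candidates with no hit at all get an
#'   explicit no-hit marker).
#' @return a \code{data.frame} with one row per database: \code{db},
#'   \code{target}, \code{description}, \code{evalue}, \code{bitscore};
#'   \code{target} is \code{NA} for a no-hit marker.
#' @export
reciprocalScreen <- function(candidate, globalDbs, scheme, cutoff = 10) {
  if (length(globalDbs) == 0L || is.null(names(globalDbs)))
    stop("globalDbs must be a non-empty named list of databases")
  rows <- lapply(names(globalDbs), function(dbName) {
    db <- globalDbs[[dbName]]
    if (length(db) == 0L)
      stop("reciprocal database '", dbName, "' is empty")
    hits <- searchProteins(candidate, db, scheme, evalueCutoff = cutoff)
    if (nrow(hits) == 0L)
      return(data.frame(db = dbName, target = NA_character_,
                        description = "no hit", evalue = NA_real_,
                        bitscore = NA_real_, stringsAsFactors = FALSE))
    top <- hits[1L, ]
    desc <- S4Vectors::mcols(db)$description
    d <- if (!is.null(desc)) desc[match(top$sseqid, names(db))] else NA
    if (is.null(d) || is.na(d) || !nzchar(d)) d <- top$sseqid
    data.frame(db = dbName, target = top$sseqid, description = d,
               evalue = top$evalue, bitscore = top$bitscore,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# does a description match any synonym of the family (case-insensitive
# substring, either direction)?
.matchesSynonyms <- function(description, synonyms) {
  d <- tolower(description)
  any(vapply(synonyms, function(s)
    grepl(s, d, fixed = TRUE) || grepl(d, s, fixed = TRUE), logical(1L)))
}

.isUninformative <- function(description) {
  d <- tolower(description)
  any(vapply(.UNINFORMATIVE, function(u) grepl(u, d, fixed = TRUE),
             logical(1L)))
}

#' Classify a forward hit as orthologue candidate or reject it
#'
#' A candidate is rejected only when some reciprocal best hit is clearly
#' better than the best family-consistent evidence \emph{and} its
#' description matches no family synonym.  "Clearly better" means an
#' E-value at least \code{margin} times smaller (default 10x) than the
#' baseline, where the baseline is the best family-consistent reciprocal
#' E-value, or the forward E-value if no reciprocal hit is
#' family-consistent.  Hits described as hypothetical/uncharacterized/
#' unnamed proteins are uninformative and can never trigger a rejection.
#'
#' @param proteinId candidate protein id.
#' @param family panel family of the forward hit.
#' @param forwardEvalue E-value of the forward hit.
#' @param reciprocals \code{data.frame} from [reciprocalScreen()].
#' @param synonyms named list mapping families to lower-cased synonym
#'   vectors (see [familySynonyms()]).
#' @param margin rejection margin (default 10).
#' @return a one-row \code{data.frame}: \code{protein_id}, \code{family},
#'   \code{forward_evalue}, \code{status} (\code{candidate} or
#'   \code{rejected_unrelated}), \code{rejection_reason} (NA unless
#'   rejected), plus \code{reciprocal_best} (collapsed per-database
#'   summary string).
#' @export
classifyOrthology <- function(proteinId, family, forwardEvalue, reciprocals,
                              synonyms, margin = 10) {
  syn <- synonyms[[family]]
  if (is.null(syn)) syn <- tolower(family)
  hit <- reciprocals[!is.na(reciprocals$target), , drop = FALSE]
  related <- vapply(hit$description, .matchesSynonyms, logical(1L),
                    synonyms = syn)
  uninf <- vapply(hit$description, .isUninformative, logical(1L))
  baseline <- suppressWarnings(
    min(forwardEvalue, hit$evalue[related], na.rm = TRUE))
  offending <- hit[!related & !uninf, , drop = FALSE]
  status <- "candidate"
  reason <- NA_character_
  if (nrow(offending)) {
    best <- offending[which.min(offending$evalue), ]
    if (best$evalue * margin <= baseline) {
      status <- "rejected_unrelated"
      reason <- sprintf(
        "better hit against unrelated '%s' in %s (E=%.2g vs family baseline %.2g)",
        best$description, best$db, best$evalue, baseline)
    }
  }
  summary <- paste(sprintf("%s:%s(%.2g)", reciprocals$db,
                           reciprocals$description, reciprocals$evalue),
                   collapse = "; ")
  data.frame(protein_id = proteinId, family = family,
             forward_evalue = forwardEvalue, status = status,
             rejection_reason = reason, reciprocal_best = summary,
             stringsAsFactors = FALSE)
}

#' Run the full screen: forward hits, reciprocal filtering, decisions
#'
#' Applies [forwardScreen()], takes the top hit per family, runs
#' [reciprocalScreen()] on it and classifies it with
#' [classifyOrthology()].  Families without forward hits are reported
#' with status \code{no_hit}.
#'
#' @inheritParams forwardScreen
#' @param globalDbs named list of reference databases (see
#'   [reciprocalScreen()]).
#' @param margin rejection margin for [classifyOrthology()].
#' @param signal optional signal-peptide annotation \code{data.frame}
#'   (see [readSignalAnnotations()]); adds a \code{signal_peptide}
#'   column.
#' @return a \code{data.frame} with one row per family: the decision
#'   columns of [classifyOrthology()] plus \code{archetype} and, when
#'   annotations are given, \code{signal_peptide}.
#' @export
screenDecisions <- function(proteome, panel, globalDbs, scheme,
                            cutoff = 1e-5, margin = 10, signal = NULL) {
  fw <- forwardScreen(proteome, panel, scheme, cutoff = cutoff)
  syn <- familySynonyms(panel)
  rows <- lapply(names(fw), function(f) {
    h <- fw[[f]]
    if (nrow(h) == 0L)
      return(data.frame(protein_id = NA_character_, family = f,
                        forward_evalue = NA_real_, status = "no_hit",
                        rejection_reason = NA_character_,
                        reciprocal_best = NA_character_,
                        archetype = NA_character_,
                        stringsAsFactors = FALSE))
    top <- h[h$top, ][1L, ]
    rec <- reciprocalScreen(
      stats::setNames(as.character(proteome[[top$protein_id]]),
                      top$protein_id),
      globalDbs, scheme)
    d <- classifyOrthology(top$protein_id, f, top$evalue, rec, syn,
                           margin = margin)
    d$archetype <- top$archetype
    d
  })
  out <- do.call(rbind, rows)
  if (!is.null(signal)) {
    i <- match(out$protein_id, signal$protein_id)
    out$signal_peptide <- ifelse(
      is.na(i), NA_character_,
      ifelse(signal$present[i],
             sprintf("Yes (%d-%d)", signal$start[i], signal$end[i]), "No"))
  }
  rownames(out) <- NULL
  out
}
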