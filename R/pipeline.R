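# Orchestration: the whole mining pipeline behind a handful of stage
# functions plus runAll(), which ties them together on a synthetic
# bundle (or user-supplied objects) and writes the TSV reports.

#' Pipeline configuration
#'
#' Collects every threshold the pipeline uses: the forward/copy E-value
#' cutoff (1e-5), the copy-calling coverage (50% of the target) and
#' similarity (70%) thresholds, the reciprocal rejection margin (10x),
#' the clan support threshold (75%) and the number of bootstrap
#' replicates (1,000), plus the top-level seed from which all stage
#' seeds are derived.
#'
#' @param cutoff forward/copy E-value cutoff.
#' @param minCoverage minimum aligned target coverage for a copy.
#' @param minSimilarity minimum percent similarity for a copy.
#' @param margin reciprocal rejection margin.
#' @param supportThreshold bootstrap support needed for a supported
#'   orthology call.
#' @param bootstrapReps bootstrap replicates for gene trees.
#' @param maxGap allowed intervening genes inside a tandem array.
#' @param coverageMode,similarityMode see [countCopies()].
#' @param seed top-level seed.
#' @return a named list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(cutoff = 1e-5, minCoverage = 0.5,
                           minSimilarity = 70, margin = 10,
                           supportThreshold = 75, bootstrapReps = 1000L,
                           maxGap = 0L,
                           coverageMode = c("target_span", "length_ratio"),
                           similarityMode = c("similarity", "identity"),
                           seed = 1L) {
  cfg <- list(cutoff = cutoff, minCoverage = minCoverage,
              minSimilarity = minSimilarity, margin = margin,
              supportThreshold = supportThreshold,
              bootstrapReps = as.integer(bootstrapReps),
              maxGap = as.integer(maxGap),
              coverageMode = match.arg(coverageMode),
              similarityMode = match.arg(similarityMode),
              seed = as.integer(seed))
  stopifnot(cfg$cutoff > 0, cfg$minCoverage >= 0, cfg$minCoverage <= 1,
            cfg$minSimilarity >= 0, cfg$minSimilarity <= 100,
            cfg$margin >= 1, cfg$bootstrapReps >= 1, cfg$maxGap >= 0)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Screening stage
#'
#' Thin wrapper around [screenDecisions()] using a [pipelineConfig()].
#'
#' @param proteome,panel,globalDbs,scheme,signal see [screenDecisions()].
#' @param config a [pipelineConfig()].
#' @return the decisions \code{data.frame}.
#' @export
runScreen <- function(proteome, panel, globalDbs, scheme,
                      config = pipelineConfig(), signal = NULL) {
  if (length(panelSequences(panel)) == 0L)
    stop("invalid configuration: the archetype panel has no sequences")
  screenDecisions(proteome, panel, globalDbs, scheme,
                  cutoff = config$cutoff, margin = config$margin,
                  signal = signal)
}

#' Copy-number stage
#'
#' For every family whose screen decision is \code{candidate}, counts
#' copies under the three thresholds, deduplicates assignments across
#' families, detects tandem arrays and scores exon/intron size
#' conservation between modeled copies.
#'
#' @param decisions decisions \code{data.frame} from [runScreen()].
#' @param proteome an \code{AAStringSet}.
#' @param models a [GeneModelSet-class] (or NULL).
#' @param scheme a [ScoringScheme-class].
#' @param config a [pipelineConfig()].
#' @return a list: \code{results} (named list of deduped
#'   \code{CopyNumberResult}s), \code{table} (per-family summary),
#'   \code{tandem} (all arrays), \code{structure} (exon/intron classes).
#' @export
runCopies <- function(decisions, proteome, models, scheme,
                      config = pipelineConfig()) {
  cand <- decisions[decisions$status == "candidate", , drop = FALSE]
  results <- lapply(seq_len(nrow(cand)), function(i)
    countCopies(cand$protein_id[i], cand$family[i], proteome, scheme,
                models = models, cutoff = config$cutoff,
                minCoverage = config$minCoverage,
                minSimilarity = config$minSimilarity,
                coverageMode = config$coverageMode,
                similarityMode = config$similarityMode))
  names(results) <- cand$family
  results <- dedupeCopies(results, models = models)

  tandem <- do.call(rbind, c(lapply(results, detectTandem, models = models,
                                    maxGap = config$maxGap),
                             make.row.names = FALSE))
  structure_ <- do.call(rbind, lapply(names(results), function(f) {
    r <- results[[f]]
    ei <- exonIntronConservation(models, r$copies)
    if (!length(ei)) return(NULL)
    data.frame(family = f, n_modeled = ei$n_copies,
               exon_conservation = ei$exon_conservation,
               exon_class = ei$exon_class,
               intron_conservation = ei$intron_conservation,
               intron_class = ei$intron_class, stringsAsFactors = FALSE)
  }))
  table <- do.call(rbind, lapply(results, function(r) data.frame(
    family = r$family, query_id = r$query_id, n_copies = r$n_copies,
    n_scaffolds = length(r$scaffolds[!is.na(r$scaffolds)]),
    scaffolds = paste(r$scaffolds, collapse = ","),
    dropped = paste(r$assignments_dropped$protein_id, collapse = ","),
    stringsAsFactors = FALSE)))
  rownames(table) <- NULL
  list(results = results, table = table, tandem = tandem,
       structure = structure_)
}

#' Conservation stage
#'
#' Aligns each family's top candidate against its archetype, truncates
#' terminal gaps and reports the conservation statistics.
#'
#' @param decisions decisions \code{data.frame} from [runScreen()].
#' @param proteome an \code{AAStringSet}.
#' @param panel an [ArchetypePanel-class].
#' @param scheme a [ScoringScheme-class].
#' @return a list: \code{table} (one row per candidate-archetype pair)
#'   and \code{alignments} (list of trimmed [AlignedPair-class]s).
#' @export
runConserve <- function(decisions, proteome, panel, scheme) {
  cand <- decisions[decisions$status == "candidate", , drop = FALSE]
  pseqs <- panelSequences(panel)
  alns <- list()
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    id <- cand$protein_id[i]
    arch <- cand$archetype[i]
    aln <- trimTerminalGaps(globalAlign(
      stats::setNames(as.character(proteome[[id]]), id),
      stats::setNames(as.character(pseqs[[arch]]), arch), scheme))
    alns[[paste(id, arch, sep = "|")]] <<- aln
    st <- conservationStats(aln, scheme)
    data.frame(
      family = cand$family[i], protein_id = id, archetype = arch,
      pct_identity_shared = st$pctIdentityShared,
      pct_similarity_shared = st$pctSimilarityShared,
      n_shared_columns = st$nSharedColumns,
      cys_in_archetype = st$cysInArchetype,
      cys_conserved = st$cysConserved,
      n_indels = nrow(st$indelSpans),
      max_indel = if (nrow(st$indelSpans)) max(st$indelSpans$length) else 0L,
      max_homopolymer = max(st$maxHomopolymer$length),
      stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), alignments = alns)
}

#' Gene-tree stage
#'
#' Builds, per candidate family, a multiple alignment of the family's
#' deduped copies plus every panel archetype, an NJ tree with bootstrap
#' supports, and the clan-based orthology call for the top candidate
#' against its archetype.
#'
#' @param decisions decisions \code{data.frame} from [runScreen()].
#' @param copies output of [runCopies()].
#' @param proteome an \code{AAStringSet}.
#' @param panel an [ArchetypePanel-class].
#' @param scheme a [ScoringScheme-class].
#' @param config a [pipelineConfig()]; tree seeds derive from
#'   \code{config$seed} per family.
#' @return a list: \code{trees} (named list of \code{phylo}),
#'   \code{table} (per-family clan calls).
#' @export
runTree <- function(decisions, copies, proteome, panel, scheme,
                    config = pipelineConfig()) {
  cand <- decisions[decisions$status == "candidate", , drop = FALSE]
  pseqs <- panelSequences(panel)
  archFam <- stats::setNames(S4Vectors::mcols(pseqs)$family, names(pseqs))
  trees <- list()
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    f <- cand$family[i]
    r <- copies$results[[f]]
    ids <- unique(c(cand$protein_id[i], r$copies))
    seqs <- c(stats::setNames(as.character(proteome[ids]), ids),
              stats::setNames(as.character(pseqs), names(pseqs)))
    seqs <- Biostrings::AAStringSet(seqs)
    msa <- progressiveMSA(seqs, scheme)
    tr <- bootstrapSupport(msa, nReps = config$bootstrapReps,
                           seed = config$seed + i)
    trees[[f]] <<- tr
    fams <- c(stats::setNames(rep(f, length(ids)), ids), archFam)
    cr <- smallestClan(tr, query = cand$protein_id[i],
                       archetype = cand$archetype[i], families = fams,
                       supportThreshold = config$supportThreshold)
    data.frame(family = f, protein_id = cand$protein_id[i],
               archetype = cand$archetype[i],
               clan_size = length(cr$smallest_clan),
               clan = paste(cr$smallest_clan, collapse = ","),
               support = cr$support, call = cr$call,
               trivial = cr$trivial, stringsAsFactors = FALSE)
  })
  list(trees = trees, table = do.call(rbind, rows))
}

#' Run the whole pipeline on a synthetic bundle
#'
#' Screens the bundle's proteome against its panel (reciprocal reference
#' databases are the panel archetypes and the decoy reference set),
#' counts copies, detects tandem arrays, computes conservation reports
#' and clan-based orthology calls, and optionally writes every report to
#' \code{outDir} (\code{decisions.tsv}, \code{copy_number.tsv},
#' \code{tandem.tsv}, \code{structure.tsv}, \code{conservation.tsv},
#' \code{clans.tsv}, \code{trees/<family>.nwk}, \code{config.txt}).
#'
#' @param bundle a [SimBundle-class] from [plantGenome()].
#' @param outDir optional output directory.
#' @param config a [pipelineConfig()].
#' @param scheme a [ScoringScheme-class].
#' @return a list with elements \code{decisions}, \code{copies},
#'   \code{conservation}, \code{trees}.
#' @export
runAll <- function(bundle, outDir = NULL, config = pipelineConfig(),
                   scheme = scoringScheme()) {
  stopifnot(is(bundle, "SimBundle"))
  proteome <- bundle@proteome
  tr <- bundle@truth
  decoyIds <- tr$protein_id[tr$class == "decoy"]
  refPanel <- panelSequences(bundle@panel)
  S4Vectors::mcols(refPanel)$description <- names(refPanel)
  decoyDb <- proteome[decoyIds]
  S4Vectors::mcols(decoyDb)$description <-
    S4Vectors::mcols(proteome)$description[match(decoyIds,
                                                 names(proteome))]
  globalDbs <- list(archetype_refs = refPanel, unrelated_refs = decoyDb)

  decisions <- runScreen(proteome, bundle@panel, globalDbs, scheme,
                         config = config, signal = bundle@signal)
  copies <- runCopies(decisions, proteome, bundle@models, scheme,
                      config = config)
  conserve <- runConserve(decisions, proteome, bundle@panel, scheme)
  trees <- runTree(decisions, copies, proteome, bundle@panel, scheme,
                   config = config)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) if (!is.null(x))
      utils::write.table(x, file.path(outDir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wt(decisions, "decisions.tsv")
    wt(copies$table, "copy_number.tsv")
    wt(copies$tandem, "tandem.tsv")
    wt(copies$structure, "structure.tsv")
    wt(conserve$table, "conservation.tsv")
    wt(trees$table, "clans.tsv")
    dir.create(file.path(outDir, "trees"), showWarnings = FALSE)
    for (f in names(trees$trees))
      writeNewickTree(trees$trees[[f]],
                      file.path(outDir, "trees", paste0(f, ".nwk")))
    writeLines(c(sprintf("hirumine %s",
                         as.character(utils::packageVersion("hirumine"))),
                 sprintf("%s = %s", names(unclass(config)),
                         vapply(unclass(config), format, ""))),
               file.path(outDir, "config.txt"))
  }
  list(decisions = decisions, copies = copies, conservation = conserve,
       trees = trees)
}
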