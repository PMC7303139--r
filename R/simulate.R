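# Synthetic proteomes with planted anticoagulant-like gene families:
# archetypes with frozen cysteine scaffolds, evolved copies (Jukes-
# Cantor substitutions, Poisson indels), tandem arrays and dispersed
# duplicates laid out on scaffolds with decoy proteins, plus a
# machine-readable truth table.  Everything is deterministic in the
# seed, so every pipeline stage is testable without downloads.

#' Simulation configuration
#'
#' The defaults define the standard study conditions used throughout the
#' package's tests: six families of four copies (half of each family in
#' a tandem array), 300-residue archetypes with a 10-cysteine scaffold
#' retained during divergence, copies at 0.1 expected substitutions per
#' site, occasional short indels, thirty decoy proteins and twelve
#' scaffolds.
#'
#' @param seed integer RNG seed; identical configurations produce
#'   byte-identical outputs.
#' @param nFamilies number of planted families.
#' @param archetypeLength archetype length in residues.
#' @param cysCount cysteines planted per archetype.
#' @param copiesPerFamily evolved copies per family.
#' @param tandemFraction fraction of each family's copies placed at
#'   consecutive gene positions on one scaffold (an array forms when at
#'   least two copies land there).
#' @param divergenceT expected substitutions per site between archetype
#'   and copy (Jukes-Cantor time).
#' @param cysRetentionP probability that a cysteine scaffold site
#'   resists substitution (1 = frozen scaffold).
#' @param indelRate expected number of indel events per copy (Poisson).
#' @param indelLengthP geometric length parameter of an indel (mean
#'   length \code{1/indelLengthP}).
#' @param nDecoys number of unrelated decoy proteins.
#' @param nScaffolds number of scaffolds.
#' @param intronJitter standard deviation of the multiplicative
#'   (1 + Normal) jitter applied to each copy's intron lengths.
#' @param signalFraction fraction of planted copies annotated with a
#'   signal peptide (annotation only; no sequence realism).
#' @return a named list of class \code{"SimConfig"}.
#' @export
simConfig <- function(seed = 1L, nFamilies = 6L, archetypeLength = 300L,
                      cysCount = 10L, copiesPerFamily = 4L,
                      tandemFraction = 0.5, divergenceT = 0.1,
                      cysRetentionP = 1, indelRate = 0.5,
                      indelLengthP = 0.3, nDecoys = 30L, nScaffolds = 12L,
                      intronJitter = 0.1, signalFraction = 0.5) {
  cfg <- list(seed = as.integer(seed), nFamilies = as.integer(nFamilies),
              archetypeLength = as.integer(archetypeLength),
              cysCount = as.integer(cysCount),
              copiesPerFamily = as.integer(copiesPerFamily),
              tandemFraction = tandemFraction, divergenceT = divergenceT,
              cysRetentionP = cysRetentionP, indelRate = indelRate,
              indelLengthP = indelLengthP, nDecoys = as.integer(nDecoys),
              nScaffolds = as.integer(nScaffolds),
              intronJitter = intronJitter, signalFraction = signalFraction)
  stopifnot(cfg$nFamilies >= 0, cfg$archetypeLength >= 1,
            cfg$cysCount >= 0, cfg$cysCount <= cfg$archetypeLength,
            cfg$copiesPerFamily >= 0,
            cfg$tandemFraction >= 0, cfg$tandemFraction <= 1,
            cfg$divergenceT >= 0,
            cfg$cysRetentionP >= 0, cfg$cysRetentionP <= 1,
            cfg$indelRate >= 0,
            cfg$indelLengthP > 0, cfg$indelLengthP < 1,
            cfg$nDecoys >= 0, cfg$intronJitter >= 0,
            cfg$signalFraction >= 0, cfg$signalFraction <= 1)
  if (cfg$nScaffolds < 1L) stop("nScaffolds must be at least 1")
  class(cfg) <- "SimConfig"
  cfg
}

.AA19 <- setdiff(.AA21, c("C", "X"))  # residues drawn for non-cys sites

#' Simulate an archetype with a planted cysteine scaffold
#'
#' Residues are drawn uniformly from the 19 non-cysteine canonical
#' letters; \code{cysCount} positions chosen without replacement are set
#' to C and recorded.
#'
#' @param length sequence length.
#' @param cysCount number of cysteines (at most \code{length}).
#' @return a list: \code{sequence} (string), \code{cysPositions}
#'   (sorted integer positions).
#' @export
simulateArchetype <- function(length, cysCount) {
  if (cysCount > length) stop("cysCount must not exceed length")
  ch <- sample(.AA19, length, replace = TRUE)
  cys <- sort(sample.int(length, cysCount))
  ch[cys] <- "C"
  list(sequence = paste(ch, collapse = ""), cysPositions = cys)
}

#' Evolve a protein along a Jukes-Cantor branch with indels
#'
#' Substitutions follow the 20-state Jukes-Cantor chain: after time t
#' (expected substitutions per site) a site differs from the parent
#' with probability \eqn{(19/20)(1 - e^{-20t/19})}, the replacement
#' drawn uniformly from the other 19 letters.  Sites listed in
#' \code{cysPositions} are substituted only with probability
#' \code{1 - cysRetentionP} (times the site substitution probability),
#' emulating a conserved disulphide scaffold.  Indel events are
#' Poisson(\code{indelRate}) many, insertion/deletion equiprobable,
#' lengths geometric(\code{indelLengthP}), positions uniform over the
#' sequence interior.
#'
#' @param sequence parent amino-acid string.
#' @param t branch length (expected substitutions per site).
#' @param cysPositions parent positions exempted from substitution with
#'   probability \code{cysRetentionP}.
#' @param cysRetentionP,indelRate,indelLengthP see [simConfig()].
#' @return a list: \code{sequence} (child), \code{subFraction}
#'   (realized substituted fraction of parent sites),
#'   \code{indelSpans} (data.frame \code{type}, \code{start},
#'   \code{length} in child coordinates at the time of the event),
#'   \code{cysPositions} (child coordinates of the surviving scaffold
#'   cysteines).
#' @export
evolveProtein <- function(sequence, t, cysPositions = integer(),
                          cysRetentionP = 1, indelRate = 0,
                          indelLengthP = 0.3) {
  if (t < 0) stop("t must be non-negative")
  ch <- strsplit(sequence, "")[[1L]]
  L <- length(ch)
  pDiff <- (19 / 20) * (1 - exp(-20 * t / 19))
  pSite <- rep(pDiff, L)
  pSite[cysPositions] <- pDiff * (1 - cysRetentionP)
  hit <- stats::runif(L) < pSite
  for (i in which(hit)) {
    alt <- setdiff(.AA21[1:20], ch[i])
    ch[i] <- alt[sample.int(19L, 1L)]
  }
  subFraction <- sum(hit) / L

  # track parent site ids through indels so scaffold positions survive
  siteId <- seq_len(L)
  nIndel <- stats::rpois(1L, indelRate)
  spans <- data.frame(type = character(), start = integer(),
                      length = integer(), stringsAsFactors = FALSE)
  for (k in seq_len(nIndel)) {
    len <- stats::rgeom(1L, indelLengthP) + 1L
    cur <- length(ch)
    if (cur <= len + 2L) break
    if (stats::runif(1L) < 0.5) {          # deletion, interior only
      start <- sample(2:(cur - len), 1L)
      idx <- start:(start + len - 1L)
      ch <- ch[-idx]; siteId <- siteId[-idx]
      spans <- rbind(spans, data.frame(type = "del", start = start,
                                       length = len))
    } else {                               # insertion, interior only
      start <- sample(2:cur, 1L)
      ins <- sample(.AA19, len, replace = TRUE)
      ch <- append(ch, ins, after = start - 1L)
      siteId <- append(siteId, rep(NA_integer_, len), after = start - 1L)
      spans <- rbind(spans, data.frame(type = "ins", start = start,
                                       length = len))
    }
  }
  list(sequence = paste(ch, collapse = ""), subFraction = subFraction,
       indelSpans = spans,
       cysPositions = which(siteId %in% cysPositions & ch == "C"))
}

# exon structure for one gene: nExons exons holding 3*proteinLength nt
# of coding sequence split by fixed proportions, introns of the given
# lengths between them; returns start/end matrix anchored at `offset`
.layoutExons <- function(proteinLength, exonProps, intronLens, offset) {
  cds <- 3L * proteinLength
  nEx <- length(exonProps)
  sizes <- diff(round(cds * cumsum(c(0, exonProps)) / sum(exonProps)))
  sizes <- pmax(sizes, 3L)
  starts <- integer(nEx); ends <- integer(nEx)
  cur <- offset
  for (e in seq_len(nEx)) {
    starts[e] <- cur
    ends[e] <- cur + sizes[e] - 1L
    cur <- ends[e] + 1L + if (e < nEx) intronLens[e] else 0L
  }
  cbind(start = starts, end = ends)
}

#' Plant a synthetic genome
#'
#' Generates, per family, one archetype (exported to the panel) and
#' \code{copiesPerFamily} evolved copies; a \code{tandemFraction} of the
#' copies is placed at consecutive gene positions on one scaffold, the
#' rest dispersed so that no two same-family genes are accidentally
#' adjacent.  Decoys are simulated independently (no shared ancestry).
#' Every protein gets a gene model; intron lengths are jittered across
#' copies by \code{intronJitter}.  The truth table records family,
#' scaffold, gene index, tandem array id, realized substitution
#' fraction, indel spans, cysteine positions and the signal-peptide
#' flag.
#'
#' @param config a [simConfig()].
#' @return a [SimBundle-class].
#' @examples
#' bundle <- plantGenome(simConfig(seed = 7, nFamilies = 2, nDecoys = 5))
#' bundle
#' @export
plantGenome <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  fams <- sprintf("fam%02d", seq_len(config$nFamilies))
  panelRows <- list()
  prot <- list(); desc <- list()
  truth <- list()
  famExonProps <- list(); famIntrons <- list(); famExonCount <- list()

  for (f in seq_along(fams)) {
    fam <- fams[f]
    arch <- simulateArchetype(config$archetypeLength, config$cysCount)
    # no whitespace in the name: it doubles as a tree leaf label
    panelRows[[fam]] <- data.frame(
      name = paste0(fam, "_arch"), family = fam,
      accession = sprintf("SYN%05d", f), species = "Synthetica exempli",
      sequence = arch$sequence, known_cys_count = config$cysCount,
      stringsAsFactors = FALSE)
    nEx <- sample(2:4, 1L)
    famExonCount[[fam]] <- nEx
    famExonProps[[fam]] <- as.numeric(stats::runif(nEx, 0.5, 1.5))
    famIntrons[[fam]] <- round(stats::runif(nEx - 1L, 200, 800))
    for (k in seq_len(config$copiesPerFamily)) {
      id <- sprintf("%s_c%02d", fam, k)
      ev <- evolveProtein(arch$sequence, config$divergenceT,
                          arch$cysPositions, config$cysRetentionP,
                          config$indelRate, config$indelLengthP)
      prot[[id]] <- ev$sequence
      desc[[id]] <- sprintf("planted %s copy %d", fam, k)
      truth[[id]] <- data.frame(
        protein_id = id, class = "planted", family = fam,
        sub_fraction = ev$subFraction,
        n_indels = nrow(ev$indelSpans),
        indel_spans = paste(sprintf("%s:%d:%d", ev$indelSpans$type,
                                    ev$indelSpans$start,
                                    ev$indelSpans$length), collapse = ";"),
        cys_positions = paste(ev$cysPositions, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }

  for (k in seq_len(config$nDecoys)) {
    id <- sprintf("decoy_d%02d", k)
    dec <- simulateArchetype(sample(150:350, 1L), sample(0:6, 1L))
    prot[[id]] <- dec$sequence
    desc[[id]] <- sprintf("synthetic unrelated protein %d", k)
    truth[[id]] <- data.frame(
      protein_id = id, class = "decoy", family = "decoy",
      sub_fraction = NA_real_, n_indels = NA_integer_,
      indel_spans = "", cys_positions = paste(dec$cysPositions,
                                              collapse = ","),
      stringsAsFactors = FALSE)
  }

  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  # --- scaffold layout --------------------------------------------------
  scafIds <- sprintf("SCF_%06d", seq_len(config$nScaffolds))
  layout <- stats::setNames(vector("list", config$nScaffolds), scafIds)
  arrayOf <- character()

  nTandem <- round(config$tandemFraction * config$copiesPerFamily)
  for (f in seq_along(fams)) {
    fam <- fams[f]
    if (nTandem >= 2L) {
      s <- scafIds[(f - 1L) %% config$nScaffolds + 1L]
      blk <- sprintf("%s_c%02d", fam, seq_len(nTandem))
      layout[[s]] <- c(layout[[s]], blk)
      arrayOf[blk] <- paste0(fam, "_arr1")
    }
  }
  dispersed <- unlist(lapply(fams, function(fam) {
    from <- if (nTandem >= 2L) nTandem + 1L else 1L
    if (from > config$copiesPerFamily) character()
    else sprintf("%s_c%02d", fam, from:config$copiesPerFamily)
  }))
  pool <- sample(c(dispersed,
                   sprintf("decoy_d%02d", seq_len(config$nDecoys))))
  famOfId <- function(id) sub("_[cd][0-9]+$", "", id)
  sPtr <- 0L
  for (id in pool) {
    placed <- FALSE
    for (try in seq_len(config$nScaffolds)) {
      sPtr <- sPtr %% config$nScaffolds + 1L
      s <- scafIds[sPtr]
      last <- if (length(layout[[s]])) layout[[s]][length(layout[[s]])]
              else ""
      # only same-family adjacency matters (it would fake a tandem array)
      if (!nzchar(last) || famOfId(id) == "decoy" ||
          famOfId(last) != famOfId(id)) {
        layout[[s]] <- c(layout[[s]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) layout[[scafIds[1L]]] <- c(layout[[scafIds[1L]]], id)
  }

  # --- gene models ------------------------------------------------------
  anno <- list(); exons <- list()
  for (s in scafIds) {
    cur <- 1000L
    for (gi in seq_along(layout[[s]])) {
      id <- layout[[s]][gi]
      fam <- famOfId(id)
      plen <- nchar(prot[[id]])
      if (fam %in% fams) {
        props <- famExonProps[[fam]]
        introns <- pmax(30L, round(famIntrons[[fam]] *
          (1 + stats::rnorm(length(famIntrons[[fam]]), 0,
                            config$intronJitter))))
      } else {
        props <- rep(1, sample(1:3, 1L))
        introns <- if (length(props) > 1L)
          round(stats::runif(length(props) - 1L, 100, 600)) else integer()
      }
      ex <- .layoutExons(plen, props, introns, cur)
      exons[[id]] <- ex
      anno[[id]] <- data.frame(
        protein_id = id, gene_id = paste0("g_", id), scaffold_id = s,
        strand = sample(c("+", "-"), 1L),
        start = ex[1L, "start"], end = ex[nrow(ex), "end"],
        gene_index = gi - 1L, stringsAsFactors = FALSE)
      cur <- ex[nrow(ex), "end"] + 1L +
        round(stats::runif(1L, 500, 1500))
    }
  }
  anno <- do.call(rbind, anno)
  rownames(anno) <- NULL
  models <- new("GeneModelSet", anno = anno, exons = exons)

  truth$scaffold_id <- scaffoldOf(models, truth$protein_id)
  truth$gene_index <- geneIndexOf(models, truth$protein_id)
  truth$tandem_array_id <- unname(arrayOf[truth$protein_id])
  truth$tandem_array_id[is.na(truth$tandem_array_id)] <- ""

  # --- signal-peptide annotation (flag only) ----------------------------
  planted <- truth$protein_id[truth$class == "planted"]
  hasSig <- stats::runif(length(planted)) < config$signalFraction
  signal <- data.frame(
    protein_id = truth$protein_id,
    present = truth$protein_id %in% planted[hasSig],
    stringsAsFactors = FALSE)
  signal$start <- ifelse(signal$present, 1L, NA_integer_)
  signal$end <- ifelse(signal$present, 20L, NA_integer_)
  truth$signal_peptide <- signal$present[match(truth$protein_id,
                                               signal$protein_id)]

  proteome <- Biostrings::AAStringSet(unlist(prot))
  S4Vectors::mcols(proteome)$description <- unlist(desc)

  panel <- do.call(rbind, panelRows)
  pan <- archetypePanel(
    name = panel$name, family = panel$family, accession = panel$accession,
    species = panel$species, sequence = panel$sequence,
    known_cys_count = panel$known_cys_count,
    synonyms = lapply(panel$family, function(f)
      c(f, paste0(f, "_arch"), paste("planted", f))))

  new("SimBundle", proteome = proteome, models = models, panel = pan,
      truth = truth, signal = signal, config = unclass(config))
}

#' Write a simulated bundle to disk
#'
#' Emits exactly the formats the pipeline consumes: \code{proteome.fasta},
#' \code{models.gff3}, \code{panel.tsv}, \code{signal.tsv},
#' \code{truth.tsv} under \code{dir}.
#'
#' @param bundle a [SimBundle-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeProteome(bundle@proteome, file.path(dir, "proteome.fasta"))
  writeGeneModels(bundle@models, file.path(dir, "models.gff3"))
  writePanel(bundle@panel, file.path(dir, "panel.tsv"))
  utils::write.table(bundle@signal, file.path(dir, "signal.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle@truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
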