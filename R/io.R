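# Readers and writers for the standard formats the pipeline touches:
# FASTA proteomes, GFF3 gene models, TSV archetype panels and annotation
# tables, and newick trees.  All genomic coordinates are 1-based
# inclusive (the GFF3 convention); exon order is stored in genomic
# (ascending) order regardless of strand because tandem-array detection
# works on genomic gene order.

#' Read a predicted proteome from FASTA
#'
#' The first whitespace-delimited token of each header is the record id,
#' the remainder its description.  Sequences are uppercased; duplicate
#' ids, empty sequences and letters outside the 20 canonical amino acids
#' plus X are rejected.
#'
#' @param path path to a protein FASTA file.
#' @return an \code{AAStringSet} named by id, with the descriptions in
#'   \code{mcols(x)$description}.
#' @seealso [writeProteome()]
#' @export
readProteome <- function(path) {
  if (!file.exists(path)) stop("no such FASTA file: ", path)
  x <- Biostrings::readAAStringSet(path)
  if (length(x) == 0L) stop("FASTA file contains no records: ", path)
  hdr <- names(x)
  ids <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (any(!nzchar(ids)))
    stop("FASTA record ", which(!nzchar(ids))[1L], " has an empty header")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated FASTA ids: ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(x))
  if (any(!nzchar(seqs)))
    stop("empty sequence for record: ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  bad <- !grepl(paste0("^[", paste(.AA21, collapse = ""), "]+$"), seqs)
  if (any(bad))
    stop("sequence with letters outside the canonical alphabet + X: ",
         paste(ids[bad], collapse = ", "))
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

#' Write a proteome to FASTA
#'
#' @param x an \code{AAStringSet}; descriptions in
#'   \code{mcols(x)$description} are appended to the headers.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProteome <- function(x, path) {
  desc <- S4Vectors::mcols(x)$description
  hdr <- names(x)
  if (!is.null(desc)) {
    has <- !is.na(desc) & nzchar(desc)
    hdr[has] <- paste(hdr[has], desc[has])
  }
  lines <- character(2L * length(x))
  lines[c(TRUE, FALSE)] <- paste0(">", hdr)
  lines[c(FALSE, TRUE)] <- as.character(x)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon features (1-based inclusive coordinates), groups
#' exons under their parent mRNA in ascending genomic order, and assigns
#' each mRNA a 0-based per-scaffold gene order index by ascending start
#' coordinate.  The mRNA ID is taken as the protein id.  Exons without a
#' parent mRNA and overlapping exons within one mRNA are format errors.
#'
#' @param path path to a GFF3 file.
#' @return a [GeneModelSet-class].
#' @export
readGeneModels <- function(path) {
  if (!file.exists(path)) stop("no such GFF3 file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  mrna <- gr[typ == "mRNA"]
  exon <- gr[typ == "exon"]
  if (length(mrna) == 0L) stop("GFF3 file contains no mRNA features: ", path)
  mid <- as.character(mrna$ID)
  if (anyDuplicated(mid)) stop("duplicated mRNA IDs in ", path)
  gene_id <- as.character(sapply(mrna$Parent, function(p)
    if (length(p)) p[[1L]] else NA_character_))
  parents <- sapply(exon$Parent, function(p)
    if (length(p)) p[[1L]] else NA_character_)
  if (anyNA(parents) || !all(parents %in% mid))
    stop("exon without a parent mRNA in ", path)
  exdf <- data.frame(parent = parents,
                     start = GenomicRanges::start(exon),
                     end = GenomicRanges::end(exon),
                     stringsAsFactors = FALSE)
  exons <- lapply(mid, function(id) {
    e <- exdf[exdf$parent == id, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1L && any(e$start[-1L] <= e$end[-nrow(e)]))
      stop("overlapping exons within mRNA ", id)
    cbind(start = e$start, end = e$end)
  })
  names(exons) <- mid
  anno <- data.frame(
    protein_id = mid, gene_id = gene_id,
    scaffold_id = as.character(GenomicRanges::seqnames(mrna)),
    strand = as.character(GenomicRanges::strand(mrna)),
    start = GenomicRanges::start(mrna),
    end = GenomicRanges::end(mrna),
    stringsAsFactors = FALSE)
  anno$gene_index <- stats::ave(anno$start, anno$scaffold_id,
                                FUN = function(s) rank(s, ties.method = "first") - 1L)
  anno$gene_index <- as.integer(anno$gene_index)
  new("GeneModelSet", anno = anno, exons = exons)
}

#' Write gene models to GFF3
#'
#' @param models a [GeneModelSet-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneModels <- function(models, path) {
  a <- models@anno
  a <- a[order(a$scaffold_id, a$start), , drop = FALSE]
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(a))) {
    ex <- models@exons[[a$protein_id[i]]]
    lines <- c(lines,
      sprintf("%s\thirumine\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              a$scaffold_id[i], a$start[i], a$end[i], a$strand[i],
              a$gene_id[i]),
      sprintf("%s\thirumine\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              a$scaffold_id[i], a$start[i], a$end[i], a$strand[i],
              a$protein_id[i], a$gene_id[i]),
      sprintf("%s\thirumine\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
              a$scaffold_id[i], ex[, "start"], ex[, "end"], a$strand[i],
              a$protein_id[i], seq_len(nrow(ex)), a$protein_id[i]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Exon and intron lengths of one gene model
#'
#' @param models a [GeneModelSet-class].
#' @param id protein id.
#' @return integer vector of exon lengths in genomic order.
#' @export
exonLengths <- function(models, id) {
  ex <- models@exons[[id]]
  if (is.null(ex)) stop("no gene model for ", id)
  as.integer(ex[, "end"] - ex[, "start"] + 1L)
}

#' @rdname exonLengths
#' @return for \code{intronLengths}, an integer vector of intron lengths
#'   (\code{start[k+1] - end[k] - 1}); empty for single-exon genes.
#' @export
intronLengths <- function(models, id) {
  ex <- models@exons[[id]]
  if (is.null(ex)) stop("no gene model for ", id)
  if (nrow(ex) < 2L) return(integer())
  as.integer(ex[-1L, "start"] - ex[-nrow(ex), "end"] - 1L)
}

#' Scaffold and gene-order lookup
#'
#' @param models a [GeneModelSet-class].
#' @param ids protein ids.
#' @return \code{scaffoldOf}: the scaffold id for each protein (NA when
#'   unknown); \code{geneIndexOf}: the 0-based per-scaffold gene order
#'   index.
#' @export
scaffoldOf <- function(models, ids) {
  a <- models@anno
  a$scaffold_id[match(ids, a$protein_id)]
}

#' @rdname scaffoldOf
#' @export
geneIndexOf <- function(models, ids) {
  a <- models@anno
  a$gene_index[match(ids, a$protein_id)]
}

#' Read an archetype panel from TSV
#'
#' The panel lists the previously characterised anticoagulants used as
#' search archetypes.  Expected tab-separated columns: \code{name},
#' \code{family}, \code{accession}, \code{species}, \code{sequence},
#' \code{known_cys_count}, \code{synonyms} (semicolon-separated, stored
#' lower-cased).  Unknown columns and empty family labels are format
#' errors.
#'
#' The panel template shipped under \code{inst/extdata} carries the
#' published accessions with empty sequence fields: the sequences are
#' fetched by the user from the named accessions and are deliberately not
#' vendored.  Read such a file with \code{requireSequences = FALSE}.
#'
#' @param path path to the TSV file.
#' @param requireSequences if \code{TRUE} (default), every entry must
#'   carry a sequence.
#' @return an [ArchetypePanel-class].
#' @export
readPanel <- function(path, requireSequences = TRUE) {
  if (!file.exists(path)) stop("no such panel file: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  need <- c("name", "family", "accession", "species", "sequence",
            "known_cys_count", "synonyms")
  extra <- setdiff(names(df), need)
  if (length(extra))
    stop("unknown panel columns: ", paste(extra, collapse = ", "))
  if (!all(need %in% names(df)))
    stop("missing panel columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (any(!nzchar(df$family)))
    stop("panel rows without a family label: ",
         paste(df$name[!nzchar(df$family)], collapse = ", "))
  df$sequence <- toupper(df$sequence)
  if (requireSequences && any(!nzchar(df$sequence)))
    stop("panel entries without a sequence: ",
         paste(df$name[!nzchar(df$sequence)], collapse = ", "),
         " (use requireSequences = FALSE for metadata-only panels)")
  df$known_cys_count <- suppressWarnings(as.integer(df$known_cys_count))
  df$synonyms <- lapply(strsplit(df$synonyms, ";", fixed = TRUE),
                        function(s) tolower(trimws(s[nzchar(trimws(s))])))
  new("ArchetypePanel", entries = df)
}

#' Build an archetype panel in code
#'
#' @param name,family,accession,species,sequence,known_cys_count,synonyms
#'   vectors of equal length; \code{synonyms} is a list of character
#'   vectors (lower-cased on construction).
#' @return an [ArchetypePanel-class].
#' @export
archetypePanel <- function(name, family, accession = rep("", length(name)),
                           species = rep("", length(name)), sequence,
                           known_cys_count = rep(NA_integer_, length(name)),
                           synonyms = as.list(family)) {
  df <- data.frame(name = name, family = family, accession = accession,
                   species = species, sequence = toupper(sequence),
                   known_cys_count = as.integer(known_cys_count),
                   stringsAsFactors = FALSE)
  df$synonyms <- lapply(synonyms, tolower)
  new("ArchetypePanel", entries = df)
}

#' Panel accessors
#'
#' @param panel an [ArchetypePanel-class].
#' @return \code{panelFamilies}: unique family labels;
#'   \code{familyMembers}: the entry names belonging to one family;
#'   \code{panelSequences}: an \code{AAStringSet} of the entries that
#'   carry sequences, named by entry name;
#'   \code{familySynonyms}: named list mapping each family to its pooled
#'   lower-cased synonyms (family label and member names included).
#' @export
panelFamilies <- function(panel) unique(panel@entries$family)

#' @rdname panelFamilies
#' @param family one family label.
#' @export
familyMembers <- function(panel, family) {
  e <- panel@entries
  e$name[e$family == family]
}

#' @rdname panelFamilies
#' @export
panelSequences <- function(panel) {
  e <- panel@entries
  e <- e[nzchar(e$sequence), , drop = FALSE]
  out <- Biostrings::AAStringSet(e$sequence)
  names(out) <- e$name
  S4Vectors::mcols(out)$family <- e$family
  out
}

#' @rdname panelFamilies
#' @export
familySynonyms <- function(panel) {
  e <- panel@entries
  fams <- unique(e$family)
  out <- lapply(fams, function(f) {
    i <- e$family == f
    unique(c(tolower(f), tolower(e$name[i]), unlist(e$synonyms[i])))
  })
  names(out) <- fams
  out
}

#' Write an archetype panel to TSV
#'
#' @param panel an [ArchetypePanel-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePanel <- function(panel, path) {
  e <- panel@entries
  e$synonyms <- vapply(e$synonyms, paste, "", collapse = ";")
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an unrooted tree from newick
#'
#' Trees are analysed unrooted throughout: a rooted newick input is
#' silently unrooted (the two root edges are merged, summing their
#' lengths).  Internal node labels are kept and interpreted as edge
#' support values (the label of the child node of each internal edge).
#'
#' @param path path to a newick file, or a literal newick string via
#'   \code{text}.
#' @param text optional newick string (overrides \code{path}).
#' @return an \pkg{ape} \code{phylo} object, unrooted.
#' @export
readNewickUnrooted <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path),
    error = function(e) stop("newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("newick parse error: ", conditionMessage(w)))
  if (is.null(tr)) {
    src <- if (!is.null(text)) text else readLines(path, warn = FALSE)
    src <- paste(src, collapse = "")
    op <- lengths(regmatches(src, gregexpr("(", src, fixed = TRUE)))
    cl <- lengths(regmatches(src, gregexpr(")", src, fixed = TRUE)))
    stop("newick parse error",
         if (op != cl) sprintf(": unbalanced parentheses (%d '(' vs %d ')', near position %d)",
                               op, cl, nchar(src)) else "")
  }
  if (ape::is.rooted(tr) && ape::Ntip(tr) > 2L)
    tr <- ape::unroot(tr)
  tr
}

#' Write a tree to newick
#'
#' Internal node labels (edge supports) and branch lengths are preserved.
#'
#' @param tree a \code{phylo}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNewickTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read signal-peptide annotations from TSV
#'
#' Signal peptides are consumed as externally computed annotations, never
#' predicted.  Columns: \code{protein_id}, \code{present} (TRUE/FALSE),
#' \code{start}, \code{end} (1-based, \code{start} must be 1 when
#' present).
#'
#' @param path path to the TSV file.
#' @return a \code{data.frame}.
#' @export
readSignalAnnotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "present", "start", "end")
  if (!all(need %in% names(df)))
    stop("missing signal-peptide columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$present <- as.logical(df$present)
  if (any(df$present & (is.na(df$start) | df$start != 1L)))
    stop("signal-peptide regions must start at position 1")
  if (any(!df$present & (!is.na(df$start) | !is.na(df$end))))
    stop("region given for a record marked absent")
  df
}
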