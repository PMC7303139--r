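#' Construct a scoring scheme
#'
#' Builds the default scoring scheme used everywhere in the package:
#' BLOSUM62 restricted to the 20 canonical amino acids plus X, affine gap
#' costs of 11/1 (a gap of length L costs \code{11 + L}), and the standard
#' gapped Karlin-Altschul constants for that combination,
#' \eqn{\lambda = 0.267} and \eqn{K = 0.041}.  X is treated as a neutral
#' ambiguity character and scores 0 against every letter, including
#' itself.
#'
#' Raw scores S are converted to bit scores as
#' \deqn{S' = (\lambda S - \ln K) / \ln 2}
#' and a bit score is converted to an E-value over a search space of a
#' query of length m against a database of total length n as
#' \deqn{E = m \, n \, 2^{-S'}.}
#' No composition-based statistics and no edge-effect length correction
#' are applied; m and n are raw sequence lengths.
#'
#' @param matrix substitution matrix; either the name of a matrix shipped
#'   with \pkg{Biostrings} (default \code{"BLOSUM62"}) or a symmetric
#'   numeric matrix whose dimnames cover the 21-letter alphabet.
#' @param gapOpen,gapExtend positive affine gap costs,
#'   \code{gapExtend <= gapOpen}.
#' @param lambda,K positive Karlin-Altschul parameters.
#' @param xNeutral if \code{TRUE} (default) the X row and column are set
#'   to 0.
#' @return a [ScoringScheme-class] object.
#' @examples
#' sc <- scoringScheme()
#' bitScore(100, sc)
#' @export
scoringScheme <- function(matrix = "BLOSUM62", gapOpen = 11, gapExtend = 1,
                          lambda = 0.267, K = 0.041, xNeutral = TRUE) {
  if (is.character(matrix)) {
    env <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = env)
    matrix <- get(matrix, envir = env)
  }
  if (!all(.AA21 %in% rownames(matrix)))
    stop("substitution matrix must cover the 20 canonical amino acids plus X")
  m <- matrix[.AA21, .AA21, drop = FALSE]
  storage.mode(m) <- "double"
  if (xNeutral) {
    m["X", ] <- 0
    m[, "X"] <- 0
  }
  new("ScoringScheme", matrix = m, gapOpen = as.numeric(gapOpen),
      gapExtend = as.numeric(gapExtend), lambda = as.numeric(lambda),
      K = as.numeric(K))
}

#' Convert a raw alignment score to a bit score
#'
#' @param rawScore non-negative raw score(s).
#' @param scheme a [ScoringScheme-class].
#' @return bit score(s), monotone increasing in \code{rawScore}.
#' @examples
#' bitScore(0, scoringScheme())   # (0 - ln 0.041) / ln 2
#' @export
bitScore <- function(rawScore, scheme) {
  stopifnot(is(scheme, "ScoringScheme"))
  if (any(rawScore < 0)) stop("rawScore must be non-negative")
  (scheme@lambda * rawScore - log(scheme@K)) / log(2)
}

#' E-value of a bit score over a given search space
#'
#' @param bits bit score(s).
#' @param m query length (positive integer).
#' @param n database length in residues (positive integer); for a
#'   database search this is the summed length of all database sequences.
#' @return expected number of chance hits of at least this score:
#'   \code{m * n * 2^-bits}.
#' @examples
#' expectValue(20, 1000, 1000)
#' @export
expectValue <- function(bits, m, n) {
  if (length(m) != 1L || length(n) != 1L || m <= 0 || n <= 0)
    stop("m and n must be single positive lengths")
  m * n * 2^(-bits)
}

# Encode an amino-acid string as 0-based indices into .AA21.
# Rejects empty sequences and any letter outside the alphabet.
.encodeAA <- function(x, what = "sequence") {
  if (is(x, "AAString") || is(x, "AAStringSet")) x <- as.character(x)
  if (length(x) != 1L || is.na(x) || !nzchar(x))
    stop(what, " must be a single non-empty amino-acid string")
  ch <- strsplit(toupper(x), "")[[1L]]
  idx <- match(ch, .AA21)
  if (anyNA(idx)) {
    bad <- unique(ch[is.na(idx)])
    stop(what, " contains letters outside the 20 canonical amino acids + X: ",
         paste(bad, collapse = ", "))
  }
  idx - 1L
}

# One sequence out of (character | named character | AAStringSet), with id.
.seqAndId <- function(x, default = "seq") {
  if (is(x, "AAStringSet")) {
    if (length(x) != 1L) stop("expected a single sequence")
    return(list(id = if (is.null(names(x))) default else names(x),
                seq = as.character(x)))
  }
  if (is(x, "AAString")) return(list(id = default, seq = as.character(x)))
  if (is.character(x) && length(x) == 1L) {
    id <- if (is.null(names(x)) || !nzchar(names(x))) default else names(x)
    return(list(id = id, seq = unname(x)))
  }
  stop("expected a single sequence (character, AAString or AAStringSet)")
}
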