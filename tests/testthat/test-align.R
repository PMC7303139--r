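# pairwise search: alignment scores, bit scores, E-values, ranked search

sc <- defaultScheme

test_that("self-alignment is maximal with 100% identity", {
  set.seed(1)
  for (r in 1:5) {
    s <- randomSeq(sample(10:40, 1), alphabet = LETTERS[c(1, 3, 4, 5, 7)])
    h <- smithWaterman(c(q = s), c(t = s), sc)
    expect_equal(h$pident, 100)
    chars <- strsplit(s, "")[[1L]]
    expect_equal(h$rawscore, sum(sc@matrix[cbind(chars, chars)]))
  }
})

test_that("alignment score is symmetric and bounded by self-scores", {
  set.seed(2)
  for (r in 1:10) {
    a <- randomSeq(sample(5:25, 1), alphabet = c("A", "C", "D", "E", "W"))
    b <- randomSeq(sample(5:25, 1), alphabet = c("A", "C", "D", "E", "W"))
    sab <- smithWaterman(c(q = a), c(t = b), sc)$rawscore
    expect_equal(sab, smithWaterman(c(q = b), c(t = a), sc)$rawscore)
    expect_lte(sab, min(smithWaterman(c(q = a), c(t = a), sc)$rawscore,
                        smithWaterman(c(q = b), c(t = b), sc)$rawscore))
  }
})

test_that("worked local alignment equals the enumeration oracle", {
  h <- smithWaterman(c(q = "HEAGAWGHEE"), c(t = "PAWHEAE"), sc)
  ora <- bruteLocalScore("HEAGAW", "PAWHEA", sc@matrix, sc@gapOpen,
                         sc@gapExtend)
  expect_equal(smithWaterman(c(q = "HEAGAW"), c(t = "PAWHEA"), sc)$rawscore,
               ora)
  # and against an independent implementation on the full strings
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString("HEAGAWGHEE"), Biostrings::AAString("PAWHEAE"),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "local")
  expect_equal(h$rawscore, Biostrings::score(pa))
})

test_that("local and global scores match Biostrings on random pairs", {
  set.seed(3)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]
  for (r in 1:15) {
    a <- randomSeq(sample(8:50, 1), aa)
    b <- randomSeq(sample(8:50, 1), aa)
    mine <- smithWaterman(c(q = a), c(t = b), sc)$rawscore
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      type = "local"))
    expect_equal(mine, max(ref, 0))
    gmine <- globalAlign(c(q = a), c(t = b), sc, type = "global")@score
    gref <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      type = "global"))
    expect_equal(gmine, gref)
  }
})

test_that("bit scores follow the closed form and are monotone", {
  expect_equal(bitScore(0, sc), -log(0.041) / log(2), tolerance = 1e-12)
  expect_equal(bitScore(100, sc), (26.7 - log(0.041)) / log(2),
               tolerance = 1e-12)
  raws <- seq(0, 200, by = 10)
  expect_true(all(diff(bitScore(raws, sc)) > 0))
  expect_error(bitScore(-1, sc), "non-negative")
})

test_that("E-values follow the closed form, scale with n, shift with bits", {
  expect_equal(expectValue(20, 1000, 1000), 1e6 * 2^-20)
  expect_equal(expectValue(30, 1000, 1000),
               expectValue(20, 1000, 1000) / 1024)
  expect_equal(expectValue(20, 1000, 2000), 2 * expectValue(20, 1000, 1000))
  expect_error(expectValue(20, 0, 10), "positive")
})

test_that("X scores zero against everything", {
  expect_true(all(sc@matrix["X", ] == 0))
  h <- smithWaterman(c(q = "AXAXA"), c(t = "AXAXA"), sc)
  expect_equal(h$rawscore, 3 * sc@matrix["A", "A"])
})

test_that("database search ranks by E-value and respects the cutoff", {
  set.seed(4)
  db <- Biostrings::AAStringSet(c(
    hit = "MKWVTFISLLLLFSSAYSRGVFRRDTHKSEIAHRFKDLGE",
    other = randomSeq(40, strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]),
    far = randomSeq(40, strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]])))
  q <- c(q = "MKWVTFISLLLLFSSAYSRGVFRRDTHKSEIAHRFKDLGE")
  hits <- searchProteins(q, db, sc, evalueCutoff = 1e-5)
  expect_equal(hits$sseqid[1L], "hit")
  expect_true(all(diff(hits$evalue) >= 0))
  # cutoff 0 always yields nothing: E > 0
  expect_equal(nrow(searchProteins(q, db, sc, evalueCutoff = 0)), 0L)
})

test_that("a planted homologue is the top hit in every seeded replicate", {
  set.seed(5)
  aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]
  for (r in 1:20) {
    fam <- makeFamily(1, length = 200, t = 0.1)
    db <- Biostrings::AAStringSet(c(
      stats::setNames(fam$copies, "planted"),
      stats::setNames(vapply(1:19, function(i) randomSeq(200, aa20), ""),
                      paste0("bg", 1:19))))
    hits <- searchProteins(c(q = fam$archetype$sequence), db, sc,
                           evalueCutoff = 10)
    expect_equal(hits$sseqid[1L], "planted")
  }
})

test_that("hit tables are written with the canonical 12 columns", {
  h <- smithWaterman(c(q = "HEAGAWGHEE"), c(t = "PAWHEAE"), sc)
  f <- tempfile(fileext = ".tsv")
  writeHitTable(h, f)
  got <- utils::read.delim(f)
  expect_identical(names(got),
                   c("qseqid", "sseqid", "pident", "length", "mismatch",
                     "gapopen", "qstart", "qend", "sstart", "send",
                     "evalue", "bitscore"))
})
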