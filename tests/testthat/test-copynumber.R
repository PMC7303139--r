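# copy-number calling, deduplication, tandem arrays, exon/intron sizes

sc <- defaultScheme

test_that("a family with no qualifying hits still counts its own query", {
  set.seed(21)
  aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]
  prot <- Biostrings::AAStringSet(c(
    q = randomSeq(150, aa20), x = randomSeq(150, aa20),
    y = randomSeq(150, aa20)))
  r <- suppressWarnings(countCopies("q", "fam", prot, sc))
  expect_equal(r$n_copies, 1L)
  expect_equal(r$copies, "q")
})

test_that("planted copies pass the three thresholds; raising any never adds copies", {
  set.seed(22)
  fam <- makeFamily(4, length = 250, t = 0.05)
  aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]
  prot <- Biostrings::AAStringSet(c(
    fam$copies,
    stats::setNames(vapply(1:6, function(i) randomSeq(250, aa20), ""),
                    paste0("d", 1:6))))
  r <- suppressWarnings(countCopies("s1", "fam", prot, sc))
  expect_setequal(r$copies, names(fam$copies))

  # monotonicity in each threshold
  n0 <- r$n_copies
  expect_lte(suppressWarnings(
    countCopies("s1", "fam", prot, sc, cutoff = 1e-40))$n_copies, n0)
  expect_lte(suppressWarnings(
    countCopies("s1", "fam", prot, sc, minCoverage = 0.99))$n_copies, n0)
  expect_lte(suppressWarnings(
    countCopies("s1", "fam", prot, sc, minSimilarity = 99))$n_copies, n0)
})

test_that("deduplication assigns shared hits to the higher-scoring family", {
  set.seed(23)
  arch <- simulateArchetype(200, 6)
  closeCopy <- evolveProtein(arch$sequence, 0.03, arch$cysPositions)$sequence
  farCopy <- evolveProtein(arch$sequence, 0.25, arch$cysPositions)$sequence
  prot <- Biostrings::AAStringSet(c(g = arch$sequence, p = farCopy,
                                    shared = closeCopy))
  rg <- suppressWarnings(countCopies("g", "guamerin_like", prot, sc))
  rp <- suppressWarnings(countCopies("p", "piguamerin_like", prot, sc))
  expect_true("shared" %in% rg$copies && "shared" %in% rp$copies)
  dd <- dedupeCopies(list(guamerin_like = rg, piguamerin_like = rp))
  gotG <- "shared" %in% dd$guamerin_like$copies
  gotP <- "shared" %in% dd$piguamerin_like$copies
  expect_true(xor(gotG, gotP))
  expect_true(gotG)  # close to g's query -> higher bit score there
  expect_equal(dd$piguamerin_like$assignments_dropped$winning_family,
               rep("guamerin_like",
                   nrow(dd$piguamerin_like$assignments_dropped)))
  # after dedup no protein is counted twice
  all_ids <- c(dd$guamerin_like$copies, dd$piguamerin_like$copies)
  expect_equal(anyDuplicated(all_ids), 0L)
})

test_that("dedupe is the identity on disjoint families and breaks exact ties lexicographically", {
  r1 <- structure(list(family = "a", query_id = "q1", copies = c("p1"),
                       n_copies = 1L, scaffolds = "s1",
                       hits = data.frame(sseqid = "p1", bitscore = 50,
                                         evalue = 1e-10),
                       assignments_dropped = data.frame()),
                  class = "CopyNumberResult")
  r2 <- structure(list(family = "b", query_id = "q2", copies = c("p2"),
                       n_copies = 1L, scaffolds = "s2",
                       hits = data.frame(sseqid = "p2", bitscore = 60,
                                         evalue = 1e-12),
                       assignments_dropped = data.frame()),
                  class = "CopyNumberResult")
  dd <- dedupeCopies(list(a = r1, b = r2))
  expect_equal(dd$a$copies, "p1")
  expect_equal(dd$b$copies, "p2")

  # same protein claimed by two families with identical scores
  r3 <- r1; r3$family <- "zeta"; r3$copies <- "p1"
  dd2 <- dedupeCopies(list(a = r1, zeta = r3))
  expect_equal(dd2$a$n_copies, 1L)      # "a" < "zeta"
  expect_equal(dd2$zeta$n_copies, 0L)
  expect_equal(dd2$zeta$assignments_dropped$winning_family, "a")
})

.modelsFromLayout <- function(layout) {
  # layout: list(scaffold = character vector of gene ids in order)
  anno <- list(); exons <- list()
  for (s in names(layout)) {
    cur <- 100L
    for (i in seq_along(layout[[s]])) {
      id <- layout[[s]][i]
      exons[[id]] <- cbind(start = cur, end = cur + 299L)
      anno[[id]] <- data.frame(protein_id = id, gene_id = paste0("g", id),
                               scaffold_id = s, strand = "+", start = cur,
                               end = cur + 299L, gene_index = i - 1L)
      cur <- cur + 1000L
    }
  }
  new("GeneModelSet", anno = do.call(rbind, anno), exons = exons)
}

test_that("tandem arrays are maximal runs of adjacent same-family copies", {
  res <- structure(list(family = "bdellin_like", query_id = "b1",
                        copies = c("b1", "b2", "b3"), n_copies = 3L,
                        scaffolds = "scafA",
                        hits = data.frame(),
                        assignments_dropped = data.frame()),
                   class = "CopyNumberResult")
  gm <- .modelsFromLayout(list(
    scafA = c("x1", "x2", "x3", "x4", "b1", "b2", "b3", "x5")))
  arr <- detectTandem(res, gm)
  expect_equal(nrow(arr), 1L)
  expect_equal(arr$length, 3L)
  expect_equal(arr$first_index, 4L)
  expect_equal(arr$members, "b1,b2,b3")

  # two copies on different scaffolds: no array
  gm2 <- .modelsFromLayout(list(scafA = c("b1"), scafB = c("b2", "x1"),
                                scafC = c("b3")))
  expect_equal(nrow(detectTandem(res, gm2)), 0L)
})

test_that("maxGap relaxes adjacency exactly as specified", {
  res <- structure(list(family = "f", query_id = "c1",
                        copies = c("c1", "c2"), n_copies = 2L,
                        scaffolds = "s", hits = data.frame(),
                        assignments_dropped = data.frame()),
                   class = "CopyNumberResult")
  # copies at gene indices 2 and 4
  gm <- .modelsFromLayout(list(s = c("x1", "x2", "c1", "x3", "c2")))
  expect_equal(nrow(detectTandem(res, gm, maxGap = 0L)), 0L)
  arr <- detectTandem(res, gm, maxGap = 1L)
  expect_equal(nrow(arr), 1L)
  expect_equal(arr$members, "c1,c2")

  # exhaustive check over random layouts against a direct scan
  set.seed(24)
  for (r in 1:20) {
    pos <- sort(sample(0:9, 4))
    ids <- paste0("c", 1:4)
    layout <- rep(paste0("x", 1:10), 1)
    layout[pos + 1L] <- ids
    gm3 <- .modelsFromLayout(list(s = layout))
    res4 <- res; res4$copies <- ids; res4$n_copies <- 4L
    for (mg in 0:2) {
      arr <- detectTandem(res4, gm3, maxGap = mg)
      # oracle: group positions whose successive differences <= mg + 1
      grp <- cumsum(c(1, diff(pos) > mg + 1))
      want <- table(grp)
      expect_equal(sort(arr$length), as.integer(sort(want[want >= 2])),
                   ignore_attr = TRUE)
    }
  }
})

test_that("exon/intron size conservation follows the positional formula", {
  gm <- new("GeneModelSet",
    anno = data.frame(protein_id = c("a", "b"), gene_id = c("ga", "gb"),
                      scaffold_id = "s", strand = "+",
                      start = c(1L, 5000L), end = c(800L, 6400L),
                      gene_index = 0:1),
    exons = list(a = cbind(start = c(1L, 301L), end = c(100L, 500L)),
                 b = cbind(start = c(5000L, 5300L),
                           end = c(5099L, 5699L))))
  # exons a: 100,200 ; exons b: 100,400 -> (1 + 0.5)/2 = 0.75 "mixed"
  ei <- exonIntronConservation(gm, c("a", "b"))
  expect_equal(ei$exon_conservation, 0.75)
  expect_equal(ei$exon_class, "mixed")
  # introns a: 200 ; b: 200 -> 1.0 strong
  expect_equal(ei$intron_conservation, 1.0)
  expect_equal(ei$intron_class, "strong")

  # identical structures are perfectly conserved
  ei2 <- exonIntronConservation(gm, c("a", "a"))
  expect_equal(ei2$exon_conservation, 1.0)
  expect_equal(ei2$exon_class, "strong")

  # fewer than two modeled copies: empty report
  expect_length(exonIntronConservation(gm, "a"), 0L)
})

test_that("intron jitter degrades intron conservation as the jitter model predicts", {
  # oracle: simulate the stated jitter process directly on the base
  # lengths (multiplicative 1 + N(0, sigma), floored at 30)
  oracle <- function(sigma, reps = 300) {
    set.seed(25)
    mean(replicate(reps, {
      base <- round(stats::runif(2, 200, 800))
      a <- pmax(30, round(base * (1 + stats::rnorm(2, 0, sigma))))
      b <- pmax(30, round(base * (1 + stats::rnorm(2, 0, sigma))))
      mean(1 - abs(a - b) / pmax(a, b))
    }))
  }
  classes <- character(); vals <- numeric()
  for (r in 1:25) {
    b <- plantGenome(simConfig(seed = 2500 + r, nFamilies = 1,
                               copiesPerFamily = 4, tandemFraction = 1,
                               intronJitter = 0.5, nDecoys = 0))
    ids <- b@truth$protein_id[b@truth$class == "planted"]
    ei <- exonIntronConservation(b@models, ids)
    classes <- c(classes, ei$intron_class)
    vals <- c(vals, ei$intron_conservation)
  }
  expect_false(any(classes == "strong"))
  expect_equal(mean(vals), oracle(0.5), tolerance = 0.12)
  # and low jitter keeps intron sizes strongly conserved
  b2 <- plantGenome(simConfig(seed = 2599, nFamilies = 1,
                              copiesPerFamily = 4, tandemFraction = 1,
                              intronJitter = 0.01, nDecoys = 0))
  ids2 <- b2@truth$protein_id[b2@truth$class == "planted"]
  expect_equal(exonIntronConservation(b2@models, ids2)$intron_class,
               "strong")
})
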