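# gene trees: distances, NJ, progressive MSA, bootstrap, clans

sc <- defaultScheme

test_that("Poisson distance follows the closed form with the 0.95 cap", {
  expect_equal(poissonDistance("ACDEFGHIKL", "ACDEFGHIKL", sc), 0)
  # 2 differences over 8 shared columns = 0.25
  a <- "ACDEFGHK"; b <- "ACDEFGWR"
  expect_equal(poissonDistance(a, b, sc), -log(0.75), tolerance = 1e-12)
  # saturated pairs are capped at -ln 0.05
  set.seed(41)
  x <- randomSeq(200, strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]])
  y <- randomSeq(200, strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]])
  expect_lte(poissonDistance(x, y, sc), -log(0.05) + 1e-12)
})

test_that("three-taxon NJ matches the closed-form branch lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(D)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2L]])
  expect_equal(unname(bl["A"]), (3 + 4 - 5) / 2)  # 1
  expect_equal(unname(bl["B"]), (3 + 5 - 4) / 2)  # 2
  expect_equal(unname(bl["C"]), (4 + 5 - 3) / 2)  # 3
})

test_that("NJ reconstructs additive matrices exactly and matches ape", {
  set.seed(42)
  for (n in c(5, 6, 8)) {
    am <- randomAdditiveMatrix(n)
    tr <- njTree(am$D)
    got <- ape::cophenetic.phylo(tr)[rownames(am$D), colnames(am$D)]
    expect_lt(max(abs(got - am$D)), 1e-9)
    # independent implementation agrees on the topology
    ref <- ape::nj(am$D)
    expect_equal(ape::dist.topo(tr, ref), 0, ignore_attr = TRUE)
  }
})

test_that("NJ topology is invariant under label-order permutations", {
  set.seed(43)
  am <- randomAdditiveMatrix(7)
  tr0 <- njTree(am$D)
  for (r in 1:5) {
    p <- sample(nrow(am$D))
    trp <- njTree(am$D[p, p])
    expect_equal(ape::dist.topo(tr0, trp), 0, ignore_attr = TRUE)
  }
  expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2,
                             dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric|3 taxa")
})

test_that("progressive MSA reduces to pairwise alignment for two sequences", {
  set.seed(44)
  fam <- makeFamily(2, length = 80, t = 0.1)
  msa <- progressiveMSA(fam$copies, sc)
  g <- globalAlign(fam$copies[1L], fam$copies[2L], sc)
  expect_equal(as.character(msa[[1L]]), g@rowA)
  expect_equal(as.character(msa[[2L]]), g@rowB)

  # identical triplet aligns gaplessly
  trip <- stats::setNames(rep(fam$archetype$sequence, 3), c("x", "y", "z"))
  m3 <- progressiveMSA(trip, sc)
  expect_false(any(grepl("-", as.character(m3))))
  # column count never below the longest input
  expect_gte(unique(Biostrings::width(m3)), 80L)
})

test_that("majority residue per MSA column recovers the ancestor at low divergence", {
  set.seed(45)
  fam <- makeFamily(6, length = 200, t = 0.05)
  msa <- progressiveMSA(fam$copies, sc)
  m <- do.call(rbind, strsplit(as.character(msa), ""))
  anc <- strsplit(fam$archetype$sequence, "")[[1L]]
  # columns where no row is gapped map 1:1 onto ancestral sites
  full <- colSums(m == "-") == 0
  maj <- apply(m[, full, drop = FALSE], 2L, function(col)
    names(sort(table(col), decreasing = TRUE))[1L])
  agree <- mean(maj == anc[seq_len(sum(full))])
  expect_gte(agree, 0.95)
})

test_that("clan enumeration matches graph-surgery brute force on random trees", {
  skip_if_not_installed("igraph")
  set.seed(46)
  for (r in 1:5) {
    n <- sample(5:8, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    want <- bruteClans(tr)
    cl <- treeClans(tr)
    got <- unique(lapply(cl$leaves, identity))
    keyify <- function(l) sort(vapply(l, paste, "", collapse = "|"))
    expect_identical(keyify(got), keyify(want))
    # binary unrooted n-leaf tree: 2n-3 edges, 2(2n-3) clans
    expect_equal(nrow(cl), 2L * (2L * n - 3L))
    # isClan agrees with membership for every subset of moderate size
    for (k in 1:6) {
      S <- sample(tr$tip.label, sample(seq_len(n - 1L), 1))
      inBrute <- any(vapply(want, function(w) setequal(w, S), logical(1L)))
      expect_equal(isClan(tr, S), inBrute)
    }
  }
})

test_that("singletons are clans; full set and empty set are rejected", {
  tr <- ape::rtree(6, rooted = FALSE)
  expect_true(isClan(tr, tr$tip.label[1L]))
  expect_error(isClan(tr, character()), "non-empty")
  expect_error(isClan(tr, tr$tip.label), "proper subset")
})

test_that("smallest clan equals the brute-force minimum over all clans", {
  skip_if_not_installed("igraph")
  set.seed(47)
  for (r in 1:5) {
    tr <- ape::rtree(10, rooted = FALSE)
    want <- bruteClans(tr)
    must <- sample(tr$tip.label, 2)
    cands <- Filter(function(w) all(must %in% w), want)
    res <- smallestClan(tr, must[1L], must[2L])
    if (length(cands) == 0L) {
      expect_true(res$trivial)
    } else {
      expect_equal(length(res$smallest_clan),
                   min(vapply(cands, length, 0L)))
      expect_true(all(must %in% res$smallest_clan))
    }
  }
})

test_that("clan calls read the defining edge support and the family labels", {
  tr <- readNewickUnrooted(
    text = "((A:1,B:1)97:1,(C:1,D:1)60:1,(E:1,F:1)80:1);")
  fams <- c(A = "hir", B = "hir", C = "ant", D = "ant",
            E = "egl", F = "egl")
  r <- smallestClan(tr, "A", "B", families = fams)
  expect_equal(r$support, 97)
  expect_equal(r$call, "orthologue_supported")
  expect_true(r$is_pair_clan)
  # low support: unsupported
  r2 <- smallestClan(tr, "C", "D", families = fams)
  expect_equal(r2$support, 60)
  expect_equal(r2$call, "orthologue_unsupported")
  # mixed families: not an orthologue (clan {A,B,C,D} via the E,F edge)
  r3 <- smallestClan(tr, "A", "C", families = fams)
  expect_setequal(r3$smallest_clan, c("A", "B", "C", "D"))
  expect_equal(r3$support, 80)
  expect_equal(r3$call, "not_orthologue")
  expect_false(r3$is_pair_clan)
})

test_that("adjacent groups are the clans meeting across the defining edge", {
  tr <- readNewickUnrooted(text = "((A,B),(C,D));")
  adj <- adjacentGroup(tr, c("A", "B"))
  keyify <- function(l) sort(vapply(l, paste, "", collapse = "|"))
  expect_identical(keyify(adj), keyify(list("C", "D")))

  # pendant leaf in a binary tree has exactly two adjacent groups, and
  # each union is again a clan
  set.seed(48)
  tr2 <- ape::rtree(7, rooted = FALSE)
  leaf <- tr2$tip.label[1L]
  adj2 <- adjacentGroup(tr2, leaf)
  expect_length(adj2, 2L)
  for (B in adj2) expect_true(isClan(tr2, c(leaf, B)))
  # a non-clan input is rejected
  nonclan <- tr2$tip.label[c(1L, 3L)]
  if (!isClan(tr2, nonclan))
    expect_error(adjacentGroup(tr2, nonclan), "not a clan")
})

test_that("bootstrap supports are seeded, bounded and binary at one replicate", {
  set.seed(49)
  f1 <- makeFamily(3, length = 150, t = 0.05, prefix = "a")
  f2 <- makeFamily(3, length = 150, t = 0.05, prefix = "b")
  seqs <- c(f1$copies, f2$copies)
  msa <- progressiveMSA(seqs, sc)
  t1 <- bootstrapSupport(msa, nReps = 40, seed = 7)
  t2 <- bootstrapSupport(msa, nReps = 40, seed = 7)
  expect_identical(t1$node.label, t2$node.label)
  sup <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  tOne <- bootstrapSupport(msa, nReps = 1, seed = 7)
  s1 <- suppressWarnings(as.numeric(tOne$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
  expect_error(bootstrapSupport(msa, nReps = 0), "at least 1")
})
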