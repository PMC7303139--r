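# orthology screen: forward hits, reciprocal filtering, candidacy calls

sc <- defaultScheme

.toyPanel <- function() {
  set.seed(11)
  fams <- list(alpha = makeFamily(2, length = 180, t = 0.08, prefix = "a"),
               beta = makeFamily(2, length = 180, t = 0.08, prefix = "b"))
  panel <- archetypePanel(
    name = c("alpha_arch", "beta_arch"),
    family = c("alpha", "beta"),
    sequence = c(fams$alpha$archetype$sequence,
                 fams$beta$archetype$sequence),
    synonyms = list(c("alpha", "alpha protein"), c("beta", "beta protein")))
  list(fams = fams, panel = panel)
}

test_that("forward screen finds planted members, ranks the best first", {
  tp <- .toyPanel()
  set.seed(12)
  aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]
  decoys <- stats::setNames(vapply(1:5, function(i) randomSeq(180, aa20), ""),
                            paste0("d", 1:5))
  prot <- Biostrings::AAStringSet(c(tp$fams$alpha$copies,
                                    tp$fams$beta$copies, decoys))
  fw <- forwardScreen(prot, tp$panel, sc)
  expect_setequal(names(fw), c("alpha", "beta"))
  expect_setequal(fw$alpha$protein_id, names(tp$fams$alpha$copies))
  expect_true(fw$alpha$top[1L])
  expect_true(all(diff(fw$alpha$evalue) >= 0))

  # decoy-only proteome: every family maps to an empty list
  fw0 <- forwardScreen(Biostrings::AAStringSet(decoys), tp$panel, sc)
  expect_true(all(vapply(fw0, nrow, 0L) == 0L))
})

test_that("a protein similar to two family members appears in both lists", {
  set.seed(13)
  arch <- simulateArchetype(150, 4)
  near <- evolveProtein(arch$sequence, 0.05, arch$cysPositions)$sequence
  panel <- archetypePanel(
    name = c("guamerin_like", "piguamerin_like"),
    family = c("antistasin-family", "antistasin-family2"),
    sequence = c(arch$sequence,
                 evolveProtein(arch$sequence, 0.03,
                               arch$cysPositions)$sequence))
  prot <- Biostrings::AAStringSet(c(p1 = near))
  fw <- forwardScreen(prot, panel, sc)
  expect_equal(fw[["antistasin-family"]]$protein_id, "p1")
  expect_equal(fw[["antistasin-family2"]]$protein_id, "p1")
})

test_that("reciprocal screen returns per-database best hits or no-hit markers", {
  tp <- .toyPanel()
  cand <- stats::setNames(tp$fams$alpha$copies[1L], "a1")
  swiss <- Biostrings::AAStringSet(c(
    alpha_ref = tp$fams$alpha$archetype$sequence,
    beta_ref = tp$fams$beta$archetype$sequence))
  S4Vectors::mcols(swiss)$description <- c("alpha protein", "beta protein")
  rec <- reciprocalScreen(cand, list(swiss = swiss), sc)
  expect_equal(rec$target, "alpha_ref")
  expect_equal(rec$description, "alpha protein")

  set.seed(14)
  far <- Biostrings::AAStringSet(c(x = randomSeq(60, c("A", "C", "D"))))
  rec2 <- reciprocalScreen(cand, list(tiny = far), sc, cutoff = 1e-20)
  expect_true(is.na(rec2$target))
  expect_equal(rec2$description, "no hit")

  expect_error(
    reciprocalScreen(cand, list(empty = Biostrings::AAStringSet()), sc),
    "'empty' is empty")
})

test_that("classification keeps family-consistent and hypothetical hits, rejects unrelated", {
  syn <- list(destabilase = c("destabilase", "lysozyme"),
              lefaxin = c("lefaxin"))
  # family-consistent reciprocal: candidate
  rec <- data.frame(db = "nr", target = "d1",
                    description = "Destabilase I", evalue = 1e-64,
                    bitscore = 200, stringsAsFactors = FALSE)
  d <- classifyOrthology("p", "destabilase", 2e-68, rec, syn)
  expect_equal(d$status, "candidate")

  # far superior unrelated reciprocal: rejected (the hemerythrin pattern)
  rec2 <- data.frame(db = "nr", target = "h1",
                     description = "Neurohemerythrin", evalue = 7e-82,
                     bitscore = 300, stringsAsFactors = FALSE)
  d2 <- classifyOrthology("p", "lefaxin", 3e-8, rec2, syn)
  expect_equal(d2$status, "rejected_unrelated")
  expect_match(d2$rejection_reason, "Neurohemerythrin")
  expect_match(d2$rejection_reason, "nr")

  # uninformative descriptions never reject
  rec3 <- data.frame(db = "nr", target = "h2",
                     description = "hypothetical protein", evalue = 1e-140,
                     bitscore = 400, stringsAsFactors = FALSE)
  d3 <- classifyOrthology("p", "lefaxin", 3e-8, rec3, syn)
  expect_equal(d3$status, "candidate")

  # within the 10x margin: not "clearly better", kept
  rec4 <- data.frame(db = "nr", target = "h3",
                     description = "Neurohemerythrin", evalue = 1e-8,
                     bitscore = 60, stringsAsFactors = FALSE)
  expect_equal(classifyOrthology("p", "lefaxin", 3e-8, rec4, syn)$status,
               "candidate")
})

test_that("improving the family-consistent evidence never flips candidate to rejected", {
  syn <- list(fam = c("fam protein"))
  unrelated <- data.frame(db = "nr", target = "u",
                          description = "other enzyme", evalue = 1e-30,
                          bitscore = 150, stringsAsFactors = FALSE)
  related <- data.frame(db = "sp", target = "f",
                        description = "fam protein", evalue = 1e-10,
                        bitscore = 80, stringsAsFactors = FALSE)
  base <- classifyOrthology("p", "fam", 1e-6,
                            rbind(unrelated, related), syn)$status
  for (e in 10^-(12:40)) {
    related$evalue <- e
    s <- classifyOrthology("p", "fam", 1e-6,
                           rbind(unrelated, related), syn)$status
    if (base == "candidate") expect_equal(s, "candidate")
    base <- s
  }
})

test_that("screenDecisions reports no_hit families and attaches signal peptides", {
  tp <- .toyPanel()
  prot <- Biostrings::AAStringSet(tp$fams$alpha$copies)
  dbs <- list(refs = local({
    x <- Biostrings::AAStringSet(c(alpha_ref = tp$fams$alpha$archetype$sequence))
    S4Vectors::mcols(x)$description <- "alpha protein"
    x
  }))
  sig <- data.frame(protein_id = names(prot),
                    present = c(TRUE, FALSE),
                    start = c(1L, NA), end = c(20L, NA))
  dec <- screenDecisions(prot, tp$panel, dbs, sc, signal = sig)
  expect_setequal(dec$family, c("alpha", "beta"))
  expect_equal(dec$status[dec$family == "alpha"], "candidate")
  expect_equal(dec$status[dec$family == "beta"], "no_hit")
  a <- dec[dec$family == "alpha", ]
  expect_true(a$signal_peptide %in% c("Yes (1-20)", "No"))
})
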