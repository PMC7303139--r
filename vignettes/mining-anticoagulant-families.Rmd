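---
title: "Mining anticoagulant gene families: models, thresholds and design notes"
author: "hirumine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining anticoagulant gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hirumine)
```

## The problem

Bloodfeeding leeches secrete dozens of salivary proteins that
antagonise hemostasis: direct thrombin inhibitors (hirudin and its
relatives), factor Xa inhibitors of the antistasin family (antistasin,
ghilanten, guamerin, piguamerin, bdellastasin), protease inhibitors
(bdellin, eglin C, the leech-derived tryptase inhibitor), lectins,
endoglucuronidases and more.  Given a newly annotated genome — a
predicted proteome plus gene models — the questions this package
answers are: *which known anticoagulant families are present*, *in how
many gene copies*, *are the copies arranged in tandem arrays*, and *is
each candidate a credible orthologue of the known protein rather than a
chance or paralogous match*?

The approach is deliberately the classical one: similarity search
against a panel of archetypal sequences, reciprocal-search filtering,
threshold-based copy calling, pairwise conservation reports, and a
corroborating phylogenetic test on unrooted gene trees.  Each stage is
exposed as ordinary R functions over Bioconductor containers
(`AAStringSet`, `phylo`), so the pipeline can be run whole
(`runAll()`) or stage by stage.

## Search model and statistics

The search engine is an affine-gap Smith–Waterman (Gotoh three-state
recurrences, implemented in C++) over BLOSUM62 restricted to the 20
canonical residues plus X.  Design choices:

* **Gap costs 11/1**, i.e. a gap of length $L$ costs $11 + L$; the
  familiar protein-search default.
* **X is neutral**: it scores 0 against everything, including itself.
  Any other ambiguity code (B, Z, J, ...) is rejected on input, because
  the scoring model is defined over the canonical alphabet.
* **Deterministic traceback** with tie order diagonal > up > left, so
  alignments are reproducible bit for bit across platforms.
* **Karlin–Altschul statistics** with fixed gapped constants
  $\lambda = 0.267$, $K = 0.041$ (the standard values for BLOSUM62
  11/1).  Raw score $S$ becomes $S' = (\lambda S - \ln K)/\ln 2$ bits
  and the E-value over a query of length $m$ against a database of
  total length $n$ is $E = m\,n\,2^{-S'}$.  No composition-based
  statistics and no edge-effect length correction are applied — $m$
  and $n$ are raw lengths.  This reproduces the familiar bit-score
  scale without re-estimating parameters, which is sufficient for the
  decisive quantities here (rankings and a $10^{-5}$ cutoff several
  orders of magnitude away from the noise floor), but E-values should
  not be expected to match a production search engine to the digit.

The screening cutoff is $E \le 10^{-5}$ throughout.

## The screening decision

The forward screen ranks, per family, the proteome members hitting any
panel archetype at the cutoff.  The top hit is then searched against
one or more reference databases ("reciprocal" search).  The decision
rule:

* a reciprocal best hit whose description matches a family synonym
  (case-insensitive substring over a curated synonym table) is
  *family-consistent* evidence;
* descriptions like "hypothetical protein", "uncharacterized protein"
  or "unnamed protein product" are *uninformative* and can never cause
  a rejection — an unannotated protein is not evidence of
  unrelatedness;
* the candidate is rejected only when an informative, non-matching hit
  is *clearly better* than the best family-consistent evidence (or
  than the forward hit, when no reciprocal hit is family-consistent).
  "Clearly better" requires an E-value at least 10× smaller.  The
  margin exists because float-level differences between E-values carry
  no biological signal; it is configurable.

"Related to the family" is operationalised by the synonym table; this
is a stated design decision, not something the screening literature
fixes precisely.  The margin and the uninformative list are the two
knobs a user may want to revisit for unusual reference databases.

## Copy number, deduplication, tandem arrays

A proteome member counts as a copy of a family when the family's top
hit aligns to it with $E \le 10^{-5}$, aligned span covering at least
50 % of the target, and at least 70 % similarity (identity plus
positive-scoring substitutions) over aligned columns.  Two documented
ambiguities and how they are resolved:

* "50 % of the target" is read as *aligned-span coverage of the
  target* (the standard coverage notion); a literal query/target
  length-ratio reading is available via
  `countCopies(..., coverageMode = "length_ratio")`.
* "similarity" is read as identities plus positives;
  `similarityMode = "identity"` switches to identity only.

Families with similar composition (the antistasin family especially)
can claim the same protein; `dedupeCopies()` assigns each protein to
the family whose query hits it with the highest bit score (ties: lower
E-value, then lexicographically first family), recording the losing
assignments.

Tandem arrays are maximal runs of same-family copies at consecutive
per-scaffold gene positions.  Gene order is genomic (ascending start
coordinate, strand ignored) because physical adjacency is what tandem
duplication produces.  `maxGap = 0` ("adjacent") is the default.
Exon and intron size conservation between copies is the mean over copy
pairs of positionally paired lengths scored $1 - |a-b|/\max(a,b)$
(unpaired positions score 0), classed strong ($\ge 0.9$), low
($< 0.6$) or mixed.  The class boundaries are package conventions for
turning qualitative labels into reproducible output.

## Conservation reports

Candidate and archetype are aligned semi-globally (free terminal gaps)
so that length differences appear as terminal overhangs, which
`trimTerminalGaps()` removes — mirroring the usual align-then-truncate
workflow.  Statistics are computed on the trimmed alignment only:

* identity and similarity percentages use **shared columns** (both
  rows hold a residue; gaps not counted) as denominator;
* cysteine conservation counts archetype cysteines whose column holds
  C in both rows — conserved cysteine scaffolds are the structural
  signature of many anticoagulant families (disulphide topology);
* internal gap runs are reported as indel spans; the longest
  homopolymer run of each sequence is reported because low-complexity
  runs flag dubious alignments.

Both identity and similarity are always printed: for near-identical
pairs the distinction is immaterial, for divergent pairs it is not,
and the reader should see both.  Signal-peptide regions are *not*
excluded from the statistics; signal-peptide annotations are consumed
from a TSV (their prediction is a separate, external concern).

## Gene trees and the clan test

The bundled tree builder is distance-based: Poisson-corrected
distances $d = -\ln(1-p)$ (with $p$ the mismatch fraction over shared
columns, capped at 0.95) and neighbor joining with a deterministic
lexicographic tie-break, so permuting the input order cannot change
the topology.  Negative NJ branch lengths are clamped to zero.
Maximum-likelihood inference is intentionally *not* re-implemented:
externally computed trees import via `readNewickUnrooted()` (rooted
inputs are silently unrooted; internal node labels are read as edge
supports), and the analysis that matters — the clan test — is
tree-agnostic.

Two numerical guards matter in practice:

* **Saturation**: distances are capped at $-\ln 0.05 \approx 3.0$.
* **Vanishing overlaps**: pairs sharing fewer than `minShared`
  (default 30) residue-residue columns get the capped distance.  A
  handful of chance matches over an 8-column overlap would otherwise
  fake a small distance and destabilise the tree; this guard makes
  all "unrelated" distances consistently maximal.

Bootstrap supports resample alignment columns with replacement,
rebuild the tree, and count the replicates containing each original
bipartition; supports attach to the internal node labels, the same
convention used on import.  Supports are fully seeded.

A *clan* is a leaf set separated from everything else by one edge —
the unrooted analogue of a monophyletic group; trees stay unrooted
because leech anticoagulants lack credible outgroups.  The orthology
test takes the smallest clan containing the candidate and its
archetype: a foreign-family leaf inside it vetoes orthology; otherwise
the call is *supported* when the defining edge's bootstrap support
reaches 75 % (a conventional cut for "well supported"), else
*unsupported*.  Leaves without a family label never veto — absence of
annotation is not evidence of non-orthology.  On multifurcating
imports the smallest clan can tie; ties prefer support-bearing clans,
then the lexicographically smallest leaf set.

## The synthetic-data generator

`plantGenome()` emulates exactly the structures the pipeline mines,
and nothing more:

* archetypes are uniform random sequences over the 19 non-cysteine
  residues with a planted cysteine scaffold;
* copies evolve under a 20-state Jukes–Cantor model — a site differs
  after time $t$ with probability $(19/20)(1 - e^{-20t/19})$ — with
  scaffold cysteines retained with probability `cysRetentionP`
  (default 1: frozen scaffold, the biologically typical case);
  indel events are Poisson(`indelRate`) with geometric lengths,
  interior positions, insertion/deletion equiprobable;
* a fraction of each family's copies is placed at consecutive gene
  positions on one scaffold (a tandem array); dispersed copies and
  decoys are laid out so that no same-family pair is accidentally
  adjacent, which keeps the truth table exact;
* intron lengths are family-fixed bases jittered per copy by a
  multiplicative $1 + \mathcal N(0, \sigma)$ factor (floored at 30
  nt); exon counts and proportions are family-fixed;
* decoys are independent random sequences — they model "no shared
  ancestry", not remote homology.

The defaults (6 families × 4 copies, 300-residue archetypes, 10
cysteines, divergence 0.1 substitutions/site, half of each family in a
tandem array, 30 decoys, 12 scaffolds) are the study conditions used
by the test suite and the acceptance script; they were chosen once as
a realistic desk-scale mirror of a small anticoagulant repertoire.

What the generator does **not** emulate — and hence what green tests
do not certify about real data: BLOSUM-structured substitution
preferences, domain architecture (repeats, shuffling), low-complexity
and compositional bias, remote homologues in the decoy set,
alternative splicing, and annotation errors in the gene models.
Uniform substitutions keep every expectation analytic, which is what
makes the calibration tests sharp; the price is that E-value tails on
real proteomes are harsher than on synthetic ones.

At CV = 0.5 intron jitter the conservation metric lands near its
class boundary ($\approx 0.5$–$0.6$), so individual simulated arrays
fall in "low" or occasionally "mixed"; the suite asserts the
distribution against a direct simulation of the jitter model rather
than a single class label.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run on one CPU in a few
minutes: proteomes of ~55 proteins, alignments up to ~350 residues,
trees of 6–10 leaves, 100–200 bootstrap replicates, 50-replicate
recovery experiments.  These sizes were picked so that every number
the package reports is recomputed from scratch on every run; the
pipeline itself has no scale ceiling beyond the $O(mn)$ alignment
cost.  All randomness flows from explicit seeds: the simulator and
the bootstrap save and restore the RNG state, and `runAll()` derives
per-stage seeds from the single top-level seed, so identical inputs
and configuration yield byte-identical reports.

## Known limitations

* E-values are desk-calibrated (fixed λ, K; raw lengths); use them for
  ranking and thresholding, not for cross-tool comparison.
* The reciprocal screen is only as good as the reference databases and
  the synonym table supplied.
* Progressive MSA (NJ guide order, profile–profile merges, free
  terminal gaps) is a stand-in adequate for within-family alignments;
  for publication-grade alignments and trees, import externally
  computed alignments/newick and run the clan test on those.
* The copy counter searches predicted proteins only; copies hiding in
  unannotated genomic sequence are invisible to it.
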