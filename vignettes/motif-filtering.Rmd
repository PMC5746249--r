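---
title: "Discovering short linear motif instances with an information-gain-optimized filtering protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif discovery and filtering methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Short linear motifs (SLiMs) are 3–10-residue peptide modules, usually in
intrinsically disordered regions, that are recognized by a globular
partner. `slimgate` implements a proteome-scale discovery protocol for such
motifs, developed around the dynein light chain LC8 (DYNLL) and its
TQT-class binding motif: an 8-residue window spanning positions −5..+2
around a central core glutamine. A position-specific scoring matrix (PSSM)
built from curated instances finds candidate windows, but the information
content of an 8-column matrix is low — on a whole proteome, true motifs are
buried under orders of magnitude more chance matches. The package's core
contribution is a principled way to build the *filtering* stage: binary
sequence-feature filters whose choice, cutoffs and order are selected by a
weighted information-gain criterion, followed by an ortholog-conservation
filter and integration of protein–protein interaction (PPI) evidence.

## The scoring model

For amino acid $i$ at motif position $j$, with occurrence count $A_{ij}$
over $m$ aligned training motifs, background frequency $D_i$, and a
pseudocount $B$ shared evenly across the 20 residues,

$$P_{ij} = \log_2 \frac{(A_{ij} + B/20)/(m + B)}{D_i}.$$

A window scores the sum of its eight per-position entries; the training
property that every curated motif scores positive against its own PSSM is
asserted by the test suite. Defaults: $B = 5$, base-2 logarithm (all scores
and the conservation cutoff are therefore in bits, and the base is recorded
in the object and its serialization, since a cutoff such as 3.3 is
meaningless without it). With $B = 0$ a zero count produces $-\infty$;
this is refused unless explicitly allowed. The shipped background is the
average UniProtKB/Swiss-Prot residue composition; any user FASTA can be
substituted, and we do not claim identity with any particular proteome
snapshot's composition.

Window classification is positional: the full ELM-style pattern requires
Pro at −5, Lys at −3 and Thr-Gln-Thr at −1..+1 (the `^` anchor of the
published regular expression is dropped deliberately — the windows are
internal 8-mers); the TQT core alone, the non-canonical TMT/TNT cores, and
everything else form the remaining classes, which partition all windows.

## Feature extraction

Predictor outputs are consumed as *data* (per-residue score tracks and
interval tracks in TSV form); no disorder, topology or domain predictor is
re-implemented or invoked. Per-window attributes are:

* **mean scores** — arithmetic mean over exactly the 8 window positions
  (whether the original protocol averaged a flanked window is not
  documented; 8 positions is the assumption here);
* **localization** — `INT` when the protein has no predicted signal
  peptide; otherwise the topology segment containing the window decides,
  with any overlap of a transmembrane segment resolved as `TM` (the
  conservative choice for an accessibility filter);
* **PFAM overlap** — true if at least one window residue lies inside an
  annotation interval of the requested type (adjacency is not overlap);
* **PSSM score** — the scan score, passed through.

All coordinates are 1-based inclusive. Windows whose protein lacks a
required track are dropped and reported, never silently imputed.

## Weighted information gain

Candidate sets are extremely imbalanced (tens of positives against
thousands of background windows), so every example of class $k$ carries
weight $1/N_k$: both classes contribute equal total weight and the
unfiltered parent has entropy $H_p = 1$ bit. For a binary split into a
retained child $c_1$ and a removed child $c_2$ with weighted fractions
$p_{c_1}, p_{c_2}$,

$$I = H_p - p_{c_1} H_{c_1} - p_{c_2} H_{c_2}.$$

Cutoffs for continuous attributes are optimized by exhaustive scan over the
midpoints of consecutive sorted distinct values — exact for the dataset and
fully reproducible, with ties broken toward more negatives removed, then
the smaller cutoff. Complementary predicates produce the same partition and
hence the same gain, so predicate polarity (and the category kept for a
categorical attribute) is decided by where the positives go: the retained
child is always the presumed-motif child.

The pipeline is a greedy decision list, not a full tree: at each step every
unused attribute is re-evaluated on the currently retained set, and only
the retained child is recursed on. When several attributes achieve a clean
split (no positive removed), the one removing the most negatives wins —
the information gain cannot distinguish among clean splits of very
imbalanced data, but the number of discarded background windows can.
Construction stops when the best gain drops below `epsilon` (default 1e-6
bits) or no negatives are removed; splits whose retained child would lose
the majority of positives are inadmissible. Because it is genuinely
ambiguous whether the original protocol ordered steps by gains on the
original parent set or on successively filtered sets, both modes are
implemented (`order = "global"` and the default `"greedy"`).

Generalization is measured by stratified k-fold cross-validation (default
k = 3): cutoffs are re-learned on the training folds and correctly
retained positives are summed over the held-out folds.

## Conservation filter

Candidate motifs are mapped through ortholog multiple sequence alignments
(inputs — no ortholog inference or aligning happens here) by locating the
eight alignment columns of the reference motif. Ortholog-private
insertions are ignored; an ortholog with a gap in any of the eight columns
counts as *non-conserved*, not as missing data (a deletion over the motif
is loss of the site; the policy is switchable). An aligned window is
conserved when its PSSM score strictly exceeds the cutoff (default 3.3
bits — the reference protocol's learned value, recorded as configuration).
Orthologs are grouped into five taxonomic levels (Mammalia, Vertebrata,
Metazoa, Fungi, Eukarya); a level with fewer than two orthologs is
unevaluable, and the reference sequence itself is excluded from the counts
(including it would inflate every fraction). The mammalian filter keeps a
motif conserved in at least 80% of mammalian orthologs; an unevaluable
Mammalia level fails by default (configurable, logged). Island-like
conservation (a SLiMPrints-style relative-conservation signal) is consumed
as externally computed significant regions; the flag is true when at least
3 of the 8 positions overlap a region with p < 0.05.

## Interaction evidence

MITAB 2.5 files are reduced to per-partner summaries by four fixed-order
deduplication rules (direct beats non-direct within a partner/study;
generic affinity-chromatography annotations yield to TAP/co-IP/pulldown;
unknown association types yield to fully annotated copies of the same
interaction from another database; PubMed-less records yield to the same
detection method in an identifiable study). Removals are disjointly
attributed in an audit table, and deduplication is idempotent. A study is
high-throughput when its largest per-source annotation count exceeds 50,
strictly. The grouping of detection-method identifiers into eight groups
is shipped as an editable YAML default — the composition used originally
is not published, so the map is configuration, not code. Records are keyed
by PubMed id; records lacking one form per-source singleton studies so the
later rules can act on them. A partner is classified low-throughput when
any supporting study is low-throughput, because low-throughput evidence is
the more reliable class.

## High-confidence set

A pipeline-surviving, mammalian-conserved candidate becomes
high-confidence when its protein has interaction-database support or its
island-conservation flag is set; the two support channels give the
Venn-style accounting `ppi_only / island_only / both`, which satisfies
inclusion–exclusion exactly. Each candidate window counts as its own
instance even when a protein hosts several.

## Synthetic study conditions

Everything is testable offline through seeded generators:

* **Curated table** — a labelled stand-in for the literature-curated
  collection (which is not redistributable). Its default composition
  mirrors the reference collection: 67 instances over 53 partners, 40
  human-mappable instances in 33 proteins, 13 full-pattern and 24
  additional TQT-core motifs (7/17 among human instances); the remaining
  30 instances split 20 non-canonical and 10 divergent cores, a realistic
  allocation that is our choice since only the first four class counts are
  published. Flanks are drawn from a synthetic preference profile (acidic
  −4, mild flank preferences, strong TQT core); the profile is *not* the
  published matrix.
* **Proteome** — i.i.d. sequences from the background composition,
  normally distributed lengths. The standard benchmark uses 220 proteins
  of mean length 500 (about 1.1e5 residues, so over 1e5 scanned windows)
  — large enough for a stable background, small enough that the whole
  benchmark runs in seconds.
* **Planted motifs** — 20 instances sampled from the PSSM's smoothed
  column frequencies into non-overlapping slots, re-sampled until the
  instance scores positive (the defining property of verified motifs).
* **Feature tracks** — class-conditional: disorder-like scores
  N(0.75, 0.12) on motif residues against N(0.40, 0.25) background
  (clamped to [0, 1]; the window mean tightens by √8), half the
  motif-free proteins get a signal peptide with EXT/TM/INT topology, 40%
  get a domain interval placed away from planted windows. The overlap
  between the disorder classes is intentional: with fully separated
  classes a single attribute filters everything and the learned protocol
  would degenerate to one step.
* **Ortholog alignments** — substitution-only (no indels), per-level
  rates with purifying selection on motif columns: flanks evolve fast
  (0.30/site already within mammals, emulating disordered-region
  turnover), motif columns slowly (0.02/site in mammals, drawn from the
  PSSM frequencies — tolerated substitutions), with constraint decaying
  toward Eukarya.

What passing the benchmark shows — and what it does not: the protocol
recovers ≥90% of planted motifs while retaining ≤1% of background windows
under these conditions, which demonstrates the machinery (scanning,
weighting, optimization, ordering, conservation counting) is correct and
self-consistent. It does not validate any real predictor's accuracy, the
published cutoffs (3.3 / 0.42), or performance on a real proteome; the
published paper-scale figures (85.53% localization pass rate, 34/40
cross-validation, 335→172 conservation reduction, 381 partners / 782
experiments, the 71 = 29 + 27 + 15 high-confidence set) depend on external
predictors, a 2017 proteome and database snapshots, and are documented as
reference behaviour only, not reproduced.

## Worked example

```{r example}
library(slimgate)

curated <- simulate_curated_motifs(seed = 1)
pssm <- build_pssm(curated$sequence)          # B = 5, log base 2
res <- evaluate_protocol_recovery(seed = 1)   # the standard benchmark
res$planted_retention
res$background_retention
res$pipeline
```

## Numerical choices and limitations

* Entropies and scores are base-2 throughout; changing `log_base` rescales
  cutoffs.
* Cutoff candidates are data midpoints, so learned cutoffs are
  reproducible but dataset-dependent to within one inter-datum gap.
* Windows containing non-standard residues (X, B, Z, U) are excluded from
  scans — the matrix has no columns for them; `score_window` can instead
  assign them a background-neutral zero contribution.
* The positive-score threshold is strict (`> 0`), as is the conservation
  cutoff and the >50 throughput boundary; the ≥80% mammalian threshold and
  the ≥2-ortholog minimum are inclusive.
* XLSX ingestion is not provided; curated tables are read from TSV.
* Negative windows are sampled uniformly without replacement from
  positive-scoring windows, excluding any window overlapping a true
  positive, under an explicit seed — the original sampling scheme is
  unpublished.
* The curated collection's non-redundant subset (produced originally with
  an unspecified identity threshold) is treated as an input; no redundancy
  reduction is performed here.
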