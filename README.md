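# slimgate

Proteome-scale discovery of short linear motif (SLiM) instances for a
motif-binding hub protein, built around the dynein light chain LC8 (DYNLL)
and its TQT-class binding motif.

Linear-motif interactions are mediated by ~8-residue peptides inside
intrinsically disordered regions. A position-specific scoring matrix (PSSM)
built from curated instances finds candidates, but chance matches outnumber
real motifs by orders of magnitude. `slimgate` implements the full
filtering protocol around the scan:

* **PSSM construction and scanning.** Pseudocount-smoothed log-odds,
  `P_ij = log2(((A_ij + B/20)/(m + B))/D_i)` with `B = 5` by default,
  positions −5..+2 around the central core glutamine; every overlapping
  8-mer of a proteome is scored, and windows are classified by core type
  (full ELM-style pattern, canonical TQT, non-canonical TMT/TNT, other).
* **Information-gain-optimized filtering.** Binary filters over
  sequence-derived features (intracellular localization, PFAM overlap,
  PSSM score, disorder score) are selected, cut and ordered by the weighted
  information gain `I = H_p − p_c1·H_c1 − p_c2·H_c2`, with per-class weight
  normalization for the extreme class imbalance; includes exhaustive
  midpoint cutoff optimization, greedy decision-list construction and
  k-fold cross-validation.
* **Ortholog conservation.** Candidates are mapped through ortholog
  alignments; a motif passes when its PSSM score exceeds the cutoff
  (default 3.3 bits) in at least 80% of mammalian orthologs (≥2 orthologs
  per level required).
* **Interaction evidence.** MITAB 2.5 records are deduplicated by four
  fixed-order rules, classified direct/non-direct and
  high/low-throughput (>50 annotations), and summarized per partner; the
  high-confidence set combines pipeline survivors with PPI or
  island-conservation support, with Venn accounting.
* **Synthetic fixtures.** Seeded generators for proteomes with planted
  motifs, class-conditional feature tracks, purifying-selection ortholog
  alignments, curated tables and MITAB files make every stage testable
  offline.

## Worked example

```r
library(slimgate)

curated <- simulate_curated_motifs(seed = 1)   # synthetic curated table
pssm <- build_pssm(curated$sequence)           # B = 5, log base 2
score_window(pssm, "RDGSTQTE")                 # one validated AMOTL2 motif
#> [1] 19.93642

res <- evaluate_protocol_recovery(seed = 1)    # standard benchmark
res$planted_retention                          # fraction of planted motifs kept
#> [1] 0.95
res$background_retention                       # background windows surviving
#> [1] 0
res$pipeline
#> filter pipeline (greedy order), 3 step(s):
#>   1. iupred >= 0.648512  (I = 0.9895)
#>   2. pfam_domain == FALSE  (I = 0.0095)
#>   3. pssm_score >= 3.37125  (I = 0.0043)
```

`evaluate_protocol_recovery()` plants 20 motif instances in a ~1.1e5-residue
background proteome, learns the filter pipeline on the labeled scan, applies
it, and runs the mammalian-conservation filter over simulated ortholog
alignments: the numbers above say 19 of the 20 planted motifs survived the
whole protocol and none of the 991 background feature windows did.

A thin CLI over the same functions ships at `inst/cli/slimgate.R`
(`build-pssm`, `scan`, `optimize`, `filter`, `conserve`, `ppi`,
`simulate`).

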