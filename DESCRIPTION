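Package: slimgate
Title: Discovery and Filtering of Short Linear Motif Instances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Proteome-scale discovery of short linear motif (SLiM) instances
    for a motif-binding hub protein, modelled on the dynein light chain LC8
    (DYNLL) TQT-class motif. Builds pseudocount-smoothed position-specific
    scoring matrices from curated motif collections, scans protein sequences,
    and filters candidate windows through an information-gain-optimized
    binary decision list over sequence-derived features (intrinsic disorder,
    subcellular localization, PFAM overlap, PSSM score). Ortholog alignments
    provide a mammalian-conservation filter, and PSI-MI TAB interaction
    evidence is deduplicated and summarized per partner to assemble a
    high-confidence motif set. Includes seeded synthetic-fixture generators
    (background proteomes with planted motifs, class-conditional feature
    tracks, purifying-selection ortholog alignments, MITAB files) so the
    entire protocol is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
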