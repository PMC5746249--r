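toy_alignment <- function() {
  # reference has an insertion-absorbing gap layout: orthologs o1..o3
  # REF: MKT-QTDAE (gap col 4) -> ungapped MKTQTDAE
  rows <- c(REF = "MKT-QTDAEVVV",
            o1  = "MKTAQTDAEVVV",   # insertion relative to reference
            o2  = "MKT-QTDAEVVV",   # identical
            o3  = "MKT-Q--AEVVV")   # deletion over the motif
  species <- c(REF = "Homo sapiens", o1 = "Mus musculus",
               o2 = "Rattus norvegicus", o3 = "Gallus gallus")
  ortholog_alignment(rows, "REF", species)
}

test_that("aligned windows are read off the reference columns", {
  aln <- toy_alignment()
  win <- map_aligned_window(aln, 1)  # ungapped reference 1..8 = MKTQTDAE
  expect_equal(unname(win["REF"]), "MKTQTDAE")
  # hand-read columns: o1 has the insertion column skipped
  expect_equal(unname(win["o1"]), "MKTQTDAE")
  expect_equal(unname(win["o2"]), "MKTQTDAE")
  expect_true(is.na(win["o3"]))  # gap inside the motif
  expect_error(map_aligned_window(aln, 6), "outside")
})

test_that("gapless alignments map windows at identical coordinates", {
  rows <- c(REF = "AAAATQTDEEAA", x = "AAAATQTDEEAA")
  aln <- ortholog_alignment(rows, "REF",
                            c(REF = "Homo sapiens", x = "Mus musculus"))
  win <- map_aligned_window(aln, 3)
  expect_equal(unname(win["x"]), substr("AAAATQTDEEAA", 3, 10))
})

test_that("conservation verdicts equal a direct score comparison", {
  curated <- simulate_curated_motifs(6)
  pssm <- build_pssm(curated$sequence)
  set.seed(44)
  wins <- c(curated$sequence[1:5], random_8mer(20))
  verdict <- window_conserved(wins, pssm, cutoff = 3.3)
  oracle <- vapply(wins, function(w) oracle_score(pssm, w) > 3.3,
                   logical(1))
  expect_equal(verdict, unname(oracle))
  # gapped windows are non-conserved by default, excluded on demand
  expect_false(window_conserved(NA_character_, pssm))
  expect_true(is.na(window_conserved(NA_character_, pssm,
                                     gapped = "exclude")))
  # boundary: strictly greater than the cutoff
  s <- score_window(pssm, wins[1])
  expect_true(window_conserved(wins[1], pssm, cutoff = s - 0.01))
  expect_false(window_conserved(wins[1], pssm, cutoff = s))
  expect_false(window_conserved(wins[1], pssm, cutoff = s + 0.01))
})

test_that("per-level fractions are counting-oracle exact", {
  curated <- simulate_curated_motifs(6)
  pssm <- build_pssm(curated$sequence)
  motif <- curated$sequence[1]
  flank <- function(w) paste0("AAAA", w, "AAAA")
  # 4 mammals: 3 carry the motif, 1 a scrambled window; 1 bird (below the
  # 2-ortholog minimum at Vertebrata)
  rows <- c(REF = flank(motif), m1 = flank(motif), m2 = flank(motif),
            m3 = flank(motif), m4 = flank("WWWWWWWW"),
            v1 = flank(motif))
  species <- c(REF = "Homo sapiens", m1 = "t1", m2 = "t2", m3 = "t3",
               m4 = "t4", v1 = "t5")
  taxonomy <- c("Homo sapiens" = "Mammalia", t1 = "Mammalia",
                t2 = "Mammalia", t3 = "Mammalia", t4 = "Mammalia",
                t5 = "Vertebrata")
  aln <- ortholog_alignment(rows, "REF", species)
  res <- conservation_by_level(aln, 5, pssm, cutoff = 3.3,
                               taxonomy = taxonomy)
  mam <- res$per_level[res$per_level$level == "Mammalia", ]
  expect_equal(mam$n_orthologs, 4L)  # reference excluded
  expect_equal(mam$n_conserved, 3L)
  expect_equal(mam$fraction, 0.75)
  vert <- res$per_level[res$per_level$level == "Vertebrata", ]
  expect_false(vert$evaluable)
  expect_true(is.na(vert$fraction))
  expect_error(conservation_by_level(aln, 5, pssm, taxonomy = taxonomy[-2]),
               "missing from taxonomy")
})

test_that("the mammalian filter is exact at its boundaries", {
  fake <- function(frac, n = 5L) {
    structure(list(start = 1L, cutoff = 3.3, per_level = data.frame(
      level = "Mammalia", n_orthologs = n,
      n_conserved = round(frac * n), fraction = frac,
      evaluable = n >= 2)), class = "conservation_result")
  }
  expect_true(mammalian_conservation_filter(fake(1.0)))
  expect_true(mammalian_conservation_filter(fake(0.8)))
  expect_false(mammalian_conservation_filter(fake(0.75)))
  one <- fake(NA_real_, n = 1L)
  expect_false(suppressMessages(mammalian_conservation_filter(one)))
  expect_true(suppressMessages(
    mammalian_conservation_filter(one, indeterminate = "pass")))
})

test_that("fractions respond monotonically to added orthologs", {
  curated <- simulate_curated_motifs(6)
  pssm <- build_pssm(curated$sequence)
  motif <- curated$sequence[2]
  flank <- function(w) paste0("GGGG", w, "GGGG")
  base_rows <- c(REF = flank(motif), a = flank(motif), b = flank(motif))
  sp <- function(ids) stats::setNames(paste0("tax_", ids), ids)
  taxonomy <- stats::setNames(rep("Mammalia", 5),
                              paste0("tax_", c("REF", "a", "b", "c", "d")))
  frac_of <- function(rows) {
    aln <- ortholog_alignment(rows, "REF", sp(names(rows)))
    res <- conservation_by_level(aln, 5, pssm, 3.3, taxonomy)
    res$per_level$fraction[res$per_level$level == "Mammalia"]
  }
  f0 <- frac_of(base_rows)
  f_plus <- frac_of(c(base_rows, c = flank(motif)))
  f_minus <- frac_of(c(base_rows, d = flank("WWWWWWWW")))
  expect_gte(f_plus, f0)
  expect_lte(f_minus, f0)
  # row order invariance
  expect_equal(frac_of(rev(base_rows)), f0)
})

test_that("island-like conservation needs three significant positions", {
  regions <- data.frame(start = c(10L, 50L), end = c(12L, 90L),
                        p = c(0.01, 0.2))
  # window 8..15 overlaps 10..12 (3 positions, significant) -> TRUE
  expect_true(island_conservation_flag(8, regions))
  # window 11..18 overlaps only 11..12 (2 positions) -> FALSE
  expect_false(island_conservation_flag(11, regions))
  # the p = 0.2 region never counts
  expect_false(island_conservation_flag(60, regions))
  expect_true(island_conservation_flag(60, transform(regions,
                                                     p = c(0.01, 0.04))))
})

test_that("alignment stores round-trip through FASTA + manifests", {
  dir <- tempfile()
  dir.create(dir)
  aln_seqs <- c(REF = "MKT-QTDAE", o1 = "MKTAQTDAE")
  writeLines(c(">REF", "MKT-QTDAE", ">o1", "MKTAQTDAE"),
             file.path(dir, "P1.fa"))
  utils::write.table(data.frame(accession = "P1", file = "P1.fa",
                                reference_id = "REF"),
                     file.path(dir, "alignments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sequence_id = c("REF", "o1"),
                                taxon = c("Homo sapiens", "Mus musculus")),
                     file.path(dir, "species.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  alns <- read_alignments(dir)
  expect_equal(unname(alns[["P1"]]$rows["o1"]), "MKTAQTDAE")
  tax_path <- file.path(dir, "tax.tsv")
  utils::write.table(data.frame(taxon = c("Homo sapiens", "Mus musculus"),
                                level = c("Mammalia", "Mammalia")),
                     tax_path, sep = "\t", quote = FALSE, row.names = FALSE)
  tax <- read_taxonomy(tax_path)
  expect_equal(unname(tax["Mus musculus"]), "Mammalia")
})
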