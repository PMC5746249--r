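test_that("mitab parsing matches a hand parse of the fixture", {
  path <- write_fixture_mitab()
  rec <- parse_mitab(path, BAIT)
  expect_equal(nrow(rec), 7L)
  expect_equal(rec$partner_accession[1], "Q00001")
  expect_equal(rec$detection_method_id[3], "MI:0004")
  expect_equal(rec$detection_group[3], "other_affinity")
  expect_equal(rec$detection_group[4], "pulldown")
  expect_equal(rec$association_type,
               c("direct", "non_direct", "non_direct", "non_direct",
                 "unknown", "non_direct", "direct"))
  expect_true(is.na(rec$pubmed_id[6]))
  expect_equal(rec$study[2], "pubmed:111")
  expect_match(rec$study[6], "^nopubmed:")
  expect_equal(rec$taxon[5], "10090")
})

test_that("lines with missing publication fields still parse", {
  line <- paste("uniprotkb:P63167", "uniprotkb:Q99999", "-", "-", "-", "-",
                'psi-mi:"MI:0018"(two hybrid)', "-", "-",
                "taxid:9606(human)", "taxid:9606(human)",
                'psi-mi:"MI:0915"(physical association)',
                'psi-mi:"MI:0000"(intact)', "-", "-", sep = "\t")
  path <- tempfile()
  writeLines(line, path)
  rec <- parse_mitab(path, "P63167")
  expect_equal(nrow(rec), 1L)
  expect_true(is.na(rec$pubmed_id))
  # malformed and non-bait lines are dropped with warnings
  writeLines(c(line, "too\tfew\tcolumns"), path)
  expect_warning(rec2 <- parse_mitab(path, "P63167"), "malformed")
  expect_equal(nrow(rec2), 1L)
  writeLines(line, path)
  expect_warning(parse_mitab(path, "P00000"), "no record matched")
})

test_that("deduplication applies the four rules like a hand curator", {
  path <- write_fixture_mitab()
  rec <- parse_mitab(path, BAIT)
  dedup <- deduplicate_evidence(rec)
  audit <- attr(dedup, "audit")
  # rule 1: Q00001/study 111 has direct + non-direct -> non-direct out
  expect_false(any(dedup$partner_accession == "Q00001" &
                     dedup$association_type == "non_direct"))
  expect_true(1L %in% audit$rule[audit$row == 2])
  # rule 2: Q00002/study 222 other-affinity out, pulldown kept
  expect_false(any(dedup$partner_accession == "Q00002" &
                     dedup$detection_group == "other_affinity"))
  expect_true(any(dedup$partner_accession == "Q00002" &
                    dedup$detection_group == "pulldown"))
  # rule 4: Q00003's pubmed-less coip duplicates an identifiable study
  expect_equal(sum(dedup$partner_accession == "Q00003"), 1L)
  expect_true(4L %in% audit$rule)
  # single-record partners are untouched
  expect_true("Q00004" %in% dedup$partner_accession)
})

test_that("rule 3 removes unknowns only when another source annotates", {
  rec <- data.frame(
    partner_accession = "Q1", bait_accession = BAIT,
    pubmed_id = "555", detection_method_id = "MI:0018",
    detection_method_name = "two hybrid", detection_group = "two_hybrid",
    association_type = c("unknown", "non_direct"),
    source_db = c("mint", "intact"), taxon = "9606",
    study = "pubmed:555", stringsAsFactors = FALSE)
  class(rec) <- c("evidence_records", "data.frame")
  out <- deduplicate_evidence(rec)
  expect_equal(out$association_type, "non_direct")
  expect_equal(attr(out, "audit")$rule, 3L)
  # same source: the unknown survives
  rec2 <- rec
  rec2$source_db <- "mint"
  out2 <- deduplicate_evidence(rec2)
  expect_equal(nrow(out2), 2L)
})

test_that("deduplication is idempotent and never invents records", {
  path <- write_fixture_mitab()
  rec <- parse_mitab(path, BAIT)
  once <- deduplicate_evidence(rec)
  twice <- deduplicate_evidence(once)
  expect_equal(as.data.frame(twice), as.data.frame(once),
               ignore_attr = TRUE)
  key <- function(x) paste(x$partner_accession, x$study,
                           x$detection_method_id, x$association_type)
  expect_true(all(key(once) %in% key(rec)))
  # removals are disjointly attributed to exactly one rule
  audit <- attr(once, "audit")
  expect_false(any(duplicated(audit$row)))
  expect_true(all(audit$rule %in% 1:4))
  expect_equal(nrow(once) + nrow(audit), nrow(rec))
})

test_that("study throughput turns high strictly above 50 annotations", {
  expect_equal(classify_study_scale(c(dbA = 3, dbB = 60)), "high")
  expect_equal(classify_study_scale(c(dbA = 50)), "low")
  expect_equal(classify_study_scale(c(dbA = 51)), "high")
  expect_warning(out <- classify_study_scale(numeric(0)), "unknown")
  expect_true(is.na(out))
})

test_that("partner summaries merge taxa, exclude accessions and count", {
  path <- write_fixture_mitab()
  dedup <- deduplicate_evidence(parse_mitab(path, BAIT))
  sums <- summarize_partners(dedup)
  expect_equal(sums$n_experiments[sums$partner_accession == "Q00001"], 1L)
  expect_true(sums$any_direct[sums$partner_accession == "Q00001"])
  expect_false(sums$any_direct[sums$partner_accession == "Q00002"])
  # merging mouse Q00003 into a human accession
  map <- data.frame(accession = "Q00003", canonical = "Q90003",
                    stringsAsFactors = FALSE)
  merged <- summarize_partners(dedup, merge_taxa = c("9606", "10090"),
                               ortholog_map = map)
  expect_true("Q90003" %in% merged$partner_accession)
  expect_false("Q00003" %in% merged$partner_accession)
  expect_error(summarize_partners(dedup, merge_taxa = "9606"),
               "ortholog")
  # exclusion drops the known non-motif binders
  excl <- summarize_partners(dedup, exclude = c("Q00004"))
  expect_false("Q00004" %in% excl$partner_accession)
  # order invariance
  rev_sums <- summarize_partners(dedup[rev(seq_len(nrow(dedup))), ])
  expect_equal(rev_sums, sums)
})

test_that("same-partner records in human and mouse merge additively", {
  rec <- data.frame(
    partner_accession = c("Qh", "Qm"), bait_accession = BAIT,
    pubmed_id = c("1", "2"), detection_method_id = "MI:0018",
    detection_method_name = "two hybrid", detection_group = "two_hybrid",
    association_type = "non_direct", source_db = "intact",
    taxon = c("9606", "10090"), study = c("pubmed:1", "pubmed:2"),
    stringsAsFactors = FALSE)
  class(rec) <- c("evidence_records", "data.frame")
  map <- data.frame(accession = "Qm", canonical = "Qh",
                    stringsAsFactors = FALSE)
  out <- summarize_partners(rec, merge_taxa = c("9606", "10090"),
                            ortholog_map = map)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_experiments, 2L)
})

test_that("partner throughput aggregates with low-throughput priority", {
  rec <- data.frame(
    partner_accession = "Q1", bait_accession = BAIT,
    pubmed_id = c("1", "2"), detection_method_id = c("MI:0018", "MI:0019"),
    detection_method_name = "x", detection_group = "two_hybrid",
    association_type = "non_direct", source_db = "intact", taxon = "9606",
    study = c("pubmed:1", "pubmed:2"), stringsAsFactors = FALSE)
  class(rec) <- c("evidence_records", "data.frame")
  scale <- c("pubmed:1" = "high", "pubmed:2" = "low")
  out <- summarize_partners(rec, study_scale = scale)
  expect_equal(out$throughput, "low")
  out2 <- summarize_partners(rec, study_scale = c("pubmed:1" = "high",
                                                  "pubmed:2" = "high"))
  expect_equal(out2$throughput, "high")
})
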