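# Shared fixtures and independent oracles for the test suite.

# Experimentally validated Hippo-pathway binding motifs (published table:
# gene, accession, 1-based start, 8-mer). A real curated-table instance.
table1_motifs <- function() {
  data.frame(
    accession = c("Q8IX03", "Q8IX03", "Q6AWC2", "Q6AWC2", "Q9ULE0",
                  "Q9ULE0", "Q4VCS5", "Q8IY63", "Q9Y2J4"),
    gene = c("WWC1", "WWC1", "WWC2", "WWC2", "WWC3", "WWC3", "AMOT",
             "AMOTL1", "AMOTL2"),
    taxon = "Homo sapiens",
    start = c(278L, 887L, 282L, 962L, 208L, 867L, 860L, 873L, 724L),
    sequence = c("LDVSSQTD", "VDKETNTE", "LDAGSQTS", "VDKETNTD",
                 "CDAGSQTD", "VDKETNTE", "RDCSTQTE", "KDSSTQTD",
                 "RDGSTQTE"),
    human_mappable = TRUE,
    evidence = "SPR-validated",
    stringsAsFactors = FALSE)
}

write_table1_tsv <- function(path = tempfile(fileext = ".tsv")) {
  utils::write.table(table1_motifs(), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# independent brute-force window scorer: per-position lookup and sum
oracle_score <- function(pssm, window) {
  chars <- strsplit(window, "")[[1]]
  total <- 0
  for (j in seq_along(chars)) total <- total + pssm$matrix[chars[j], j]
  total
}

# independent information-gain oracle: direct evaluation of
# I = Hp - p1*H1 - p2*H2 with weighted class proportions
oracle_entropy <- function(labels, weights) {
  q <- tapply(weights, labels, sum) / sum(weights)
  q <- q[!is.na(q) & q > 0]
  -sum(q * log2(q))
}
oracle_gain <- function(labels, weights, keep) {
  hp <- oracle_entropy(labels, weights)
  p1 <- sum(weights[keep]) / sum(weights)
  h1 <- if (any(keep)) oracle_entropy(labels[keep], weights[keep]) else 0
  h2 <- if (any(!keep)) oracle_entropy(labels[!keep], weights[!keep]) else 0
  hp - p1 * h1 - (1 - p1) * h2
}

# minimal labelled feature table built in code
toy_feature_table <- function(values, labels, attr_name = "x") {
  tab <- data.frame(accession = sprintf("P%03d", seq_along(values)),
                    start = 1L, sequence = "AAAAAAAA", label = labels,
                    stringsAsFactors = FALSE)
  tab[[attr_name]] <- values
  tab$weight <- numeric(nrow(tab))
  for (cl in unique(labels)) {
    tab$weight[labels == cl] <- 1 / sum(labels == cl)
  }
  class(tab) <- c("feature_table", "data.frame")
  tab
}

BAIT <- "P63167"

# ten-line toy MITAB evidence set exercising all four dedup rules
fixture_records <- function() {
  data.frame(
    partner = c("Q00001", "Q00001", "Q00002", "Q00002", "Q00003",
                "Q00003", "Q00004"),
    pubmed = c("111", "111", "222", "222", "333", NA, "444"),
    method_id = c("MI:0018", "MI:0018", "MI:0004", "MI:0096", "MI:0019",
                  "MI:0019", "MI:0065"),
    method_name = c("two hybrid", "two hybrid", "other affinity",
                    "pull down", "coip", "coip", "itc"),
    type_id = c("MI:0407", "MI:0915", "MI:0915", "MI:0915", NA,
                "MI:0915", "MI:0407"),
    type_name = c("direct interaction", "physical association",
                  "physical association", "physical association", NA,
                  "physical association", "direct interaction"),
    source = c("intact", "mint", "intact", "intact", "biogrid",
               "biogrid", "intact"),
    taxid = c("9606", "9606", "9606", "9606", "10090", "10090", "9606"),
    stringsAsFactors = FALSE)
}

write_fixture_mitab <- function() {
  path <- tempfile(fileext = ".tsv")
  write_mitab_fixture(path, BAIT, fixture_records())
  path
}

random_8mer <- function(n) {
  vapply(seq_len(n), function(i) {
    paste(sample(AA_ALPHABET_20, 8, replace = TRUE), collapse = "")
  }, character(1))
}
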