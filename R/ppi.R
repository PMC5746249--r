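# PSI-MI TAB (MITAB 2.5) interaction-evidence ingestion, deduplication and
# per-partner summaries. Files in, files out: no live PSICQUIC queries.

MITAB_COLS <- c("id_a", "id_b", "alt_a", "alt_b", "alias_a", "alias_b",
                "detection_method", "first_author", "publication",
                "taxid_a", "taxid_b", "interaction_type", "source_db",
                "interaction_id", "confidence")

# extract the first value with the given prefix from a pipe-separated
# MITAB field, e.g. mitab_field("uniprotkb:P63167|intact:EBI-1", "uniprotkb")
mitab_field <- function(x, prefix) {
  vapply(strsplit(x, "|", fixed = TRUE), function(parts) {
    hit <- grep(paste0("^", prefix, ":"), parts, value = TRUE)
    if (length(hit)) sub(paste0("^", prefix, ":"), "", hit[1]) else
      NA_character_
  }, character(1))
}

# 'psi-mi:"MI:0004"(affinity chromatography technology)' -> c(id, name)
parse_psimi <- function(x) {
  id <- sub('^.*(MI:[0-9]{4}).*$', "\\1", x)
  id[!grepl("MI:[0-9]{4}", x)] <- NA_character_
  name <- sub("^.*\\(([^)]*)\\).*$", "\\1", x)
  name[!grepl("\\(", x)] <- NA_character_
  list(id = id, name = name)
}

#' Default PSI-MI detection-method grouping
#'
#' Reads the shipped YAML mapping PSI-MI detection-method ids to the 8
#' groups used for evidence curation (`tap`, `coip`, `pulldown`,
#' `two_hybrid`, `pca`, `biophysical`, `other_affinity`, `other`). The map
#' is user-editable configuration: pass any YAML of the same shape to
#' [parse_mitab()].
#'
#' @param path Optional alternative YAML.
#' @return Named character vector MI id -> group.
#' @export
detection_groups <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "detection_groups.yaml",
                        package = "slimgate")
  }
  map <- yaml::read_yaml(path)
  out <- character(0)
  for (grp in names(map)) {
    ids <- unlist(map[[grp]])
    out[ids] <- grp
  }
  out
}

#' Default direct-interaction PSI-MI term set
#'
#' Interaction-type ids whose records are labelled `direct`; anything else
#' with an id is `non_direct`, records without an id are `unknown`.
#'
#' @return Character vector of MI ids ("direct interaction" subtree).
#' @export
direct_interaction_terms <- function() {
  c("MI:0407", "MI:0195")  # direct interaction, covalent binding
}

#' Parse a MITAB 2.5 file into evidence records
#'
#' Keeps rows where either interactor is the bait; the other interactor
#' becomes the partner. PSI-MI ids are extracted from the detection-method
#' and interaction-type fields; the association type is `direct` when the
#' interaction-type id is in `direct_terms`, `unknown` when absent, else
#' `non_direct`. Malformed lines are skipped with a line-numbered warning.
#'
#' @param path MITAB 2.5 TSV (no header, or a `#`-prefixed header line).
#' @param bait Bait accession (e.g. the hub protein).
#' @param groups Detection-method grouping map ([detection_groups()]).
#' @param direct_terms Direct-interaction id set
#'   ([direct_interaction_terms()]).
#' @return data.frame of class `"evidence_records"` with columns
#'   `partner_accession`, `bait_accession`, `pubmed_id`,
#'   `detection_method_id`, `detection_method_name`, `detection_group`,
#'   `association_type`, `source_db`, `taxon`, `study`.
#' @export
parse_mitab <- function(path, bait, groups = detection_groups(),
                        direct_terms = direct_interaction_terms()) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 13L) {
      warning("skipping malformed MITAB line ", i, " (",
              length(f), " column(s))")
      next
    }
    f <- c(f, rep("-", 15L - length(f)))
    a <- mitab_field(f[1], "uniprotkb")
    b <- mitab_field(f[2], "uniprotkb")
    if (is.na(a) || is.na(b)) {
      warning("skipping MITAB line ", i, ": no uniprotkb id")
      next
    }
    if (a != bait && b != bait) next
    partner <- if (a == bait) b else a
    det <- parse_psimi(f[7])
    ity <- parse_psimi(f[12])
    pubmed <- mitab_field(f[9], "pubmed")
    src <- parse_psimi(f[13])
    src_name <- ifelse(is.na(src$name), f[13], src$name)
    taxon <- sub("\\(.*$", "",
                 mitab_field(if (a == bait) f[11] else f[10], "taxid"))
    assoc <- if (is.na(ity$id)) "unknown" else
      if (ity$id %in% direct_terms) "direct" else "non_direct"
    grp <- if (!is.na(det$id) && det$id %in% names(groups))
      groups[[det$id]] else "other"
    rows[[length(rows) + 1L]] <- data.frame(
      partner_accession = partner, bait_accession = bait,
      pubmed_id = pubmed, detection_method_id = det$id,
      detection_method_name = det$name, detection_group = grp,
      association_type = assoc, source_db = src_name, taxon = taxon,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(partner_accession = character(),
               bait_accession = character(), pubmed_id = character(),
               detection_method_id = character(),
               detection_method_name = character(),
               detection_group = character(),
               association_type = character(), source_db = character(),
               taxon = character(), stringsAsFactors = FALSE)
  if (nrow(out) == 0L && length(lines) > 0L) {
    warning("no record matched bait ", bait)
  }
  # study key: pubmed id when present, else a per-source singleton study
  out$study <- character(nrow(out))
  has_pm <- !is.na(out$pubmed_id)
  out$study[has_pm] <- paste0("pubmed:", out$pubmed_id[has_pm])
  out$study[!has_pm] <- paste0("nopubmed:", out$source_db[!has_pm], ":",
                               which(!has_pm))
  rownames(out) <- NULL
  class(out) <- c("evidence_records", "data.frame")
  out
}

#' Deduplicate interaction evidence
#'
#' Applies, in fixed order, the four redundancy-removal rules:
#' \enumerate{
#'   \item Per partner and study, keep only direct interactions — unless
#'     the study has only non-direct ones for that partner.
#'   \item Drop the less informative `other_affinity` ("other affinity
#'     chromatography technology") records when the same partner/study also
#'     carries a TAP, CO-IP or pulldown record.
#'   \item Drop records with unknown association type when another source
#'     database reports the same interaction from the same study with full
#'     annotation.
#'   \item Drop records without a PubMed id when the partner carries the
#'     same detection method in an identifiable (PubMed-bearing) study.
#' }
#' Output order is input order among survivors. The `"audit"` attribute
#' names the rule that removed each filtered record, so removals are
#' disjointly attributable.
#'
#' @param records An `"evidence_records"` data.frame.
#' @return Deduplicated `"evidence_records"`, with attribute `audit`
#'   (data.frame: `row`, `rule`).
#' @export
deduplicate_evidence <- function(records) {
  n <- nrow(records)
  alive <- rep(TRUE, n)
  rule <- integer(n)
  key <- paste(records$partner_accession, records$study, sep = "\r")

  # rule 1: direct beats non-direct within (partner, study)
  for (k in unique(key)) {
    idx <- which(alive & key == k)
    assoc <- records$association_type[idx]
    if (any(assoc == "direct") && any(assoc == "non_direct")) {
      drop <- idx[assoc == "non_direct"]
      alive[drop] <- FALSE; rule[drop] <- 1L
    }
  }
  # rule 2: other_affinity redundant next to TAP/CO-IP/pulldown
  specific <- c("tap", "coip", "pulldown")
  for (k in unique(key)) {
    idx <- which(alive & key == k)
    grp <- records$detection_group[idx]
    if (any(grp %in% specific) && any(grp == "other_affinity")) {
      drop <- idx[grp == "other_affinity"]
      alive[drop] <- FALSE; rule[drop] <- 2L
    }
  }
  # rule 3: unknown association redundant when another db annotates the
  # same (partner, study) fully
  for (k in unique(key)) {
    idx <- which(alive & key == k)
    for (i in idx[records$association_type[idx] == "unknown"]) {
      annotated_elsewhere <- any(
        records$association_type[idx] != "unknown" &
          records$source_db[idx] != records$source_db[i])
      if (annotated_elsewhere) {
        alive[i] <- FALSE; rule[i] <- 3L
      }
    }
  }
  # rule 4: missing pubmed redundant when the partner has the same
  # detection method in an identifiable study
  for (i in which(alive & is.na(records$pubmed_id))) {
    same <- which(alive & !is.na(records$pubmed_id) &
                    records$partner_accession == records$partner_accession[i] &
                    !is.na(records$detection_method_id) &
                    records$detection_method_id ==
                      records$detection_method_id[i])
    if (length(same)) {
      alive[i] <- FALSE; rule[i] <- 4L
    }
  }
  out <- records[alive, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- data.frame(row = which(!alive),
                                   rule = rule[!alive])
  class(out) <- c("evidence_records", "data.frame")
  out
}

#' Classify the throughput of a study
#'
#' The annotation counts of the study's PubMed id are sorted by source and
#' only the highest taken; above 50 the study is high-throughput, otherwise
#' low-throughput.
#'
#' @param pubmed_annotation_counts Named numeric map source -> annotation
#'   count for one study.
#' @return `"high"` or `"low"`; NA (with a warning) for an empty map.
#' @export
classify_study_scale <- function(pubmed_annotation_counts) {
  if (length(pubmed_annotation_counts) == 0L) {
    warning("no annotation counts: study scale unknown")
    return(NA_character_)
  }
  if (max(pubmed_annotation_counts) > 50) "high" else "low"
}

#' Summarize deduplicated evidence per partner
#'
#' Partners from the taxa in `merge_taxa` are merged through the ortholog
#' accession map; excluded accessions are dropped. The number of
#' independent supporting experiments is the count of distinct
#' (study, detection method) pairs. A partner is low-throughput if any of
#' its supporting studies is low-throughput (low-throughput evidence
#' dominates, being the more reliable class).
#'
#' @param records Deduplicated `"evidence_records"`.
#' @param merge_taxa Character vector of taxon ids to merge (e.g.
#'   `c("9606", "10090", "10116")` for human/mouse/rat); requires
#'   `ortholog_map`.
#' @param ortholog_map data.frame (`accession`, `canonical`) mapping
#'   non-human accessions to the merged (human) accession.
#' @param exclude Accessions to omit (e.g. the bait's own isoforms and
#'   non-motif binders).
#' @param study_scale Optional named vector study -> `"high"`/`"low"` from
#'   [classify_study_scale()].
#' @return data.frame of class `"partner_summaries"`: `partner_accession`,
#'   `n_experiments`, `any_direct`, `throughput`.
#' @export
summarize_partners <- function(records, merge_taxa = NULL,
                               ortholog_map = NULL, exclude = character(),
                               study_scale = NULL) {
  rec <- as.data.frame(records)
  if (!is.null(merge_taxa)) {
    if (is.null(ortholog_map)) {
      stop("taxa merging requested but no ortholog accession map given")
    }
    in_merge <- rec$taxon %in% merge_taxa
    idx <- match(rec$partner_accession, ortholog_map$accession)
    mapped <- !is.na(idx) & in_merge
    rec$partner_accession[mapped] <- ortholog_map$canonical[idx[mapped]]
  }
  rec <- rec[!rec$partner_accession %in% exclude, , drop = FALSE]
  if (nrow(rec) == 0L) {
    out <- data.frame(partner_accession = character(),
                      n_experiments = integer(), any_direct = logical(),
                      throughput = character(), stringsAsFactors = FALSE)
    class(out) <- c("partner_summaries", "data.frame")
    return(out)
  }
  parts <- sort(unique(rec$partner_accession))
  out <- do.call(rbind, lapply(parts, function(p) {
    sub <- rec[rec$partner_accession == p, , drop = FALSE]
    evid <- unique(paste(sub$study, sub$detection_method_id, sep = "\r"))
    tp <- NA_character_
    if (!is.null(study_scale)) {
      scales <- study_scale[unique(sub$study)]
      scales <- scales[!is.na(scales)]
      if (length(scales)) {
        tp <- if (any(scales == "low")) "low" else "high"
      }
    }
    data.frame(partner_accession = p, n_experiments = length(evid),
               any_direct = any(sub$association_type == "direct"),
               throughput = tp, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("partner_summaries", "data.frame")
  out
}

#' Write partner summaries and the deduplication audit to TSV
#'
#' @param summaries A `"partner_summaries"` data.frame.
#' @param path Output TSV.
#' @param records Optional deduplicated records whose `audit` attribute is
#'   written alongside as `<path>.audit.tsv`.
#' @return `path`, invisibly.
#' @export
write_partner_summaries <- function(summaries, path, records = NULL) {
  utils::write.table(as.data.frame(summaries), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(records) && !is.null(attr(records, "audit"))) {
    utils::write.table(attr(records, "audit"),
                       paste0(path, ".audit.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
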