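# Curated motif table ingestion and motif-class labelling.

CURATED_COLUMNS <- c("accession", "gene", "taxon", "start", "sequence",
                     "human_mappable", "evidence")

#' Load a curated motif table
#'
#' Reads a table of experimentally verified 8-residue motif instances, one
#' row per instance, with columns `accession`, `gene`, `taxon`, `start`
#' (1-based position of the first residue in the full protein), `sequence`
#' (the 8-mer in the -5..+2 frame), `human_mappable` (logical: human or
#' directly mappable to a human protein), and `evidence` (free text). Rows
#' whose sequence is not a valid 8-mer over the 20-letter alphabet, or whose
#' start is not a positive integer, are rejected and reported in the
#' `"rejected"` attribute rather than silently dropped.
#'
#' @param path Path to a tab-separated file with a header row. XLSX input is
#'   not supported; export the sheet to TSV first.
#' @param format `"auto"` (by extension) or `"tsv"`.
#' @return data.frame of class `"curated_motifs"`, with attribute
#'   `rejected`: data.frame (`row`, `reason`) for refused rows.
#' @seealso [motif_counts()], [classify_core()]
#' @export
load_curated_motifs <- function(path, format = c("auto", "tsv")) {
  format <- match.arg(format)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    stop("XLSX input is not supported in this installation; export the ",
         "sheet as TSV with columns: ",
         paste(CURATED_COLUMNS, collapse = ", "))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  missing <- setdiff(CURATED_COLUMNS, names(tab))
  if (length(missing)) {
    stop("curated motif table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  tab <- tab[, CURATED_COLUMNS]
  if (nrow(tab) == 0L) {
    out <- data.frame(accession = character(), gene = character(),
                      taxon = character(), start = integer(),
                      sequence = character(), human_mappable = logical(),
                      evidence = character(), stringsAsFactors = FALSE)
    attr(out, "rejected") <- data.frame(row = integer(), reason = character())
    class(out) <- c("curated_motifs", "data.frame")
    return(out)
  }
  tab$sequence <- toupper(tab$sequence)
  start_num <- suppressWarnings(as.integer(tab$start))
  seq_ok <- validate_window(tab$sequence)
  start_ok <- !is.na(start_num) & start_num >= 1L
  reasons <- character(nrow(tab))
  reasons[!seq_ok] <- paste0("sequence '", tab$sequence[!seq_ok],
                             "' is not a valid 8-mer")
  reasons[seq_ok & !start_ok] <- paste0("start '", tab$start[seq_ok & !start_ok],
                                        "' is not a positive integer")
  keep <- seq_ok & start_ok
  rejected <- data.frame(row = which(!keep), reason = reasons[!keep],
                         stringsAsFactors = FALSE)
  out <- tab[keep, , drop = FALSE]
  out$start <- start_num[keep]
  out$human_mappable <- toupper(out$human_mappable) %in%
    c("TRUE", "T", "1", "YES")
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  class(out) <- c("curated_motifs", "data.frame")
  out
}

#' Write a curated motif table to TSV
#'
#' Inverse of [load_curated_motifs()].
#'
#' @param motifs A `"curated_motifs"` data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_curated_motifs <- function(motifs, path) {
  utils::write.table(as.data.frame(motifs)[, CURATED_COLUMNS], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summary counts of a curated motif set
#'
#' @param motifs A `"curated_motifs"` data.frame.
#' @return List with `n_instances`, `n_partners` (distinct accessions),
#'   `n_human_instances`, `n_human_proteins` (distinct accessions among
#'   human-mappable rows).
#' @export
motif_counts <- function(motifs) {
  hm <- motifs[motifs$human_mappable, , drop = FALSE]
  list(n_instances = nrow(motifs),
       n_partners = length(unique(motifs$accession)),
       n_human_instances = nrow(hm),
       n_human_proteins = length(unique(hm$accession)))
}

#' Classify the core of an 8-residue motif window
#'
#' Labels each window (in the -5..+2 frame, central position 0 at string
#' index 6) as one of:
#' \describe{
#'   \item{`elm_match`}{fits the ELM pattern for this motif class, applied
#'     positionally: Pro at -5, Lys at -3, and Thr-Gln-Thr at -1..+1.}
#'   \item{`tqt_core`}{carries the canonical TQT core at -1..+1 but not the
#'     full ELM pattern.}
#'   \item{`noncanonical_core`}{Thr at -1 and +1 with the central Gln
#'     replaced by Met or Asn (TMT / TNT cores).}
#'   \item{`other`}{anything else (e.g. SQT, TSP cores).}
#' }
#' Exactly one label applies per window.
#'
#' @param window Character vector of 8-mers.
#' @return Character vector of labels, same length as `window`.
#' @export
classify_core <- function(window) {
  window <- toupper(as.character(window))
  if (!all(validate_window(window, allow_nonstandard = TRUE))) {
    stop("every window must be an 8-mer")
  }
  at <- function(i) substring(window, i, i)
  core <- substring(window, 5, 7)
  elm <- at(1) == "P" & at(3) == "K" & core == "TQT"
  tqt <- core == "TQT" & !elm
  noncanon <- at(5) == "T" & at(7) == "T" & at(6) %in% c("M", "N")
  out <- rep("other", length(window))
  out[noncanon] <- "noncanonical_core"
  out[tqt] <- "tqt_core"
  out[elm] <- "elm_match"
  out
}

#' Tally motif-core classes in a curated set
#'
#' @param motifs A `"curated_motifs"` data.frame (or any data.frame with a
#'   `sequence` column).
#' @param human_only Restrict to human-mappable rows.
#' @return Named integer vector over the four [classify_core()] labels.
#' @export
core_class_counts <- function(motifs, human_only = FALSE) {
  if (human_only) motifs <- motifs[motifs$human_mappable, , drop = FALSE]
  cls <- classify_core(motifs$sequence)
  table(factor(cls, levels = c("elm_match", "tqt_core",
                               "noncanonical_core", "other")))
}
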