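# Combination of pipeline-surviving, conservation-passing candidates with
# interaction evidence and island-conservation flags into the
# high-confidence set, with Venn accounting and report output.

motif_id <- function(accession, start) paste0(accession, ":", start)

#' Assemble the high-confidence motif set
#'
#' A filtered, conservation-passing candidate is high-confidence iff its
#' protein appears among the interaction partners, or its island-like
#' conservation flag is true; either line of support (or both) is recorded
#' per motif. Candidates whose accession resolves to no partner and whose
#' flag is absent are simply not supported; accessions absent from
#' `island_flags` default to FALSE.
#'
#' @param candidates data.frame of filtered motifs (columns `accession`,
#'   `start`, `sequence`, `pssm_score`, optionally conservation columns).
#' @param partners A `"partner_summaries"` data.frame (or any data.frame
#'   with a `partner_accession` column).
#' @param island_flags Named logical vector keyed `accession:start` (or a
#'   data.frame with `accession`, `start`, `island` columns).
#' @return data.frame of class `"high_confidence_motifs"`: the supported
#'   candidates with `support_ppi`, `support_island`, `support` (comma
#'   string), and the partner's `n_experiments`/`any_direct` where
#'   applicable.
#' @export
combine_high_confidence <- function(candidates, partners, island_flags) {
  if (is.data.frame(island_flags)) {
    island_flags <- stats::setNames(
      as.logical(island_flags$island),
      motif_id(island_flags$accession, island_flags$start))
  }
  ids <- motif_id(candidates$accession, candidates$start)
  island <- island_flags[ids]
  island[is.na(island)] <- FALSE
  ppi <- candidates$accession %in% partners$partner_accession
  keep <- ppi | island
  out <- candidates[keep, , drop = FALSE]
  out$support_ppi <- ppi[keep]
  out$support_island <- as.logical(island[keep])
  out$support <- vapply(seq_len(nrow(out)), function(i) {
    paste(c(if (out$support_ppi[i]) "ppi",
            if (out$support_island[i]) "island_conservation"),
          collapse = ",")
  }, character(1))
  pm <- match(out$accession, partners$partner_accession)
  if ("n_experiments" %in% names(partners)) {
    out$n_experiments <- partners$n_experiments[pm]
    out$any_direct <- partners$any_direct[pm]
  }
  rownames(out) <- NULL
  class(out) <- c("high_confidence_motifs", "data.frame")
  out
}

#' Venn composition of the high-confidence set
#'
#' @param hc A `"high_confidence_motifs"` data.frame.
#' @return Named integer vector `ppi_only`, `island_only`, `both`, `total`;
#'   the three disjoint counts sum to the total.
#' @export
venn_counts <- function(hc) {
  both <- sum(hc$support_ppi & hc$support_island)
  ppi_only <- sum(hc$support_ppi & !hc$support_island)
  island_only <- sum(!hc$support_ppi & hc$support_island)
  c(ppi_only = ppi_only, island_only = island_only, both = both,
    total = ppi_only + island_only + both)
}

#' Write the high-confidence report
#'
#' Emits `high_confidence.tsv`, `summary.json` (Venn counts plus optional
#' pipeline accounting) and a minimal `high_confidence.html` table.
#'
#' @param hc A `"high_confidence_motifs"` data.frame.
#' @param dir Output directory (created if needed).
#' @param accounting Optional per-step accounting data.frame from
#'   [apply_pipeline()].
#' @return `dir`, invisibly.
#' @export
write_report <- function(hc, dir, accounting = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(hc),
                     file.path(dir, "high_confidence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary <- list(venn = as.list(venn_counts(hc)))
  if (!is.null(accounting)) summary$pipeline_accounting <- accounting
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  html <- c("<html><body><table border='1'>",
            paste0("<tr>", paste0("<th>", names(hc), "</th>",
                                  collapse = ""), "</tr>"),
            vapply(seq_len(nrow(hc)), function(i) {
              paste0("<tr>", paste0("<td>",
                                    vapply(hc[i, ], as.character,
                                           character(1)),
                                    "</td>", collapse = ""), "</tr>")
            }, character(1)),
            "</table></body></html>")
  writeLines(html, file.path(dir, "high_confidence.html"))
  invisible(dir)
}
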