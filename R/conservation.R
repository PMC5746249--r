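# Ortholog-alignment mapping of motif windows, PSSM-based conservation per
# taxonomic level, and the mammalian conservation filter. Alignments are
# inputs (aligned FASTA); no ortholog inference or alignment construction
# happens here.

#' The five taxonomic levels used for conservation analysis
#' @export
TAXONOMIC_LEVELS <- c("Mammalia", "Vertebrata", "Metazoa", "Fungi",
                      "Eukarya")

#' Construct an ortholog alignment object
#'
#' @param rows Named character vector (or [Biostrings::AAStringSet]) of
#'   aligned sequences of equal length; gap character `-`.
#' @param reference_id Name of the query (human) row; ungapping it must
#'   reproduce the protein sequence the motif coordinates refer to.
#' @param species Named character vector mapping row ids to taxa.
#' @return Object of class `"ortholog_alignment"`.
#' @export
ortholog_alignment <- function(rows, reference_id, species) {
  if (methods::is(rows, "AAStringSet")) {
    nm <- names(rows); rows <- as.character(rows); names(rows) <- nm
  }
  rows <- toupper(rows)
  if (length(unique(nchar(rows))) != 1L) {
    stop("aligned rows must all have the same length")
  }
  if (!reference_id %in% names(rows)) {
    stop("reference id '", reference_id, "' not among alignment rows")
  }
  missing <- setdiff(names(rows), names(species))
  if (length(missing)) {
    stop("no species assigned for row(s): ", paste(missing, collapse = ", "))
  }
  structure(list(rows = rows, reference_id = reference_id,
                 species = species[names(rows)]),
            class = "ortholog_alignment")
}

#' Extract the aligned instances of a reference motif
#'
#' Locates the 8 alignment columns covering the motif on the ungapped
#' reference and reads those columns for each row. Orthologs with a gap in
#' any of the 8 columns are flagged as gapped (NA). Insertions private to an
#' ortholog are ignored: only the reference-motif columns are read, keeping
#' the fixed 8-column PSSM frame.
#'
#' @param alignment An `"ortholog_alignment"`.
#' @param start 1-based motif start on the ungapped reference.
#' @return Named character vector of 8-mers (NA for gapped rows), reference
#'   row included.
#' @export
map_aligned_window <- function(alignment, start) {
  ref <- strsplit(alignment$rows[[alignment$reference_id]], "")[[1]]
  ungapped_cols <- which(ref != "-")
  if (start < 1L || start + MOTIF_WIDTH - 1L > length(ungapped_cols)) {
    stop(sprintf("motif %d..%d outside ungapped reference (length %d)",
                 start, start + MOTIF_WIDTH - 1L, length(ungapped_cols)))
  }
  cols <- ungapped_cols[start:(start + MOTIF_WIDTH - 1L)]
  vapply(alignment$rows, function(row) {
    ch <- strsplit(row, "")[[1]][cols]
    if (any(ch == "-")) NA_character_ else paste(ch, collapse = "")
  }, character(1))
}

#' Is an aligned ortholog window conserved?
#'
#' A window counts as conserved iff its PSSM score exceeds the cutoff
#' (strictly). Gapped windows (NA) are non-conserved by policy: a deletion
#' over the motif is treated as loss of the site, not as missing data.
#'
#' @param window 8-mer (or NA for a gapped row); vectorized.
#' @param pssm A `"pssm"`.
#' @param cutoff Score cutoff; default 3.3 (in the PSSM's log base, recorded
#'   on the object).
#' @param gapped `"nonconserved"` (default) counts gapped rows in the
#'   denominator as failures; `"exclude"` drops them from the counts.
#' @return Logical vector (NA only under `gapped = "exclude"`).
#' @export
window_conserved <- function(window, pssm, cutoff = 3.3,
                             gapped = c("nonconserved", "exclude")) {
  gapped <- match.arg(gapped)
  out <- rep(if (gapped == "nonconserved") FALSE else NA, length(window))
  ok <- !is.na(window) & validate_window(window)
  if (any(ok)) out[ok] <- score_window(pssm, window[ok]) > cutoff
  out
}

#' Read a taxonomy map (taxon -> level) from TSV
#'
#' Two columns `taxon` and `level`; levels must be among
#' [TAXONOMIC_LEVELS]. Each taxon is assigned its most specific level.
#'
#' @param path TSV path.
#' @return Named character vector.
#' @export
read_taxonomy <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("taxon", "level") %in% names(tab)))
  bad <- setdiff(unique(tab$level), TAXONOMIC_LEVELS)
  if (length(bad)) stop("unknown taxonomic level(s): ",
                        paste(bad, collapse = ", "))
  stats::setNames(tab$level, tab$taxon)
}

#' Per-level conservation of a motif across orthologs
#'
#' Each non-reference alignment row is assigned to its taxon's level; per
#' level the conserved fraction is reported. Levels with fewer than
#' `min_orthologs` rows are marked unevaluable (fraction NA). The reference
#' sequence itself is excluded from the counts.
#'
#' @param alignment An `"ortholog_alignment"`.
#' @param start Motif start on the ungapped reference.
#' @param pssm A `"pssm"`.
#' @param cutoff Conservation score cutoff (default 3.3).
#' @param taxonomy Named character vector taxon -> level (see
#'   [read_taxonomy()]); must cover every alignment taxon.
#' @param min_orthologs Minimum rows for a level to be evaluable
#'   (default 2).
#' @param gapped Gapped-window policy, see [window_conserved()].
#' @return Object of class `"conservation_result"`: list with `start`,
#'   `per_level` (data.frame: level, n_orthologs, n_conserved, fraction,
#'   evaluable) and `cutoff`.
#' @export
conservation_by_level <- function(alignment, start, pssm, cutoff = 3.3,
                                  taxonomy, min_orthologs = 2,
                                  gapped = "nonconserved") {
  windows <- map_aligned_window(alignment, start)
  orth <- setdiff(names(windows), alignment$reference_id)
  taxa <- alignment$species[orth]
  unmapped <- setdiff(unique(taxa), names(taxonomy))
  if (length(unmapped)) {
    stop("taxa missing from taxonomy map: ",
         paste(unmapped, collapse = ", "))
  }
  lev <- taxonomy[taxa]
  cons <- window_conserved(windows[orth], pssm, cutoff, gapped)
  per_level <- do.call(rbind, lapply(TAXONOMIC_LEVELS, function(L) {
    idx <- which(lev == L & !is.na(cons))
    n <- length(idx)
    k <- sum(cons[idx])
    data.frame(level = L, n_orthologs = n, n_conserved = k,
               fraction = if (n >= min_orthologs) k / n else NA_real_,
               evaluable = n >= min_orthologs, stringsAsFactors = FALSE)
  }))
  structure(list(start = start, per_level = per_level, cutoff = cutoff),
            class = "conservation_result")
}

#' Mammalian conservation filter
#'
#' A candidate motif passes iff it is conserved in at least `threshold`
#' (default 80%) of its mammalian orthologs. When Mammalia is unevaluable
#' (fewer than 2 orthologs) the verdict is indeterminate and resolved by
#' `indeterminate` (default `"fail"`).
#'
#' @param result A `"conservation_result"`.
#' @param threshold Minimal conserved fraction (default 0.8).
#' @param indeterminate `"fail"` or `"pass"` for unevaluable Mammalia.
#' @return Logical.
#' @export
mammalian_conservation_filter <- function(result, threshold = 0.8,
                                          indeterminate = c("fail",
                                                            "pass")) {
  indeterminate <- match.arg(indeterminate)
  mam <- result$per_level[result$per_level$level == "Mammalia", ]
  if (!mam$evaluable) {
    message("Mammalia unevaluable (", mam$n_orthologs,
            " ortholog(s)); verdict: ", indeterminate)
    return(indeterminate == "pass")
  }
  mam$fraction >= threshold
}

#' Island-like conservation flag
#'
#' Consumes externally computed relative-conservation significant regions
#' (SLiMPrints-style output) and applies the overlap rule: a motif shows
#' island-like conservation iff at least `min_overlap` of its 8 positions
#' fall inside a region with p-value below `alpha`.
#'
#' @param start Motif start (1-based).
#' @param regions data.frame with columns `start`, `end`, `p`.
#' @param min_overlap Minimal overlapping positions (default 3).
#' @param alpha Significance level (default 0.05).
#' @return Logical.
#' @export
island_conservation_flag <- function(start, regions, min_overlap = 3,
                                     alpha = 0.05) {
  sig <- regions[regions$p < alpha, , drop = FALSE]
  if (nrow(sig) == 0L) return(FALSE)
  sig$label <- ""
  length(window_interval_hits(sig, start)) >= min_overlap
}

#' Read ortholog alignments from a directory
#'
#' The manifest (TSV: `accession file reference_id`) names one aligned
#' FASTA per protein; a species map (TSV: `sequence_id taxon`) assigns taxa
#' to rows.
#'
#' @param dir Directory of aligned FASTA files.
#' @param manifest Manifest TSV within `dir`.
#' @param species_map Species TSV within `dir`.
#' @return Named list of `"ortholog_alignment"` objects keyed by accession.
#' @export
read_alignments <- function(dir, manifest = "alignments.tsv",
                            species_map = "species.tsv") {
  man <- utils::read.delim(file.path(dir, manifest),
                           stringsAsFactors = FALSE)
  sp <- utils::read.delim(file.path(dir, species_map),
                          stringsAsFactors = FALSE)
  species <- stats::setNames(sp$taxon, sp$sequence_id)
  out <- list()
  for (i in seq_len(nrow(man))) {
    aln <- Biostrings::readAAStringSet(file.path(dir, man$file[i]))
    out[[man$accession[i]]] <- ortholog_alignment(aln, man$reference_id[i],
                                                  species)
  }
  out
}

#' Tabulate conservation results for a set of motifs
#'
#' @param results Named list of `"conservation_result"` objects (names =
#'   `accession:start`).
#' @param threshold Mammalian filter threshold.
#' @return data.frame, one row per motif per level, plus the mammalian
#'   verdict.
#' @export
conservation_table <- function(results, threshold = 0.8) {
  rows <- lapply(names(results), function(id) {
    r <- results[[id]]
    df <- r$per_level
    df$motif <- id
    df$mammalian_pass <- mammalian_conservation_filter(r, threshold)
    df
  })
  out <- do.call(rbind, rows)
  out[, c("motif", "level", "n_orthologs", "n_conserved", "fraction",
          "evaluable", "mammalian_pass")]
}
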