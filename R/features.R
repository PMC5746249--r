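# Per-protein annotation tracks and per-window feature extraction.
# Tracks are predictor OUTPUTS consumed as data (IUPred-style per-residue
# scores, interval annotations for PFAM/signal peptide/topology); the
# predictors themselves are never invoked here.

#' Construct a per-residue score track
#'
#' @param accession Protein accession.
#' @param name Track name (e.g. `"iupred"`, `"anchor"`).
#' @param values Numeric vector, one value per residue of the protein.
#' @return Object of class `"annotation_track"` with kind
#'   `"per_residue_score"`.
#' @export
score_track <- function(accession, name, values) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  structure(list(accession = accession, kind = "per_residue_score",
                 name = name, values = as.numeric(values)),
            class = "annotation_track")
}

#' Construct an interval annotation track
#'
#' Intervals are 1-based inclusive; `label` carries the segment type (e.g.
#' a PFAM accession, or `"INT"`/`"TM"`/`"EXT"` for topology segments).
#'
#' @param accession Protein accession.
#' @param name Track name (e.g. `"pfam_domain"`, `"topology"`,
#'   `"signal_peptide"`).
#' @param intervals data.frame with columns `start`, `end`, `label`.
#' @param protein_length Optional length for validation.
#' @return Object of class `"annotation_track"` with kind `"interval"`.
#' @export
interval_track <- function(accession, name, intervals,
                           protein_length = NULL) {
  if (nrow(intervals)) {
    stopifnot(all(intervals$start >= 1L),
              all(intervals$start <= intervals$end))
    if (!is.null(protein_length) && any(intervals$end > protein_length)) {
      stop("interval beyond protein length in ", accession, "/", name)
    }
  }
  structure(list(accession = accession, kind = "interval", name = name,
                 intervals = intervals[, c("start", "end", "label")]),
            class = "annotation_track")
}

#' Average a per-residue track over an 8-residue window
#'
#' @param track A per-residue `"annotation_track"`.
#' @param start 1-based window start; the window covers
#'   `start..start+7`.
#' @return Arithmetic mean of the 8 per-residue values.
#' @export
average_track_over_window <- function(track, start) {
  stopifnot(inherits(track, "annotation_track"),
            track$kind == "per_residue_score")
  end <- start + MOTIF_WIDTH - 1L
  if (start < 1L || end > length(track$values)) {
    stop(sprintf("window %d..%d outside track %s/%s (length %d)",
                 start, end, track$accession, track$name,
                 length(track$values)))
  }
  mean(track$values[start:end])
}

# positions of window that fall inside any interval of the track
window_interval_hits <- function(intervals, start) {
  end <- start + MOTIF_WIDTH - 1L
  if (is.null(intervals) || nrow(intervals) == 0L) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(nrow(intervals))) {
    lo <- max(start, intervals$start[i])
    hi <- min(end, intervals$end[i])
    if (lo <= hi) hits <- c(hits, lo:hi)
  }
  sort(unique(hits))
}

#' Does a window overlap a PFAM annotation?
#'
#' True iff at least one of the 8 window residues lies inside at least one
#' interval of the track. One-position overlap suffices; adjacency does not
#' count.
#'
#' @param track An interval `"annotation_track"` (e.g. PFAM Domain-type or
#'   Family-type annotations; ship one track per type).
#' @param start 1-based window start.
#' @return Logical.
#' @export
pfam_overlap <- function(track, start) {
  stopifnot(inherits(track, "annotation_track"), track$kind == "interval")
  length(window_interval_hits(track$intervals, start)) > 0L
}

#' Subcellular localization category of a window
#'
#' Accessibility logic for a cytoplasmic binding partner: a window in a
#' protein with no predicted signal peptide is intracellular (`"INT"`).
#' For signal-peptide-bearing proteins the predicted transmembrane topology
#' decides: any overlap of the window with a TM segment gives `"TM"`,
#' otherwise the label (`"INT"`/`"EXT"`) of the topology segment containing
#' the window.
#'
#' @param signal_track Interval track of signal-peptide annotations, or
#'   NULL/empty when none predicted.
#' @param topology_track Interval track with labels in
#'   `c("INT", "TM", "EXT")`; required when a signal peptide is present.
#' @param start 1-based window start.
#' @return One of `"INT"`, `"TM"`, `"EXT"`.
#' @export
localization_category <- function(signal_track, topology_track, start) {
  has_signal <- !is.null(signal_track) &&
    nrow(signal_track$intervals) > 0L
  if (!has_signal) return("INT")
  if (is.null(topology_track) || topology_track$kind != "interval") {
    stop("signal peptide annotated but topology track missing for ",
         signal_track$accession)
  }
  iv <- topology_track$intervals
  tm <- iv[iv$label == "TM", , drop = FALSE]
  if (length(window_interval_hits(tm, start)) > 0L) return("TM")
  end <- start + MOTIF_WIDTH - 1L
  containing <- iv[iv$start <= start & iv$end >= end, , drop = FALSE]
  if (nrow(containing) == 0L) {
    # fall back to the segment holding the window start
    containing <- iv[iv$start <= start & iv$end >= start, , drop = FALSE]
  }
  if (nrow(containing) == 0L) {
    stop(sprintf("no topology segment covers window %d..%d of %s",
                 start, end, topology_track$accession))
  }
  containing$label[1]
}

#' Build an annotation store
#'
#' A track store is a two-level list `store[[track_name]][[accession]]`
#' holding `"annotation_track"` objects.
#'
#' @param tracks List of `"annotation_track"` objects.
#' @return Object of class `"track_store"`.
#' @export
track_store <- function(tracks = list()) {
  store <- list()
  for (tr in tracks) {
    stopifnot(inherits(tr, "annotation_track"))
    store[[tr$name]][[tr$accession]] <- tr
  }
  class(store) <- "track_store"
  store
}

get_track <- function(store, name, accession) {
  tr <- store[[name]][[accession]]
  tr
}

#' Read a track store from a directory of TSV files
#'
#' The manifest (YAML) maps attribute names to files and kinds:
#' ```
#' iupred:      {file: iupred.tsv,  kind: per_residue_score}
#' pfam_domain: {file: pfam.tsv,   kind: interval}
#' ```
#' Score files have columns `accession pos value`; interval files
#' `accession start end label`.
#'
#' @param dir Directory containing the TSVs and the manifest.
#' @param manifest Manifest filename within `dir`.
#' @return A `"track_store"`.
#' @export
read_track_store <- function(dir, manifest = "manifest.yaml") {
  man <- yaml::read_yaml(file.path(dir, manifest))
  tracks <- list()
  for (nm in names(man)) {
    tab <- utils::read.delim(file.path(dir, man[[nm]]$file),
                             stringsAsFactors = FALSE)
    if (identical(man[[nm]]$kind, "per_residue_score")) {
      for (acc in unique(tab$accession)) {
        sub <- tab[tab$accession == acc, ]
        sub <- sub[order(sub$pos), ]
        if (!identical(sub$pos, seq_len(nrow(sub)))) {
          if (any(sub$pos != seq_along(sub$pos))) {
            stop("track ", nm, "/", acc, " is not a dense 1..L series")
          }
        }
        tracks[[length(tracks) + 1L]] <- score_track(acc, nm, sub$value)
      }
    } else {
      for (acc in unique(tab$accession)) {
        sub <- tab[tab$accession == acc, c("start", "end", "label")]
        tracks[[length(tracks) + 1L]] <- interval_track(acc, nm, sub)
      }
    }
  }
  track_store(tracks)
}

#' Write a track store to a directory of TSVs plus manifest
#'
#' @param store A `"track_store"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_track_store <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- list()
  for (nm in names(store)) {
    kind <- store[[nm]][[1]]$kind
    rows <- list()
    for (tr in store[[nm]]) {
      if (kind == "per_residue_score") {
        rows[[length(rows) + 1L]] <- data.frame(
          accession = tr$accession, pos = seq_along(tr$values),
          value = tr$values, stringsAsFactors = FALSE)
      } else if (nrow(tr$intervals)) {
        rows[[length(rows) + 1L]] <- data.frame(
          accession = tr$accession, tr$intervals, stringsAsFactors = FALSE)
      }
    }
    file <- paste0(nm, ".tsv")
    tab <- do.call(rbind, rows)
    if (is.null(tab)) {
      tab <- if (kind == "per_residue_score") {
        data.frame(accession = character(), pos = integer(),
                   value = numeric())
      } else {
        data.frame(accession = character(), start = integer(),
                   end = integer(), label = character())
      }
    }
    utils::write.table(tab, file.path(dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    man[[nm]] <- list(file = file, kind = kind)
  }
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Declare the feature attributes a table should carry
#'
#' Each attribute is described by a kind:
#' \describe{
#'   \item{`mean_score`}{mean of a per-residue track over the window
#'     (`track` names the source).}
#'   \item{`localization`}{INT/TM/EXT category from `signal_peptide` +
#'     `topology` tracks.}
#'   \item{`overlap`}{logical overlap with an interval track.}
#'   \item{`pssm_score`}{the hit's own scan score, passed through.}
#' }
#'
#' @param ... Named lists, e.g.
#'   `iupred = list(kind = "mean_score", track = "iupred")`.
#' @return Named list of class `"attribute_spec"`.
#' @export
attribute_spec <- function(...) {
  spec <- list(...)
  stopifnot(length(spec) == 0L || !is.null(names(spec)))
  structure(spec, class = "attribute_spec")
}

#' Default attribute set of the filtering protocol
#'
#' Localization, PFAM Domain-type overlap, PSSM score, and IUPred-style
#' disorder mean — the four attributes retained by the reference protocol.
#'
#' @return An `"attribute_spec"`.
#' @export
default_attributes <- function() {
  attribute_spec(
    localization = list(kind = "localization"),
    pfam_domain = list(kind = "overlap", track = "pfam_domain"),
    pssm_score = list(kind = "pssm_score"),
    iupred = list(kind = "mean_score", track = "iupred"))
}

#' Assemble a labeled per-window feature table
#'
#' One row per hit with every requested attribute populated; hits whose
#' protein lacks a needed track are dropped and reported in the
#' `"dropped"` attribute. Class weights follow the per-class normalization
#' scheme: every example of class k carries weight `1/N_k`, so both classes
#' contribute equal total weight to entropy calculations regardless of the
#' positive/negative imbalance.
#'
#' @param hits A `"motif_hits"` data.frame (columns `accession`, `start`,
#'   `sequence`, `pssm_score`).
#' @param store A `"track_store"`.
#' @param labels Character vector (`"positive"`/`"negative"`/`"unlabeled"`),
#'   recycled if length 1.
#' @param attributes An [attribute_spec()]; default [default_attributes()].
#' @param weighting `"per_class"` (only scheme currently defined; recorded
#'   in the result).
#' @return data.frame of class `"feature_table"` with columns `accession`,
#'   `start`, `sequence`, `label`, `weight`, then one column per attribute;
#'   attributes `dropped` (data.frame) and `weighting`.
#' @export
assemble_feature_table <- function(hits, store, labels,
                                   attributes = default_attributes(),
                                   weighting = "per_class") {
  stopifnot(inherits(store, "track_store"), weighting == "per_class")
  labels <- rep_len(labels, nrow(hits))
  n <- nrow(hits)
  cols <- list()
  ok <- rep(TRUE, n)
  why <- character(n)
  for (nm in names(attributes)) {
    spec <- attributes[[nm]]
    vals <- vector(mode = if (spec$kind %in% c("mean_score", "pssm_score"))
      "numeric" else if (spec$kind == "overlap") "logical" else "character",
      length = n)
    for (i in seq_len(n)) {
      if (!ok[i]) next
      acc <- hits$accession[i]; st <- hits$start[i]
      res <- tryCatch(switch(spec$kind,
        mean_score = {
          tr <- get_track(store, spec$track, acc)
          if (is.null(tr)) stop("no ", spec$track, " track for ", acc)
          average_track_over_window(tr, st)
        },
        overlap = {
          tr <- get_track(store, spec$track, acc)
          if (is.null(tr)) tr <- interval_track(acc, spec$track,
            data.frame(start = integer(), end = integer(),
                       label = character()))
          pfam_overlap(tr, st)
        },
        localization = localization_category(
          get_track(store, "signal_peptide", acc),
          get_track(store, "topology", acc), st),
        pssm_score = hits$pssm_score[i],
        stop("unknown attribute kind: ", spec$kind)),
        error = function(e) e)
      if (inherits(res, "error")) {
        ok[i] <- FALSE
        why[i] <- conditionMessage(res)
      } else {
        vals[i] <- res
      }
    }
    cols[[nm]] <- vals
  }
  dropped <- data.frame(accession = hits$accession[!ok],
                        start = hits$start[!ok], reason = why[!ok],
                        stringsAsFactors = FALSE)
  out <- data.frame(accession = hits$accession, start = hits$start,
                    sequence = hits$sequence, label = labels,
                    stringsAsFactors = FALSE)
  for (nm in names(cols)) out[[nm]] <- cols[[nm]]
  out <- out[ok, , drop = FALSE]
  out$weight <- class_weights(out$label)
  out <- out[, c("accession", "start", "sequence", "label", "weight",
                 names(cols))]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "weighting") <- weighting
  class(out) <- c("feature_table", "data.frame")
  out
}

# per-class normalized weights: each labeled class sums to 1
class_weights <- function(labels) {
  w <- numeric(length(labels))
  for (cl in unique(labels)) {
    idx <- labels == cl
    w[idx] <- 1 / sum(idx)
  }
  w
}

#' Read / write a feature table as TSV
#'
#' Column types are recorded in a sidecar JSON schema so that logical and
#' categorical columns round-trip.
#'
#' @param table A `"feature_table"`.
#' @param path Output TSV path (schema written alongside as
#'   `<path>.schema.json`).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  types <- vapply(table, function(col) class(col)[1], character(1))
  jsonlite::write_json(as.list(types), paste0(path, ".schema.json"),
                       auto_unbox = TRUE)
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  schema_path <- paste0(path, ".schema.json")
  if (file.exists(schema_path)) {
    types <- jsonlite::read_json(schema_path, simplifyVector = TRUE)
    for (nm in names(types)) {
      if (!nm %in% names(tab)) next
      tab[[nm]] <- switch(types[[nm]],
                          logical = as.logical(tab[[nm]]),
                          integer = as.integer(tab[[nm]]),
                          numeric = as.numeric(tab[[nm]]),
                          tab[[nm]])
    }
  }
  class(tab) <- c("feature_table", "data.frame")
  tab
}
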