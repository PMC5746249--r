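# PSSM construction and scanning for 8-residue linear motif windows.
# Position convention: the window spans -5..+2 with the central residue
# (the Gln of the canonical TQT core) at position 0, i.e. string index 6.

#' The 20-letter amino-acid alphabet
#'
#' Standard one-letter codes in alphabetical order. All PSSM matrices in this
#' package are indexed by this alphabet.
#'
#' @export
AA_ALPHABET_20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Position labels of the 8-residue motif frame
#'
#' Labels -5..+2, centred on the canonical core glutamine at 0.
#'
#' @export
MOTIF_POSITIONS <- c("-5", "-4", "-3", "-2", "-1", "0", "+1", "+2")

MOTIF_WIDTH <- 8L

#' Construct a background amino-acid frequency model
#'
#' @param x One of: a named numeric vector of 20 relative frequencies (names
#'   from [AA_ALPHABET_20]; normalized internally), an
#'   [Biostrings::AAStringSet] whose residue composition is tallied, or the
#'   path to a FASTA file. With `x = NULL` the shipped default frequencies
#'   are returned (average eukaryotic protein composition as tabulated from
#'   UniProtKB/Swiss-Prot; see [default_background()]).
#' @return A named numeric vector of class `"background_frequencies"`:
#'   20 strictly positive probabilities summing to 1.
#' @export
background_frequencies <- function(x = NULL) {
  if (is.null(x)) return(default_background())
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      is.null(names(x))) {
    x <- Biostrings::readAAStringSet(x)
  }
  if (methods::is(x, "AAStringSet") || methods::is(x, "AAString")) {
    counts <- colSums(Biostrings::letterFrequency(
      Biostrings::AAStringSet(x), letters = AA_ALPHABET_20))
    x <- counts
  }
  if (!is.numeric(x) || is.null(names(x))) {
    stop("background must be a named numeric vector, an AAStringSet, ",
         "or a FASTA path")
  }
  missing <- setdiff(AA_ALPHABET_20, names(x))
  if (length(missing)) {
    stop("background is missing amino acids: ", paste(missing, collapse = ", "))
  }
  freq <- as.numeric(x[AA_ALPHABET_20])
  if (any(freq <= 0)) {
    stop("every background frequency must be > 0 (zero counts make ",
         "log-odds undefined); add counts or use the shipped default")
  }
  freq <- freq / sum(freq)
  names(freq) <- AA_ALPHABET_20
  structure(freq, class = "background_frequencies")
}

#' Default background amino-acid frequencies
#'
#' Average composition of UniProtKB/Swiss-Prot protein sequences. The source
#' study drew its background from the UniProt eukaryotic proteome, whose
#' exact table is not published; this default is documented, not claimed
#' identical, and any user FASTA can be substituted via
#' [background_frequencies()].
#'
#' @return A `"background_frequencies"` vector.
#' @export
default_background <- function() {
  f <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.72, F = 3.86, G = 7.07,
         H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
         P = 4.74, Q = 3.93, R = 5.53, S = 6.64, T = 5.35, V = 6.86,
         W = 1.10, Y = 2.92)
  background_frequencies(f)
}

validate_window <- function(window, allow_nonstandard = FALSE) {
  chars <- strsplit(toupper(window), "", fixed = TRUE)
  ok <- vapply(chars, function(ch) {
    length(ch) == MOTIF_WIDTH && (allow_nonstandard || all(ch %in% AA_ALPHABET_20))
  }, logical(1))
  ok
}

#' Build a position-specific scoring matrix from aligned 8-mers
#'
#' Log-odds of pseudocount-smoothed per-position residue frequencies against
#' a background model. For amino acid i at position j with occurrence count
#' A\[i,j\] over m motifs, the matrix entry is
#' `log(((A[i,j] + B/20) / (m + B)) / D[i])` in base `log_base`, where B is
#' the pseudocount (default 5) and D the background frequency. Per-column
#' Shannon entropies (in units of `log_base`) are computed from the smoothed
#' frequencies.
#'
#' @param motifs Character vector of 8-mers over the 20-letter alphabet.
#' @param background A `"background_frequencies"` vector (default: shipped
#'   Swiss-Prot composition).
#' @param pseudocount Non-negative pseudocount B shared across the 20
#'   residues (each cell receives B/20). Default 5.
#' @param log_base Base of the logarithm; 2 (bits) by default. Scores and
#'   downstream cutoffs are base-dependent, so the base is recorded in the
#'   object and its serialization.
#' @param allow_zero With `pseudocount = 0`, zero counts give -Inf entries;
#'   refused unless this flag is TRUE.
#' @return An object of class `"pssm"`: list with `matrix` (20 x 8 log-odds,
#'   rows [AA_ALPHABET_20], columns [MOTIF_POSITIONS]), `counts`,
#'   `n_sequences`, `pseudocount`, `log_base`, `background`,
#'   `column_entropy`.
#' @export
build_pssm <- function(motifs, background = default_background(),
                       pseudocount = 5, log_base = 2, allow_zero = FALSE) {
  motifs <- toupper(as.character(motifs))
  if (length(motifs) < 1L) stop("need at least one motif")
  if (!all(validate_window(motifs))) {
    bad <- motifs[!validate_window(motifs)]
    stop("invalid 8-mer(s): ", paste(bad, collapse = ", "))
  }
  if (!is.numeric(pseudocount) || pseudocount < 0) {
    stop("pseudocount must be >= 0")
  }
  background <- background_frequencies(background)
  m <- length(motifs)
  counts <- matrix(0L, nrow = 20L, ncol = MOTIF_WIDTH,
                   dimnames = list(AA_ALPHABET_20, MOTIF_POSITIONS))
  split_mat <- do.call(rbind, strsplit(motifs, "", fixed = TRUE))
  for (j in seq_len(MOTIF_WIDTH)) {
    tab <- table(factor(split_mat[, j], levels = AA_ALPHABET_20))
    counts[, j] <- as.integer(tab)
  }
  smooth <- (counts + pseudocount / 20) / (m + pseudocount)
  if (pseudocount == 0 && any(counts == 0) && !allow_zero) {
    stop("pseudocount 0 with zero counts yields -Inf entries; ",
         "set allow_zero = TRUE to permit")
  }
  mat <- log(smooth / as.numeric(background)) / log(log_base)
  col_entropy <- apply(smooth, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log(p) / log(log_base))
  })
  structure(list(matrix = mat, counts = counts, n_sequences = m,
                 pseudocount = pseudocount, log_base = log_base,
                 background = background, column_entropy = col_entropy),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM: %d x %d log-odds (base %g), m = %d motifs, B = %g\n",
              nrow(x$matrix), ncol(x$matrix), x$log_base, x$n_sequences,
              x$pseudocount))
  print(round(x$matrix, 2))
  cat("column entropy:", paste(round(x$column_entropy, 2), collapse = " "),
      "\n")
  invisible(x)
}

#' Smoothed per-position residue frequencies of a PSSM
#'
#' The pseudocount-corrected probabilities `(A + B/20)/(m + B)` underlying
#' the log-odds matrix; columns sum to 1. Used for sampling motif-like
#' 8-mers in the synthetic fixtures.
#'
#' @param pssm A `"pssm"` object.
#' @return 20 x 8 matrix of probabilities.
#' @export
pssm_frequencies <- function(pssm) {
  stopifnot(inherits(pssm, "pssm"))
  (pssm$counts + pssm$pseudocount / 20) /
    (pssm$n_sequences + pssm$pseudocount)
}

#' Score one 8-residue window against a PSSM
#'
#' Sum over the 8 positions of the matrix entry of the window residue at
#' that position.
#'
#' @param pssm A `"pssm"` object.
#' @param window Character vector of 8-mers (vectorized).
#' @param on_nonstandard Policy for windows containing non-standard residues
#'   (X, B, Z, U, ...): `"reject"` (default; error) or `"zero"` (those
#'   positions contribute a background-neutral 0).
#' @return Numeric vector of scores.
#' @export
score_window <- function(pssm, window, on_nonstandard = c("reject", "zero")) {
  stopifnot(inherits(pssm, "pssm"))
  on_nonstandard <- match.arg(on_nonstandard)
  window <- toupper(as.character(window))
  if (!all(nchar(window) == MOTIF_WIDTH)) {
    stop("every window must be exactly ", MOTIF_WIDTH, " residues")
  }
  chars <- do.call(rbind, strsplit(window, "", fixed = TRUE))
  idx <- match(chars, AA_ALPHABET_20)
  if (anyNA(idx)) {
    if (on_nonstandard == "reject") {
      stop("non-standard residue(s) in window(s): ",
           paste(unique(window[apply(is.na(matrix(idx, ncol = MOTIF_WIDTH)),
                                     1, any)]), collapse = ", "))
    }
  }
  idx_mat <- matrix(idx, ncol = MOTIF_WIDTH)
  scores <- numeric(length(window))
  for (j in seq_len(MOTIF_WIDTH)) {
    contrib <- ifelse(is.na(idx_mat[, j]), 0, pssm$matrix[cbind(
      ifelse(is.na(idx_mat[, j]), 1L, idx_mat[, j]), j)])
    scores <- scores + contrib
  }
  scores
}

# Score all overlapping windows of one sequence; returns numeric vector of
# length max(0, L - 7) with NA where the window contains a non-standard
# residue. Vectorized over positions.
score_all_windows <- function(pssm, sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- length(chars)
  n_win <- L - MOTIF_WIDTH + 1L
  if (n_win < 1L) return(numeric(0))
  idx <- match(chars, AA_ALPHABET_20)
  scores <- numeric(n_win)
  bad <- logical(n_win)
  for (j in seq_len(MOTIF_WIDTH)) {
    pos <- seq_len(n_win) + j - 1L
    aa <- idx[pos]
    bad <- bad | is.na(aa)
    aa[is.na(aa)] <- 1L
    scores <- scores + pssm$matrix[cbind(aa, j)]
  }
  scores[bad] <- NA_real_
  scores
}

#' Scan protein sequences for motif-like windows
#'
#' Scores every overlapping 8-residue window of every sequence and returns
#' the windows above threshold, in stable order (input protein order, then
#' position). Windows containing non-standard residues are excluded (the
#' matrix has no columns for them); sequences shorter than 8 are skipped
#' with a message.
#'
#' @param pssm A `"pssm"` object.
#' @param sequences An [Biostrings::AAStringSet], a named character vector,
#'   or a FASTA path. UniProt-style headers (`db|ACC|NAME ...`) are parsed
#'   to the accession.
#' @param min_score Score threshold (default 0, the "positive score" bound).
#' @param strict Logical; TRUE (default) keeps windows with score strictly
#'   greater than `min_score`, FALSE keeps ties as well.
#' @return data.frame of class `"motif_hits"` with columns
#'   `accession`, `start` (1-based), `sequence` (the 8-mer), `pssm_score`.
#' @export
scan_sequences <- function(pssm, sequences, min_score = 0, strict = TRUE) {
  stopifnot(inherits(pssm, "pssm"))
  seqs <- as_aa_character(sequences)
  if (length(seqs) == 0L) {
    warning("empty proteome: no sequences to scan")
  }
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    if (nchar(s) < MOTIF_WIDTH) {
      message("skipping ", names(seqs)[i], ": shorter than ", MOTIF_WIDTH,
              " residues")
      next
    }
    sc <- score_all_windows(pssm, s)
    keep <- !is.na(sc) & (if (strict) sc > min_score else sc >= min_score)
    if (!any(keep)) next
    starts <- which(keep)
    out[[i]] <- data.frame(
      accession = names(seqs)[i], start = starts,
      sequence = substring(s, starts, starts + MOTIF_WIDTH - 1L),
      pssm_score = sc[starts], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(accession = character(), start = integer(),
                      sequence = character(), pssm_score = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  class(res) <- c("motif_hits", "data.frame")
  res
}

# Normalize sequence input to a named character vector with UniProt-style
# accessions extracted from FASTA headers.
as_aa_character <- function(sequences) {
  if (is.character(sequences) && length(sequences) == 1L &&
      is.null(names(sequences)) && file.exists(sequences)) {
    sequences <- Biostrings::readAAStringSet(sequences)
  }
  if (methods::is(sequences, "AAStringSet")) {
    nm <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- nm
  }
  if (!is.character(sequences)) stop("unsupported sequence input")
  if (is.null(names(sequences)) && length(sequences) > 0L) {
    stop("sequences must be named")
  }
  names(sequences) <- parse_fasta_accession(names(sequences))
  sequences
}

# "sp|P63167|DYNL1_HUMAN Dynein..." -> "P63167"; plain ids pass through.
parse_fasta_accession <- function(headers) {
  first <- sub("\\s.*$", "", headers)
  vapply(first, function(h) {
    parts <- strsplit(h, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2L && parts[1] %in% c("sp", "tr")) parts[2] else h
  }, character(1), USE.NAMES = FALSE)
}

#' Serialize a PSSM to a TSV file
#'
#' Tab-separated 20 x 8 matrix preceded by commented header lines recording
#' the pseudocount, number of training motifs, log base, background
#' frequencies and column entropies, so that [read_pssm()] round-trips the
#' object bit-exactly (values printed with full precision).
#'
#' @param pssm A `"pssm"` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, path) {
  stopifnot(inherits(pssm, "pssm"))
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) sprintf("%.17g", x)
  writeLines(c(
    sprintf("# pseudocount\t%s", num(pssm$pseudocount)),
    sprintf("# n_sequences\t%d", pssm$n_sequences),
    sprintf("# log_base\t%s", num(pssm$log_base)),
    sprintf("# background\t%s",
            paste(num(as.numeric(pssm$background)), collapse = "\t")),
    sprintf("# column_entropy\t%s",
            paste(num(pssm$column_entropy), collapse = "\t")),
    paste(c("aa", MOTIF_POSITIONS), collapse = "\t")), con)
  for (i in seq_len(20L)) {
    writeLines(paste(c(AA_ALPHABET_20[i], num(pssm$matrix[i, ])),
                     collapse = "\t"), con)
  }
  counts_line <- apply(pssm$counts, 1, paste, collapse = ",")
  writeLines(paste0("# counts\t", paste(counts_line, collapse = "\t")), con)
  invisible(path)
}

#' Read a PSSM written by [write_pssm()]
#'
#' @param path TSV file produced by [write_pssm()].
#' @return A `"pssm"` object.
#' @export
read_pssm <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, "\t"))]
    strsplit(sub(paste0("^# ", key, "\t"), "", ln), "\t", fixed = TRUE)[[1]]
  }
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(mat) <- list(tab[[1]], MOTIF_POSITIONS)
  counts_raw <- get("counts")
  counts <- t(vapply(counts_raw,
                     function(s) as.integer(strsplit(s, ",")[[1]]),
                     integer(MOTIF_WIDTH)))
  dimnames(counts) <- dimnames(mat)
  bg <- as.numeric(get("background"))
  names(bg) <- AA_ALPHABET_20
  structure(list(matrix = mat[AA_ALPHABET_20, ],
                 counts = counts[AA_ALPHABET_20, ],
                 n_sequences = as.integer(get("n_sequences")),
                 pseudocount = as.numeric(get("pseudocount")),
                 log_base = as.numeric(get("log_base")),
                 background = structure(bg, class = "background_frequencies"),
                 column_entropy = stats::setNames(
                   as.numeric(get("column_entropy")), MOTIF_POSITIONS)),
            class = "pssm")
}
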