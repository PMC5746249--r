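# Seeded synthetic-fixture generators: background proteomes, planted
# motifs, class-conditional annotation tracks, purifying-selection ortholog
# alignments, curated-table and MITAB fixtures. Everything is a pure
# function of (parameters, seed); the seed is recorded on every artifact.

# run code under a fixed seed without clobbering the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# build one profile column: named preferences, remaining mass spread
# uniformly over the unlisted residues
profile_column <- function(...) {
  pref <- c(...)
  rest <- setdiff(AA_ALPHABET_20, names(pref))
  p <- numeric(20)
  names(p) <- AA_ALPHABET_20
  p[names(pref)] <- pref
  p[rest] <- (1 - sum(pref)) / length(rest)
  p
}

#' Canonical motif preference profile of the synthetic fixtures
#'
#' A 20 x 8 per-position probability matrix emulating the sequence logo of
#' the TQT-class binding motif: a strongly preferred Thr-Gln-Thr core at
#' positions -1..+1 (with Asn/Met tolerated centrally), acidic preference
#' at -4, and milder flank preferences. This is a synthetic stand-in
#' profile, not the published matrix; it drives the curated-table and
#' planted-motif generators.
#'
#' @return 20 x 8 matrix of probabilities (columns sum to 1).
#' @export
motif_preference_profile <- function() {
  cols <- list(
    profile_column(V = 0.14, L = 0.10, I = 0.08, R = 0.10, K = 0.10,
                   S = 0.08, C = 0.06, E = 0.05),                  # -5
    profile_column(D = 0.45, E = 0.20, S = 0.08, A = 0.05),        # -4
    profile_column(K = 0.20, C = 0.10, A = 0.10, G = 0.10,
                   S = 0.10, R = 0.05),                            # -3
    profile_column(S = 0.22, G = 0.15, E = 0.10, A = 0.10,
                   T = 0.10),                                      # -2
    profile_column(T = 0.62, S = 0.15, I = 0.05, C = 0.04,
                   G = 0.04),                                      # -1
    profile_column(Q = 0.60, N = 0.12, M = 0.08, T = 0.04,
                   S = 0.04),                                      #  0
    profile_column(T = 0.78, Q = 0.04, S = 0.04, P = 0.03),        # +1
    profile_column(E = 0.20, D = 0.20, S = 0.12, A = 0.08,
                   T = 0.08, V = 0.06))                            # +2
  mat <- do.call(cbind, cols)
  dimnames(mat) <- list(AA_ALPHABET_20, MOTIF_POSITIONS)
  mat
}

sample_from_profile <- function(profile, n = 1) {
  vapply(seq_len(n), function(i) {
    paste(vapply(seq_len(ncol(profile)), function(j) {
      sample(AA_ALPHABET_20, 1, prob = profile[, j])
    }, character(1)), collapse = "")
  }, character(1))
}

#' Generate a synthetic curated motif table
#'
#' Produces a labelled stand-in for a literature-curated motif collection,
#' with a configurable composition: total instances, distinct partners,
#' human-mappable instances and proteins, and per-class core counts
#' (full-pattern matches, canonical-TQT-only, non-canonical TMT/TNT cores,
#' and divergent cores such as SQT/TSP). The defaults mirror the reference
#' collection for the LC8 system: 67 instances over 53 partners, 40 human
#' instances in 33 proteins, 13 full-pattern and 24 additional TQT-core
#' motifs (7 and 17 among the human instances). Flanking positions are
#' drawn from [motif_preference_profile()]; cores are set per class.
#'
#' @param seed Integer seed.
#' @param composition List with entries `n_instances`, `n_partners`,
#'   `n_human_instances`, `n_human_proteins`, and two length-4 integer
#'   vectors `classes` / `classes_human` named
#'   `elm_match`, `tqt_core`, `noncanonical_core`, `other`.
#' @return A `"curated_motifs"` data.frame (see [load_curated_motifs()]).
#' @export
simulate_curated_motifs <- function(seed = 1,
                                    composition = default_curated_composition()) {
  cmp <- composition
  stopifnot(sum(cmp$classes) == cmp$n_instances,
            sum(cmp$classes_human) == cmp$n_human_instances,
            all(cmp$classes_human <= cmp$classes))
  with_seed(seed, {
    profile <- motif_preference_profile()
    classes <- c("elm_match", "tqt_core", "noncanonical_core", "other")
    draw_instance <- function(class) {
      repeat {
        s <- strsplit(sample_from_profile(profile, 1), "")[[1]]
        s <- switch(class,
          elm_match = { s[1] <- "P"; s[3] <- "K"; s[5:7] <- c("T", "Q", "T"); s },
          tqt_core = { s[5:7] <- c("T", "Q", "T"); s },
          noncanonical_core = { s[5] <- "T"; s[7] <- "T"
            s[6] <- sample(c("M", "N"), 1); s },
          other = { s[5:7] <- strsplit(sample(
            c("SQT", "TQS", "TSP", "GQT", "SST"), 1), "")[[1]]; s })
        w <- paste(s, collapse = "")
        if (classify_core(w) == class) return(w)
      }
    }
    build_block <- function(n_instances, n_proteins, class_counts,
                            acc_prefix, taxa, human) {
      n_extra <- n_instances - n_proteins
      host <- c(seq_len(n_proteins),
                sample(seq_len(n_proteins), n_extra, replace = FALSE))
      cls <- sample(rep(classes, times = class_counts))
      data.frame(
        accession = sprintf("%s%04d", acc_prefix, host),
        gene = sprintf("%sG%d", acc_prefix, host),
        taxon = if (human) "Homo sapiens" else
          sample(taxa, n_instances, replace = TRUE),
        start = sample(20:1200, n_instances, replace = TRUE),
        sequence = vapply(cls, draw_instance, character(1)),
        human_mappable = human,
        evidence = "synthetic fixture",
        stringsAsFactors = FALSE)
    }
    nonhuman_taxa <- c("Mus musculus", "Rattus norvegicus",
                       "Gallus gallus", "Drosophila melanogaster",
                       "Saccharomyces cerevisiae")
    hm <- build_block(cmp$n_human_instances, cmp$n_human_proteins,
                      cmp$classes_human, "HSYN", NULL, TRUE)
    nh_counts <- cmp$classes - cmp$classes_human
    nh <- build_block(cmp$n_instances - cmp$n_human_instances,
                      cmp$n_partners - cmp$n_human_proteins,
                      nh_counts, "XSYN", nonhuman_taxa, FALSE)
    out <- rbind(hm, nh)
    rownames(out) <- NULL
    attr(out, "rejected") <- data.frame(row = integer(),
                                        reason = character())
    attr(out, "seed") <- seed
    class(out) <- c("curated_motifs", "data.frame")
    out
  })
}

#' @rdname simulate_curated_motifs
#' @export
default_curated_composition <- function() {
  list(n_instances = 67L, n_partners = 53L,
       n_human_instances = 40L, n_human_proteins = 33L,
       classes = c(elm_match = 13L, tqt_core = 24L,
                   noncanonical_core = 20L, other = 10L),
       classes_human = c(elm_match = 7L, tqt_core = 17L,
                         noncanonical_core = 11L, other = 5L))
}

#' Generate a background proteome
#'
#' Sequences drawn i.i.d. from the background residue frequencies, with
#' normally distributed lengths (truncated at the motif width).
#'
#' @param n_proteins Number of sequences.
#' @param length_mean,length_sd Length distribution; `length_mean` must be
#'   at least 8.
#' @param background A `"background_frequencies"` vector.
#' @param seed Integer seed.
#' @return Named character vector of sequences (accessions `SYNBG...`),
#'   with the seed recorded in the `"seed"` attribute.
#' @export
simulate_background_proteome <- function(n_proteins, length_mean = 500,
                                         length_sd = 100,
                                         background = default_background(),
                                         seed = 1) {
  if (length_mean < MOTIF_WIDTH) {
    stop("length_mean must be at least ", MOTIF_WIDTH)
  }
  with_seed(seed, {
    lens <- pmax(MOTIF_WIDTH,
                 round(stats::rnorm(n_proteins, length_mean, length_sd)))
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_ALPHABET_20, L, replace = TRUE,
                   prob = as.numeric(background)), collapse = "")
    }, character(1))
    names(seqs) <- sprintf("SYNBG%04d", seq_len(n_proteins))
    attr(seqs, "seed") <- seed
    seqs
  })
}

#' Plant motif instances into a proteome
#'
#' Overwrites `n` random, non-overlapping 8-residue slots with 8-mers
#' sampled from the PSSM's pseudocount-smoothed column frequencies, and
#' returns the modified proteome with a truth table of planted coordinates.
#'
#' @param proteome Named character vector of sequences.
#' @param pssm A `"pssm"` whose smoothed frequencies drive the sampling.
#' @param n Number of instances to plant.
#' @param seed Integer seed.
#' @return List with `sequences` (modified proteome) and `truth`
#'   (data.frame `accession`, `start`, `sequence`).
#' @export
plant_motif_instances <- function(proteome, pssm, n, seed = 1) {
  lens <- nchar(proteome)
  capacity <- sum(pmax(0L, floor(lens / MOTIF_WIDTH)))
  if (n > capacity) {
    stop("cannot plant ", n, " non-overlapping motifs: capacity ", capacity)
  }
  if (n == 0L) {
    return(list(sequences = proteome,
                truth = data.frame(accession = character(),
                                   start = integer(),
                                   sequence = character(),
                                   stringsAsFactors = FALSE)))
  }
  with_seed(seed, {
    freqs <- pssm_frequencies(pssm)
    occupied <- lapply(proteome, function(x) integer(0))
    truth <- vector("list", n)
    planted <- 0L
    attempts <- 0L
    seqs <- proteome
    while (planted < n) {
      attempts <- attempts + 1L
      if (attempts > 1000L * n) stop("failed to place motifs")
      i <- sample(length(seqs), 1, prob = pmax(1, lens - MOTIF_WIDTH + 1L))
      if (lens[i] < MOTIF_WIDTH) next
      st <- sample(lens[i] - MOTIF_WIDTH + 1L, 1)
      span <- st:(st + MOTIF_WIDTH - 1L)
      if (length(intersect(span, occupied[[i]]))) next
      # verified motif instances all score positive against their own
      # PSSM; planted instances emulate that property
      repeat {
        motif <- sample_from_profile(freqs, 1)
        if (score_window(pssm, motif) > 0) break
      }
      substr(seqs[i], st, st + MOTIF_WIDTH - 1L) <- motif
      occupied[[i]] <- c(occupied[[i]], span)
      planted <- planted + 1L
      truth[[planted]] <- data.frame(accession = names(seqs)[i],
                                     start = st, sequence = motif,
                                     stringsAsFactors = FALSE)
    }
    list(sequences = seqs, truth = do.call(rbind, truth))
  })
}

#' Default class-conditional feature parameters
#'
#' Emulates the separation the reference protocol exploits: motif windows
#' sit in disordered (high IUPred-like score), intracellular, domain-free
#' context; background windows are mixed. Values are generator design
#' choices, not estimates of any real predictor.
#'
#' @return Named list consumed by [simulate_feature_tracks()].
#' @export
default_feature_params <- function() {
  list(
    iupred = list(kind = "score", pos_mean = 0.75, pos_sd = 0.12,
                  neg_mean = 0.40, neg_sd = 0.25),
    localization = list(kind = "localization", p_signal_bg = 0.5),
    pfam_domain = list(kind = "interval", p_domain_bg = 0.4,
                       domain_frac = 0.4))
}

#' Simulate class-conditional annotation tracks
#'
#' Per-residue score tracks are drawn from the negative-class normal
#' distribution everywhere except inside true motif windows, which receive
#' the positive-class distribution (values clamped to \[0, 1\]). Proteins
#' without a planted motif receive, with the stated probability, a signal
#' peptide plus EXT/TM/INT topology, and/or a PFAM-domain interval placed
#' away from any planted window; motif-bearing proteins stay intracellular
#' and domain-free at the motif.
#'
#' @param proteome Named character vector of sequences.
#' @param truth Planted-motif truth table ([plant_motif_instances()]).
#' @param feature_params See [default_feature_params()].
#' @param seed Integer seed.
#' @return A `"track_store"`.
#' @export
simulate_feature_tracks <- function(proteome, truth,
                                    feature_params = default_feature_params(),
                                    seed = 1) {
  known <- c("score", "localization", "interval")
  kinds <- vapply(feature_params, function(p) p$kind, character(1))
  if (any(!kinds %in% known)) {
    stop("unknown feature kind(s): ",
         paste(setdiff(kinds, known), collapse = ", "))
  }
  with_seed(seed, {
    tracks <- list()
    lens <- nchar(proteome)
    for (i in seq_along(proteome)) {
      acc <- names(proteome)[i]
      L <- lens[i]
      mot <- truth[truth$accession == acc, , drop = FALSE]
      motif_pos <- unlist(lapply(mot$start,
                                 function(s) s:(s + MOTIF_WIDTH - 1L)))
      has_motif <- nrow(mot) > 0L
      for (nm in names(feature_params)) {
        p <- feature_params[[nm]]
        if (p$kind == "score") {
          v <- stats::rnorm(L, p$neg_mean, p$neg_sd)
          if (length(motif_pos)) {
            v[motif_pos] <- stats::rnorm(length(motif_pos), p$pos_mean,
                                         p$pos_sd)
          }
          tracks[[length(tracks) + 1L]] <-
            score_track(acc, nm, pmin(1, pmax(0, v)))
        } else if (p$kind == "localization") {
          empty <- data.frame(start = integer(), end = integer(),
                              label = character())
          if (!has_motif && L > 60 &&
              stats::runif(1) < p$p_signal_bg) {
            sig <- data.frame(start = 1L, end = 20L, label = "signal")
            mid <- floor(L / 2)
            topo <- data.frame(
              start = c(21L, mid + 1L, mid + 22L),
              end = c(mid, mid + 21L, L),
              label = c("EXT", "TM", "INT"))
            tracks[[length(tracks) + 1L]] <-
              interval_track(acc, "signal_peptide", sig)
            tracks[[length(tracks) + 1L]] <-
              interval_track(acc, "topology", topo)
          } else {
            tracks[[length(tracks) + 1L]] <-
              interval_track(acc, "signal_peptide", empty)
          }
        } else if (p$kind == "interval") {
          iv <- data.frame(start = integer(), end = integer(),
                           label = character())
          if (stats::runif(1) < p$p_domain_bg) {
            dl <- max(10L, floor(L * p$domain_frac))
            # place the domain clear of planted windows
            for (try in 1:20) {
              st <- sample(max(1L, L - dl + 1L), 1)
              span <- st:(min(L, st + dl - 1L))
              if (!length(intersect(span, motif_pos))) {
                iv <- data.frame(start = st, end = max(span),
                                 label = "SYNDOM")
                break
              }
            }
          }
          tracks[[length(tracks) + 1L]] <- interval_track(acc, nm, iv)
        }
      }
    }
    track_store(tracks)
  })
}

#' Default per-level substitution rates for ortholog simulation
#'
#' Flank (per-site) and motif-column (purifying) substitution
#' probabilities, and ortholog counts, per taxonomic level. Flank rates are
#' high, emulating fast-evolving disordered sequence; motif columns evolve
#' slowly at close distances and lose constraint at long range.
#'
#' @return Named list of per-level lists `n`, `rate`, `motif_rate`.
#' @export
default_msa_params <- function() {
  list(Mammalia = list(n = 6L, rate = 0.30, motif_rate = 0.02),
       Vertebrata = list(n = 4L, rate = 0.45, motif_rate = 0.08),
       Metazoa = list(n = 3L, rate = 0.60, motif_rate = 0.20),
       Fungi = list(n = 2L, rate = 0.70, motif_rate = 0.50),
       Eukarya = list(n = 2L, rate = 0.75, motif_rate = 0.60))
}

#' Simulate an ortholog alignment with purifying selection on motif columns
#'
#' Orthologs are generated per taxonomic level by independent per-site
#' substitution of the reference: flank sites at the level's `rate`, motif
#' columns at the (lower) `motif_rate`. Replacements at flank sites are
#' drawn from the background; at motif columns they are drawn from the
#' PSSM's smoothed column frequencies when a PSSM is supplied (tolerated
#' substitutions), otherwise from the background. Substitution-only: the
#' alignment is gapless.
#'
#' @param reference Ungapped reference protein sequence.
#' @param motif_starts Integer vector of planted motif starts (their 8
#'   columns evolve at the purifying rate).
#' @param msa_params See [default_msa_params()].
#' @param seed Integer seed.
#' @param pssm Optional `"pssm"` driving tolerated motif substitutions.
#' @param background Background frequencies for flank substitutions.
#' @param reference_id Row name of the reference (default `"REF"`).
#' @return List with `alignment` (an `"ortholog_alignment"`) and
#'   `taxonomy` (named vector taxon -> level).
#' @export
simulate_ortholog_alignment <- function(reference, motif_starts,
                                        msa_params = default_msa_params(),
                                        seed = 1, pssm = NULL,
                                        background = default_background(),
                                        reference_id = "REF") {
  rates <- unlist(lapply(msa_params, function(p) c(p$rate, p$motif_rate)))
  if (any(rates < 0 | rates > 1)) stop("substitution rates must be in [0,1]")
  ref <- strsplit(toupper(reference), "")[[1]]
  L <- length(ref)
  bad <- motif_starts[motif_starts < 1L |
                        motif_starts + MOTIF_WIDTH - 1L > L]
  if (length(bad)) stop("motif start(s) outside reference: ",
                        paste(bad, collapse = ", "))
  motif_cols <- unlist(lapply(motif_starts,
                              function(s) s:(s + MOTIF_WIDTH - 1L)))
  motif_offset <- unlist(lapply(motif_starts, function(s) 1:MOTIF_WIDTH))
  with_seed(seed, {
    freqs <- if (!is.null(pssm)) pssm_frequencies(pssm) else NULL
    rows <- list()
    species <- character(0)
    taxonomy <- character(0)
    for (level in names(msa_params)) {
      p <- msa_params[[level]]
      for (k in seq_len(p$n)) {
        seqv <- ref
        mut_flank <- stats::runif(L) < p$rate
        mut_flank[motif_cols] <- FALSE
        if (any(mut_flank)) {
          seqv[mut_flank] <- sample(AA_ALPHABET_20, sum(mut_flank),
                                    replace = TRUE,
                                    prob = as.numeric(background))
        }
        mut_motif <- which(stats::runif(length(motif_cols)) < p$motif_rate)
        for (mi in mut_motif) {
          col <- motif_offset[mi]
          prob <- if (is.null(freqs)) as.numeric(background) else
            freqs[, col]
          seqv[motif_cols[mi]] <- sample(AA_ALPHABET_20, 1, prob = prob)
        }
        id <- sprintf("%s_%02d", level, k)
        taxon <- sprintf("%s sp. %d", level, k)
        rows[[id]] <- paste(seqv, collapse = "")
        species[id] <- taxon
        taxonomy[taxon] <- level
      }
    }
    rows[[reference_id]] <- paste(ref, collapse = "")
    species[reference_id] <- "Homo sapiens"
    taxonomy["Homo sapiens"] <- "Mammalia"
    aln <- ortholog_alignment(unlist(rows), reference_id, species)
    list(alignment = aln, taxonomy = taxonomy)
  })
}

#' Sample negative (background) windows for the feature table
#'
#' Uniform sampling without replacement from positive-scoring scan hits,
#' excluding any window overlapping a true (planted or curated) positive.
#'
#' @param hits A `"motif_hits"` data.frame from [scan_sequences()].
#' @param truth data.frame with `accession`, `start` of true positives.
#' @param n Number of negatives (capped at availability).
#' @param seed Integer seed.
#' @return Subset of `hits`.
#' @export
sample_negative_windows <- function(hits, truth, n, seed = 1) {
  overlapping <- rep(FALSE, nrow(hits))
  for (i in seq_len(nrow(truth))) {
    overlapping <- overlapping |
      (hits$accession == truth$accession[i] &
         abs(hits$start - truth$start[i]) < MOTIF_WIDTH)
  }
  pool <- which(!overlapping)
  with_seed(seed, {
    take <- sample(pool, min(n, length(pool)))
    out <- hits[sort(take), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Write a toy MITAB 2.5 file
#'
#' Renders evidence specifications into tab-separated MITAB lines from a
#' fixed template (uniprotkb ids, `psi-mi:"MI:xxxx"(name)` method and type
#' fields, `pubmed:` references, `taxid:` organisms).
#'
#' @param path Output file.
#' @param bait Bait accession.
#' @param records data.frame with columns `partner`, `pubmed` (NA for
#'   missing), `method_id`, `method_name`, `type_id`, `type_name`,
#'   `source`, `taxid`.
#' @return `path`, invisibly.
#' @export
write_mitab_fixture <- function(path, bait, records) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    pub <- if (is.na(r$pubmed)) "-" else paste0("pubmed:", r$pubmed)
    type_f <- if (is.na(r$type_id)) "-" else
      sprintf('psi-mi:"%s"(%s)', r$type_id, r$type_name)
    paste(
      paste0("uniprotkb:", bait), paste0("uniprotkb:", r$partner),
      "-", "-", "-", "-",
      sprintf('psi-mi:"%s"(%s)', r$method_id, r$method_name),
      "-", pub,
      "taxid:9606(human)", paste0("taxid:", r$taxid, "(organism)"),
      type_f, sprintf('psi-mi:"MI:0000"(%s)', r$source),
      "-", "-", sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full protocol on a standard synthetic benchmark
#'
#' Generates a background proteome with planted motif instances, simulates
#' class-conditional annotation tracks, assembles the labeled feature table
#' from a proteome scan, learns the filtering pipeline, applies it, and
#' runs the mammalian-conservation filter over simulated ortholog
#' alignments of every protein hosting retained candidates. Reports the
#' fraction of planted motifs retained and the fraction of background
#' (negative) windows surviving, end to end.
#'
#' @param seed Integer seed driving every generator.
#' @param n_proteins,length_mean,length_sd Proteome size parameters; the
#'   defaults give roughly 1.1e5 residues, i.e. over 1e5 scanned windows.
#' @param n_motifs Planted motif instances (default 20).
#' @param pssm PSSM used for planting and scoring; by default built from a
#'   synthetic curated table ([simulate_curated_motifs()]) under the same
#'   seed.
#' @param feature_params,msa_params Generator parameters.
#' @param n_negatives Cap on background rows entering the feature table
#'   (default 10000, sampled from the positive-scoring windows).
#' @param conservation_cutoff,conservation_threshold Conservation filter
#'   settings (defaults 3.3 bits and 0.8).
#' @return List: `planted_retention`, `background_retention` (fractions),
#'   `n_background_windows` (windows scanned in background sequence),
#'   `pipeline`, `accounting`, `feature_table`, `retained`.
#' @export
evaluate_protocol_recovery <- function(seed = 1, n_proteins = 220,
                                       length_mean = 500, length_sd = 100,
                                       n_motifs = 20, pssm = NULL,
                                       feature_params = default_feature_params(),
                                       msa_params = default_msa_params(),
                                       n_negatives = 10000,
                                       conservation_cutoff = 3.3,
                                       conservation_threshold = 0.8) {
  if (is.null(pssm)) {
    curated <- simulate_curated_motifs(seed)
    pssm <- build_pssm(curated$sequence)
  }
  proteome <- simulate_background_proteome(n_proteins, length_mean,
                                           length_sd, seed = seed)
  planted <- plant_motif_instances(proteome, pssm, n_motifs,
                                   seed = seed + 1L)
  store <- simulate_feature_tracks(planted$sequences, planted$truth,
                                   feature_params, seed = seed + 2L)
  hits <- scan_sequences(pssm, planted$sequences, min_score = 0)
  truth_key <- motif_id(planted$truth$accession, planted$truth$start)
  pos_hits <- hits[motif_id(hits$accession, hits$start) %in% truth_key, ,
                   drop = FALSE]
  neg_hits <- sample_negative_windows(hits, planted$truth, n_negatives,
                                      seed = seed + 3L)
  table <- assemble_feature_table(
    rbind(pos_hits, neg_hits), store,
    labels = c(rep("positive", nrow(pos_hits)),
               rep("negative", nrow(neg_hits))))
  pipeline <- build_pipeline(table)
  applied <- apply_pipeline(pipeline, table)
  retained <- applied$retained

  # mammalian conservation of every retained candidate, one simulated
  # alignment per host protein (true motif columns under purifying rates)
  accs <- unique(retained$accession)
  passed <- logical(nrow(retained))
  for (acc in accs) {
    starts_true <- planted$truth$start[planted$truth$accession == acc]
    sim <- simulate_ortholog_alignment(
      planted$sequences[[acc]], starts_true, msa_params,
      seed = seed + 10L + match(acc, names(planted$sequences)),
      pssm = pssm)
    idx <- which(retained$accession == acc)
    for (i in idx) {
      res <- conservation_by_level(sim$alignment, retained$start[i], pssm,
                                   cutoff = conservation_cutoff,
                                   taxonomy = sim$taxonomy)
      passed[i] <- suppressMessages(
        mammalian_conservation_filter(res, conservation_threshold))
    }
  }
  final <- retained[passed, , drop = FALSE]
  n_neg <- sum(table$label == "negative")
  n_windows <- sum(pmax(0L, nchar(planted$sequences) - MOTIF_WIDTH + 1L))
  list(planted_retention = sum(final$label == "positive") /
         nrow(planted$truth),
       background_retention = sum(final$label == "negative") / n_neg,
       n_background_windows = n_windows - nrow(planted$truth),
       n_feature_negatives = n_neg,
       pipeline = pipeline, accounting = applied$accounting,
       feature_table = table, retained = final)
}
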