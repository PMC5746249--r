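# Weighted information-gain evaluation of binary filters, cutoff
# optimization, greedy decision-list construction and cross-validation.
#
# All entropies are in bits. Class imbalance is handled by per-class weight
# normalization: every example of class k carries weight 1/N_k, so the
# unfiltered parent is balanced by construction (H_p = 1 bit) and a filter
# is rewarded for removing negatives, not for the sheer size of the
# negative set.

#' Weighted Shannon entropy of a labeled group
#'
#' `H = -sum_k q_k log2 q_k` over class proportions `q_k` computed from the
#' example weights (each class's total weight divided by the group total).
#' Empty classes contribute 0.
#'
#' @param labels Character vector of class labels.
#' @param weights Non-negative example weights; at least one must be
#'   positive.
#' @return Entropy in bits.
#' @export
weighted_entropy <- function(labels, weights) {
  stopifnot(length(labels) == length(weights), all(weights >= 0))
  total <- sum(weights)
  if (total <= 0) stop("group has zero total weight")
  q <- tapply(weights, labels, sum) / total
  q <- q[q > 0]
  -sum(q * log2(q))
}

#' A binary filter predicate
#'
#' @param attribute Attribute (column) name.
#' @param op One of `">="`, `"<="`, `"in"`, `"=="`; rows satisfying the
#'   predicate are *retained*.
#' @param value Cutoff (numeric), category set (character), or logical.
#' @return List of class `"filter_predicate"`.
#' @export
filter_predicate <- function(attribute, op, value) {
  stopifnot(op %in% c(">=", "<=", "in", "=="))
  structure(list(attribute = attribute, op = op, value = value),
            class = "filter_predicate")
}

predicate_mask <- function(predicate, table) {
  if (!predicate$attribute %in% names(table)) {
    stop("attribute '", predicate$attribute, "' missing from table")
  }
  x <- table[[predicate$attribute]]
  switch(predicate$op,
         ">=" = x >= predicate$value,
         "<=" = x <= predicate$value,
         "in" = x %in% predicate$value,
         "==" = x == predicate$value)
}

format_predicate <- function(p) {
  val <- if (is.numeric(p$value)) format(p$value, digits = 6) else
    paste(p$value, collapse = ",")
  paste(p$attribute, p$op, val)
}

#' Evaluate the information gain of one binary split
#'
#' `I = H_p - p_c1 * H_c1 - p_c2 * H_c2`, where child 1 is the retained set,
#' child 2 the removed set, and `p_c` the weighted fraction of the parent in
#' child c. An empty child has entropy 0 and probability 0.
#'
#' @param table A `"feature_table"` (needs `label` and `weight` columns).
#' @param predicate A [filter_predicate()].
#' @return List of class `"split_evaluation"`: `attribute`, `predicate`,
#'   `info_gain`, `parent_entropy`, `child_entropies`,
#'   `child_probabilities`, `retained_counts`, `removed_counts` (per-class
#'   integer vectors).
#' @export
split_information_gain <- function(table, predicate) {
  keep <- predicate_mask(predicate, table)
  w <- table$weight
  lab <- table$label
  hp <- weighted_entropy(lab, w)
  total <- sum(w)
  p1 <- sum(w[keep]) / total
  p2 <- 1 - p1
  h1 <- if (any(keep)) weighted_entropy(lab[keep], w[keep]) else 0
  h2 <- if (any(!keep)) weighted_entropy(lab[!keep], w[!keep]) else 0
  gain <- hp - p1 * h1 - p2 * h2
  classes <- sort(unique(lab))
  count_by <- function(mask) {
    vapply(classes, function(cl) sum(lab[mask] == cl), integer(1))
  }
  structure(list(attribute = predicate$attribute, predicate = predicate,
                 info_gain = gain, parent_entropy = hp,
                 child_entropies = c(h1, h2),
                 child_probabilities = c(p1, p2),
                 retained_counts = count_by(keep),
                 removed_counts = count_by(!keep)),
            class = "split_evaluation")
}

#' @export
print.split_evaluation <- function(x, ...) {
  cat(sprintf("split on %s: I = %.4f bits (H_p = %.4f)\n",
              format_predicate(x$predicate), x$info_gain, x$parent_entropy))
  cat("  retained:", paste(names(x$retained_counts), x$retained_counts,
                           sep = "=", collapse = " "), "\n")
  cat("  removed: ", paste(names(x$removed_counts), x$removed_counts,
                           sep = "=", collapse = " "), "\n")
  invisible(x)
}

removed_negatives <- function(ev) {
  n <- ev$removed_counts["negative"]
  if (is.na(n)) 0L else as.integer(n)
}
removed_positives <- function(ev) {
  n <- ev$removed_counts["positive"]
  if (is.na(n)) 0L else as.integer(n)
}

#' Find the information-gain-optimal cutoff for a continuous attribute
#'
#' Candidate cutoffs are the midpoints between consecutive sorted distinct
#' values, so the scan is exhaustive and the optimum exact for the dataset.
#' Ties in information gain are broken by the larger number of negatives
#' removed, then by the smaller cutoff.
#'
#' @param table A `"feature_table"`.
#' @param attribute Numeric column name.
#' @param direction `"keep_ge"` retains rows with value >= cutoff (scores
#'   where high is motif-like, e.g. PSSM or disorder scores); `"keep_le"`
#'   the reverse.
#' @return A `"split_evaluation"`; for a constant attribute, a
#'   non-informative evaluation with `info_gain = 0` and
#'   `non_informative = TRUE`.
#' @export
optimize_cutoff <- function(table, attribute,
                            direction = c("keep_ge", "keep_le")) {
  direction <- match.arg(direction)
  x <- table[[attribute]]
  if (is.null(x)) stop("attribute '", attribute, "' missing from table")
  if (!is.numeric(x)) stop("attribute '", attribute, "' is not numeric")
  vals <- sort(unique(x))
  op <- if (direction == "keep_ge") ">=" else "<="
  if (length(vals) < 2L) {
    ev <- split_information_gain(table,
                                 filter_predicate(attribute, op, vals[1]))
    ev$info_gain <- 0
    ev$non_informative <- TRUE
    return(ev)
  }
  cuts <- (vals[-1] + vals[-length(vals)]) / 2
  best <- NULL
  for (cut in cuts) {
    ev <- split_information_gain(table,
                                 filter_predicate(attribute, op, cut))
    if (is.null(best) || better_cutoff(ev, best)) best <- ev
  }
  best
}

# strict improvement order: higher I, then more negatives removed, then
# smaller cutoff
better_cutoff <- function(ev, best, tol = 1e-12) {
  if (ev$info_gain > best$info_gain + tol) return(TRUE)
  if (ev$info_gain < best$info_gain - tol) return(FALSE)
  dn <- removed_negatives(ev) - removed_negatives(best)
  if (dn != 0) return(dn > 0)
  is.numeric(ev$predicate$value) && is.numeric(best$predicate$value) &&
    ev$predicate$value < best$predicate$value
}

#' Declare candidate filter attributes for pipeline construction
#'
#' @param ... Named lists:
#'   `list(type = "continuous", direction = "keep_ge"|"keep_le")`,
#'   `list(type = "boolean")` (both polarities evaluated), or
#'   `list(type = "categorical")` (every keep-one-category split
#'   evaluated).
#' @return Named list of class `"candidate_spec"`.
#' @export
candidate_attributes <- function(...) {
  structure(list(...), class = "candidate_spec")
}

#' Default filter candidates of the reference protocol
#'
#' @return A [candidate_attributes()] spec covering localization
#'   (categorical), PFAM Domain overlap (boolean), PSSM score and disorder
#'   mean (continuous, keep-high).
#' @export
default_candidates <- function() {
  candidate_attributes(
    localization = list(type = "categorical"),
    pfam_domain = list(type = "boolean"),
    pssm_score = list(type = "continuous", direction = "keep_ge"),
    iupred = list(type = "continuous", direction = "keep_ge"))
}

# fraction of the parent's positives kept in the retained child
retained_positive_share <- function(ev) {
  kept <- ev$retained_counts["positive"]
  lost <- ev$removed_counts["positive"]
  kept <- if (is.na(kept)) 0L else kept
  lost <- if (is.na(lost)) 0L else lost
  if (kept + lost == 0L) return(1)
  kept / (kept + lost)
}

# best split_evaluation for one attribute under its declared type. The
# retained child is the presumed-motif child: complementary predicates
# carry identical information gain (same partition), so polarity is
# decided by where the positives go.
evaluate_attribute <- function(table, name, spec) {
  if (spec$type == "continuous") {
    return(optimize_cutoff(table, name, spec$direction))
  }
  preds <- if (spec$type == "boolean") {
    list(filter_predicate(name, "==", TRUE),
         filter_predicate(name, "==", FALSE))
  } else {
    lapply(sort(unique(table[[name]])),
           function(v) filter_predicate(name, "in", v))
  }
  best <- NULL
  for (p in preds) {
    ev <- split_information_gain(table, p)
    if (is.null(best)) { best <- ev; next }
    ds <- retained_positive_share(ev) - retained_positive_share(best)
    if (ds > 1e-12 ||
        (abs(ds) <= 1e-12 && (ev$info_gain > best$info_gain + 1e-12 ||
                              (abs(ev$info_gain - best$info_gain) <= 1e-12 &&
                               removed_negatives(ev) >
                                 removed_negatives(best))))) {
      best <- ev
    }
  }
  best
}

# selection among per-attribute best evaluations: splits whose retained
# child loses the majority of positives defeat the filter's purpose and
# are inadmissible; among the rest, clean splits (no positive removed,
# >=1 negative removed) are preferred and ranked by negatives removed;
# otherwise the max information gain wins.
select_step <- function(evals) {
  evals <- Filter(function(e) retained_positive_share(e) > 0.5, evals)
  if (!length(evals)) return(NULL)
  clean <- Filter(function(e) removed_positives(e) == 0L &&
                    removed_negatives(e) > 0L, evals)
  pool <- if (length(clean)) clean else evals
  best <- pool[[1]]
  for (e in pool[-1]) {
    if (length(clean)) {
      if (removed_negatives(e) > removed_negatives(best) ||
          (removed_negatives(e) == removed_negatives(best) &&
           e$info_gain > best$info_gain + 1e-12)) best <- e
    } else if (e$info_gain > best$info_gain + 1e-12 ||
               (abs(e$info_gain - best$info_gain) <= 1e-12 &&
                removed_negatives(e) > removed_negatives(best))) {
      best <- e
    }
  }
  best
}

#' Build a filtering pipeline by greedy decision-list construction
#'
#' At each step every unused candidate attribute is evaluated (cutoffs
#' re-optimized) and the best split selected; only the retained child is
#' recursed on. Among attributes achieving a clean split (no positives
#' removed), the one removing the most negatives wins; otherwise the
#' maximal information gain. Construction stops when the best gain falls
#' below `epsilon` or the best step removes no negatives. With
#' `order = "global"` all cutoffs and the step order are instead fixed from
#' a single evaluation on the full parent set.
#'
#' @param table A `"feature_table"` with `"positive"`/`"negative"` labels.
#' @param candidates A [candidate_attributes()] spec.
#' @param epsilon Minimal information gain to accept a step (bits).
#' @param order `"greedy"` (default) or `"global"`.
#' @return Object of class `"filter_pipeline"`: list with `steps` (each a
#'   `"split_evaluation"` with `order_index`) and `config`.
#' @export
build_pipeline <- function(table, candidates = default_candidates(),
                           epsilon = 1e-6, order = c("greedy", "global")) {
  order <- match.arg(order)
  if (nrow(table) == 0L) stop("empty feature table")
  table$weight <- class_weights(table$label)
  avail <- names(candidates)
  steps <- list()
  if (order == "global") {
    evals <- lapply(avail, function(nm)
      evaluate_attribute(table, nm, candidates[[nm]]))
    names(evals) <- avail
    repeat {
      evals_left <- evals[avail]
      if (!length(evals_left)) break
      best <- select_step(evals_left)
      if (is.null(best) || best$info_gain < epsilon ||
          removed_negatives(best) == 0L) break
      steps[[length(steps) + 1L]] <- best
      avail <- setdiff(avail, best$attribute)
    }
    # re-run sequentially so per-step accounting reflects the list order
    current <- table
    for (i in seq_along(steps)) {
      ev <- split_information_gain(current, steps[[i]]$predicate)
      ev$order_index <- i
      steps[[i]] <- ev
      current <- current[predicate_mask(ev$predicate, current), ,
                         drop = FALSE]
    }
  } else {
    current <- table
    repeat {
      if (!length(avail) || sum(current$label == "negative") == 0L) break
      evals <- lapply(avail, function(nm)
        evaluate_attribute(current, nm, candidates[[nm]]))
      best <- select_step(evals)
      if (is.null(best) || best$info_gain < epsilon ||
          removed_negatives(best) == 0L) break
      best$order_index <- length(steps) + 1L
      steps[[length(steps) + 1L]] <- best
      avail <- setdiff(avail, best$attribute)
      current <- current[predicate_mask(best$predicate, current), ,
                         drop = FALSE]
    }
  }
  structure(list(steps = steps,
                 config = list(epsilon = epsilon, order = order,
                               weighting = "per_class",
                               candidates = candidates)),
            class = "filter_pipeline")
}

#' @export
print.filter_pipeline <- function(x, ...) {
  cat(sprintf("filter pipeline (%s order), %d step(s):\n",
              x$config$order, length(x$steps)))
  for (s in x$steps) {
    cat(sprintf("  %d. %s  (I = %.4f)\n", s$order_index,
                format_predicate(s$predicate), s$info_gain))
  }
  invisible(x)
}

#' Apply a filtering pipeline to a feature table
#'
#' Rows are filtered sequentially through the pipeline's predicates; the
#' accounting records, per step and per class, how many rows entered, were
#' retained and removed, with retention percentages.
#'
#' @param pipeline A `"filter_pipeline"`.
#' @param table A `"feature_table"` carrying every pipeline attribute.
#' @return List with `retained` (the surviving rows) and `accounting`
#'   (data.frame: step, attribute, predicate, and per-class counts).
#' @export
apply_pipeline <- function(pipeline, table) {
  for (s in pipeline$steps) {
    if (!s$attribute %in% names(table)) {
      stop("feature table lacks pipeline attribute '", s$attribute, "'")
    }
  }
  classes <- sort(unique(table$label))
  rows <- list()
  current <- table
  for (s in pipeline$steps) {
    keep <- predicate_mask(s$predicate, current)
    cnt <- function(mask, cl) sum(current$label[mask] == cl)
    for (cl in classes) {
      n_in <- sum(current$label == cl)
      rows[[length(rows) + 1L]] <- data.frame(
        step = s$order_index, attribute = s$attribute,
        predicate = format_predicate(s$predicate), class = cl,
        n_in = n_in, n_retained = cnt(keep, cl),
        n_removed = cnt(!keep, cl),
        pct_retained = if (n_in > 0) 100 * cnt(keep, cl) / n_in else NA_real_,
        stringsAsFactors = FALSE)
    }
    current <- current[keep, , drop = FALSE]
  }
  accounting <- if (length(rows)) do.call(rbind, rows) else
    data.frame(step = integer(), attribute = character(),
               predicate = character(), class = character(),
               n_in = integer(), n_retained = integer(),
               n_removed = integer(), pct_retained = numeric())
  list(retained = current, accounting = accounting)
}

#' Retention fraction of a labeled subset under a pipeline
#'
#' @param pipeline A `"filter_pipeline"`.
#' @param table A `"feature_table"`.
#' @param label Class of interest.
#' @return Fraction of `label` rows retained (NA if none present).
#' @export
retention_fraction <- function(pipeline, table, label = "positive") {
  n <- sum(table$label == label)
  if (n == 0L) return(NA_real_)
  kept <- apply_pipeline(pipeline, table)$retained
  sum(kept$label == label) / n
}

#' k-fold cross-validation of the filtering protocol
#'
#' Rows are split into k stratified, non-overlapping folds. For each fold
#' the pipeline is rebuilt (cutoffs re-optimized) on the other k-1 folds
#' and applied to the held-out fold; correctly retained positives and
#' correctly rejected negatives are counted and summed over folds.
#'
#' @param table A `"feature_table"`.
#' @param candidates A [candidate_attributes()] spec.
#' @param k Number of folds (default 3).
#' @param seed Integer seed controlling the fold assignment.
#' @param ... Passed to [build_pipeline()].
#' @return List with `per_fold` (data.frame: fold, counts, learned
#'   continuous cutoffs), `correct_positives`, `correct_negatives`,
#'   `n_positives`, `n_negatives`.
#' @export
cross_validate <- function(table, candidates = default_candidates(), k = 3,
                           seed = 1, ...) {
  stopifnot(k >= 2)
  pos_idx <- which(table$label == "positive")
  neg_idx <- which(table$label == "negative")
  if (length(pos_idx) < k) stop("k exceeds the number of positives")
  set.seed(as.integer(seed))
  fold_of <- integer(nrow(table))
  fold_of[pos_idx] <- sample(rep_len(seq_len(k), length(pos_idx)))
  fold_of[neg_idx] <- sample(rep_len(seq_len(k), length(neg_idx)))
  per_fold <- list()
  tot_pos <- 0L; tot_neg <- 0L
  cont <- names(Filter(function(s) s$type == "continuous", candidates))
  for (f in seq_len(k)) {
    train <- table[fold_of != f, , drop = FALSE]
    test <- table[fold_of == f, , drop = FALSE]
    pipe <- build_pipeline(train, candidates, ...)
    res <- apply_pipeline(pipe, test)
    cp <- sum(res$retained$label == "positive")
    cn <- sum(test$label == "negative") -
      sum(res$retained$label == "negative")
    tot_pos <- tot_pos + cp; tot_neg <- tot_neg + cn
    cuts <- vapply(cont, function(nm) {
      s <- Filter(function(x) x$attribute == nm, pipe$steps)
      if (length(s)) as.numeric(s[[1]]$predicate$value) else NA_real_
    }, numeric(1))
    row <- data.frame(fold = f, n_test_pos = sum(test$label == "positive"),
                      n_test_neg = sum(test$label == "negative"),
                      correct_positives = cp, correct_negatives = cn,
                      stringsAsFactors = FALSE)
    for (nm in cont) row[[paste0("cutoff_", nm)]] <- cuts[[nm]]
    per_fold[[f]] <- row
  }
  list(per_fold = do.call(rbind, per_fold),
       correct_positives = tot_pos, correct_negatives = tot_neg,
       n_positives = length(pos_idx), n_negatives = length(neg_idx))
}

#' Serialize a pipeline to JSON / read it back
#'
#' Steps, predicates, per-step evaluations and the full configuration are
#' written with stable key order.
#'
#' @param pipeline A `"filter_pipeline"`.
#' @param path Output JSON file.
#' @return `path` invisibly; `read_pipeline` returns a
#'   `"filter_pipeline"`.
#' @export
write_pipeline <- function(pipeline, path) {
  steps <- lapply(pipeline$steps, function(s) {
    list(order_index = s$order_index, attribute = s$attribute,
         op = s$predicate$op, value = s$predicate$value,
         info_gain = s$info_gain, parent_entropy = s$parent_entropy,
         child_entropies = s$child_entropies,
         child_probabilities = s$child_probabilities,
         retained_counts = as.list(s$retained_counts),
         removed_counts = as.list(s$removed_counts))
  })
  cfg <- pipeline$config
  cfg$candidates <- lapply(cfg$candidates, function(x) x)
  jsonlite::write_json(list(steps = steps, config = cfg), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline
#' @export
read_pipeline <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  steps <- lapply(obj$steps, function(s) {
    value <- s$value
    if (s$op == "in") value <- unlist(value)
    structure(list(attribute = s$attribute,
                   predicate = filter_predicate(s$attribute, s$op,
                                                unlist(value)),
                   info_gain = s$info_gain,
                   parent_entropy = s$parent_entropy,
                   child_entropies = unlist(s$child_entropies),
                   child_probabilities = unlist(s$child_probabilities),
                   retained_counts = unlist(s$retained_counts),
                   removed_counts = unlist(s$removed_counts),
                   order_index = s$order_index),
              class = "split_evaluation")
  })
  cfg <- obj$config
  cfg$candidates <- structure(lapply(cfg$candidates, function(x)
    lapply(x, function(v) v)), class = "candidate_spec")
  structure(list(steps = steps, config = cfg), class = "filter_pipeline")
}
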