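test_that("weighted entropy hits the textbook values", {
  expect_equal(weighted_entropy(rep("pos", 5), rep(0.2, 5)), 0)
  expect_equal(weighted_entropy(c("pos", "neg"), c(1, 1)), 1)
  expect_equal(weighted_entropy(c("a", "b"), c(0.25, 0.75)),
               -0.25 * log2(0.25) - 0.75 * log2(0.75))
  # permutation invariance and within-class scale invariance
  set.seed(31)
  lab <- sample(c("positive", "negative"), 30, replace = TRUE)
  w <- stats::runif(30)
  perm <- sample(30)
  expect_equal(weighted_entropy(lab[perm], w[perm]),
               weighted_entropy(lab, w))
  w2 <- w
  w2[lab == "positive"] <- w2[lab == "positive"] * 7
  # rescaling one class changes proportions, but rescaling ALL weights
  # uniformly does not
  expect_equal(weighted_entropy(lab, w * 3.7), weighted_entropy(lab, w))
  expect_error(weighted_entropy(lab, rep(0, 30)), "zero")
})

test_that("split information gain matches the defining equation", {
  # label-independent split: same class mix in both children
  tab <- toy_feature_table(rep(c(1, 2), 10),
                           rep(c("positive", "negative"), each = 10))
  ev <- split_information_gain(tab, filter_predicate("x", ">=", 1.5))
  expect_equal(ev$info_gain, 0, tolerance = 1e-12)
  # perfect separation: I == H_p
  tab2 <- toy_feature_table(c(rep(1, 4), rep(2, 6)),
                            c(rep("positive", 4), rep("negative", 6)))
  ev2 <- split_information_gain(tab2, filter_predicate("x", "<=", 1.5))
  expect_equal(ev2$info_gain, ev2$parent_entropy)
  expect_equal(sum(ev2$child_probabilities), 1, tolerance = 1e-9)
  expect_equal(unname(ev2$retained_counts["positive"]), 4L)
  expect_equal(unname(ev2$removed_counts["negative"]), 6L)
  # 4 positives / 6 negatives toy set against the brute-force oracle
  set.seed(32)
  vals <- stats::runif(10)
  labs <- c(rep("positive", 4), rep("negative", 6))
  tab3 <- toy_feature_table(vals, labs)
  for (cut in c(0.2, 0.5, 0.8)) {
    ev3 <- split_information_gain(tab3, filter_predicate("x", ">=", cut))
    expect_equal(ev3$info_gain,
                 oracle_gain(labs, tab3$weight, vals >= cut))
  }
  expect_error(split_information_gain(tab3,
                                      filter_predicate("nope", ">=", 1)),
               "missing")
})

test_that("information gain is bounded by the parent entropy", {
  set.seed(33)
  for (i in 1:1000) {
    n <- sample(4:24, 1)
    labs <- sample(c("positive", "negative"), n, replace = TRUE)
    if (length(unique(labs)) < 2) labs[1:2] <- c("positive", "negative")
    vals <- stats::rnorm(n)
    tab <- toy_feature_table(vals, labs)
    ev <- split_information_gain(tab,
                                 filter_predicate("x", ">=",
                                                  sample(vals, 1)))
    expect_gte(ev$info_gain, -1e-9)
    expect_lte(ev$info_gain, ev$parent_entropy + 1e-9)
  }
})

test_that("cutoff optimization is an exact exhaustive midpoint scan", {
  set.seed(34)
  pos <- stats::rnorm(50, 0.8, 0.05)
  neg <- stats::rnorm(5000, 0.3, 0.1)
  tab <- toy_feature_table(c(pos, neg),
                           c(rep("positive", 50), rep("negative", 5000)))
  best <- optimize_cutoff(tab, "x", "keep_ge")
  # independently coded scan over every midpoint
  v <- sort(unique(tab$x))
  mids <- (v[-1] + v[-length(v)]) / 2
  gains <- vapply(mids, function(cut) {
    oracle_gain(tab$label, tab$weight, tab$x >= cut)
  }, numeric(1))
  expect_equal(best$info_gain, max(gains), tolerance = 1e-12)
  expect_gt(best$predicate$value, 0.3)
  expect_lt(best$predicate$value, 0.8)
})

test_that("constant attributes are flagged non-informative", {
  tab <- toy_feature_table(rep(1, 10),
                           rep(c("positive", "negative"), 5))
  ev <- optimize_cutoff(tab, "x")
  expect_equal(ev$info_gain, 0)
  expect_true(ev$non_informative)
})

test_that("cutoff ties break toward more negatives removed, then smaller", {
  # two cutoffs achieve the same (perfect) gain only when they delimit the
  # same partition; construct distinct-partition ties via duplicated gaps
  tab <- toy_feature_table(c(1, 2, 3, 10, 11),
                           c("negative", "negative", "negative",
                             "positive", "positive"))
  ev <- optimize_cutoff(tab, "x", "keep_ge")
  # any cutoff in (3, 10) is perfect; the midpoint scan proposes 6.5 only;
  # the perfect split must be found
  expect_equal(ev$info_gain, ev$parent_entropy)
  expect_equal(unname(ev$removed_counts["negative"]), 3L)
})

test_that("greedy pipelines prefer clean splits that remove the most noise", {
  n_neg <- 110
  tab <- toy_feature_table(stats::runif(n_neg + 10),
                           c(rep("positive", 10), rep("negative", n_neg)))
  # two boolean candidates, both clean; 'big' removes 100, 'small' 10
  tab$big <- c(rep(TRUE, 10), rep(FALSE, 100), rep(TRUE, 10))
  tab$small <- c(rep(TRUE, 10), rep(TRUE, 100), rep(FALSE, 10))
  pipe <- build_pipeline(tab, candidate_attributes(
    small = list(type = "boolean"), big = list(type = "boolean")))
  expect_equal(pipe$steps[[1]]$attribute, "big")
  expect_equal(unname(pipe$steps[[1]]$removed_counts["negative"]), 100L)
})

test_that("one candidate yields a one-step pipeline; empty input errors", {
  tab <- toy_feature_table(c(rep(1, 5), rep(0, 5)),
                           c(rep("positive", 5), rep("negative", 5)))
  pipe <- build_pipeline(tab, candidate_attributes(
    x = list(type = "continuous", direction = "keep_ge")))
  expect_length(pipe$steps, 1L)
  expect_error(build_pipeline(tab[0, ], default_candidates()), "empty")
})

test_that("greedy construction recovers a planted attribute ranking", {
  set.seed(36)
  n_pos <- 40; n_neg <- 2000
  labs <- c(rep("positive", n_pos), rep("negative", n_neg))
  tab <- toy_feature_table(stats::rnorm(n_pos + n_neg), labs)
  # planted marginal separation: localization > pfam > pssm > disorder
  tab$localization <- c(rep("INT", n_pos),
                        sample(c("INT", "EXT", "TM"), n_neg, TRUE,
                               prob = c(0.3, 0.5, 0.2)))
  tab$pfam_domain <- c(rep(FALSE, n_pos),
                       sample(c(TRUE, FALSE), n_neg, TRUE,
                              prob = c(0.55, 0.45)))
  # continuous attributes with planted clean-removal fractions: negatives
  # below the positive range are removable (45% for pssm, 15% for
  # disorder); the rest mix uniformly with the positives
  mix <- function(frac_below, lo, hi) {
    below <- stats::runif(n_neg, lo - 2, lo - 0.01)
    inside <- stats::runif(n_neg, lo, hi)
    ifelse(stats::runif(n_neg) < frac_below, below, inside)
  }
  tab$pssm_score <- c(stats::runif(n_pos, 4, 6), mix(0.45, 4, 6))
  tab$iupred <- c(stats::runif(n_pos, 0.5, 0.8), mix(0.15, 0.5, 0.8))
  cand <- candidate_attributes(
    localization = list(type = "categorical"),
    pfam_domain = list(type = "boolean"),
    pssm_score = list(type = "continuous", direction = "keep_ge"),
    iupred = list(type = "continuous", direction = "keep_ge"))
  # the generator's intended ranking, verified by exhaustive
  # single-attribute evaluation on the full table: the clean categorical
  # and boolean splits rank by negatives removed
  evs <- lapply(names(cand), function(nm)
    slimgate:::evaluate_attribute(tab, nm, cand[[nm]]))
  names(evs) <- names(cand)
  clean_removed <- vapply(evs, function(ev) {
    if (slimgate:::removed_positives(ev) == 0L)
      unname(ev$removed_counts["negative"]) else -1L
  }, numeric(1))
  expect_equal(names(sort(clean_removed, decreasing = TRUE))[1:2],
               c("localization", "pfam_domain"))
  pipe <- build_pipeline(tab, cand)
  order <- vapply(pipe$steps, function(s) s$attribute, character(1))
  expect_equal(order[1:2], c("localization", "pfam_domain"))
  expect_true(which(order == "pssm_score") < which(order == "iupred"))
})

test_that("applying a pipeline matches row-by-row predicate application", {
  set.seed(37)
  tab <- toy_feature_table(stats::runif(10),
                           rep(c("positive", "negative"), 5))
  tab$flag <- sample(c(TRUE, FALSE), 10, replace = TRUE)
  pipe <- structure(list(steps = list(
    structure(list(attribute = "x",
                   predicate = filter_predicate("x", ">=", 0.3),
                   order_index = 1L), class = "split_evaluation"),
    structure(list(attribute = "flag",
                   predicate = filter_predicate("flag", "==", TRUE),
                   order_index = 2L), class = "split_evaluation")),
    config = list()), class = "filter_pipeline")
  res <- apply_pipeline(pipe, tab)
  manual <- tab[tab$x >= 0.3 & tab$flag, ]
  expect_equal(res$retained$accession, manual$accession)
  acc <- res$accounting
  expect_equal(sum(acc$n_removed[acc$step == 1]), sum(tab$x < 0.3))
  # empty pipeline is the identity
  empty <- structure(list(steps = list(), config = list()),
                     class = "filter_pipeline")
  expect_equal(nrow(apply_pipeline(empty, tab)$retained), nrow(tab))
  # a step that removes everything still yields full accounting
  pipe$steps[[1]]$predicate <- filter_predicate("x", ">=", 99)
  res2 <- apply_pipeline(pipe, tab)
  expect_equal(nrow(res2$retained), 0L)
  expect_equal(nrow(res2$accounting), 2L * 2L)
  expect_error(apply_pipeline(pipe, tab[, 1:4]), "lacks")
})

test_that("pipelines are self-consistent and serialize round-trip", {
  set.seed(38)
  labs <- c(rep("positive", 20), rep("negative", 400))
  tab <- toy_feature_table(c(stats::rnorm(20, 2), stats::rnorm(400)), labs)
  tab$flag <- c(rep(TRUE, 20), sample(c(TRUE, FALSE), 400, TRUE))
  cand <- candidate_attributes(
    x = list(type = "continuous", direction = "keep_ge"),
    flag = list(type = "boolean"))
  pipe <- build_pipeline(tab, cand)
  res <- apply_pipeline(pipe, tab)
  # the construction's own per-step retained counts equal re-application
  last <- pipe$steps[[length(pipe$steps)]]
  expect_equal(sum(res$retained$label == "positive"),
               unname(last$retained_counts["positive"]))
  path <- tempfile(fileext = ".json")
  write_pipeline(pipe, path)
  back <- read_pipeline(path)
  res2 <- apply_pipeline(back, tab)
  expect_equal(res2$retained$accession, res$retained$accession)
  expect_equal(back$steps[[1]]$info_gain, pipe$steps[[1]]$info_gain)
})

test_that("global ordering mode fixes cutoffs on the full parent set", {
  set.seed(39)
  labs <- c(rep("positive", 20), rep("negative", 500))
  tab <- toy_feature_table(c(stats::rnorm(20, 3), stats::rnorm(500)), labs)
  tab$flag <- c(rep(TRUE, 20), sample(c(TRUE, FALSE), 500, TRUE))
  cand <- candidate_attributes(
    x = list(type = "continuous", direction = "keep_ge"),
    flag = list(type = "boolean"))
  pipe <- build_pipeline(tab, cand, order = "global")
  expect_equal(pipe$config$order, "global")
  expect_gte(length(pipe$steps), 1L)
  expect_equal(retention_fraction(pipe, tab, "positive"), 1,
               tolerance = 0.15)
})

test_that("cross-validation retains held-out positives on separable data", {
  set.seed(40)
  labs <- c(rep("positive", 12), rep("negative", 300))
  tab <- toy_feature_table(c(stats::runif(12, 0.8, 1),
                             stats::runif(300, 0, 0.5)), labs)
  cand <- candidate_attributes(
    x = list(type = "continuous", direction = "keep_ge"))
  cv <- cross_validate(tab, cand, k = 3, seed = 17)
  expect_equal(cv$correct_positives, 12L)
  expect_equal(cv$correct_negatives, 300L)
  expect_equal(nrow(cv$per_fold), 3L)
  expect_error(cross_validate(tab[c(1, 13:312), ], cand, k = 3, seed = 1),
               "exceeds")
})

test_that("cross-validation equals an independent re-run of the same folds", {
  set.seed(41)
  labs <- c(rep("positive", 15), rep("negative", 200))
  tab <- toy_feature_table(c(stats::rnorm(15, 1.5, 0.6),
                             stats::rnorm(200, 0, 0.8)), labs)
  cand <- candidate_attributes(
    x = list(type = "continuous", direction = "keep_ge"))
  cv <- cross_validate(tab, cand, k = 3, seed = 7)
  # independently scripted fold assignment and evaluation
  pos_idx <- which(tab$label == "positive")
  neg_idx <- which(tab$label == "negative")
  set.seed(7L)
  fold_of <- integer(nrow(tab))
  fold_of[pos_idx] <- sample(rep_len(1:3, length(pos_idx)))
  fold_of[neg_idx] <- sample(rep_len(1:3, length(neg_idx)))
  total <- 0L
  for (f in 1:3) {
    pipe <- build_pipeline(tab[fold_of != f, ], cand)
    kept <- apply_pipeline(pipe, tab[fold_of == f, ])$retained
    total <- total + sum(kept$label == "positive")
  }
  expect_equal(cv$correct_positives, total)
})
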