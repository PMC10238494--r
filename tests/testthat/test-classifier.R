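panel_cohort <- function(n_cases = 60, n_controls = 60, n_peptides = 9,
                         fc = 1.5, cv = 0.3, seed = 1) {
  generate_cohort(cohort_spec(n_cases, n_controls, n_peptides,
                              n_differential = n_peptides, planted_fc = fc,
                              cv_biological = cv, cv_technical = 0.1,
                              seed = seed))
}

test_that("hold-out split is stratified, deterministic, leak-free", {
  out <- panel_cohort(100, 100, 4)
  qm <- out$quant
  s1 <- split_holdout(qm, eval_config(), state = 3)
  s2 <- split_holdout(qm, eval_config(), state = 3)
  expect_identical(s1, s2)

  meta <- qm$sample_meta
  train_bio <- unique(meta$replicate_of[s1$train])
  test_bio <- unique(meta$replicate_of[s1$test])
  expect_length(intersect(train_bio, test_bio), 0)
  # replicates stay together: every biological sample contributes both rows
  # to exactly one side
  expect_equal(length(s1$train) + length(s1$test), nrow(qm$values))
  # 70/30 per class at the biological level
  g <- meta$group[!duplicated(meta$replicate_of)]
  names(g) <- meta$replicate_of[!duplicated(meta$replicate_of)]
  expect_equal(sum(g[train_bio] == "case"), 70)
  expect_equal(sum(g[train_bio] == "control"), 70)
  expect_equal(length(test_bio), 60)
})

test_that("AUC rank statistic equals the pair-counting oracle", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.1, 0.2),
                        c("case", "case", "control", "control")), 1)
  expect_equal(auc_rank(rep(0.5, 6), rep(c("case", "control"), 3)), 0.5)
  set.seed(51)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    labels <- ifelse(runif(n) < 0.5, "case", "control")
    if (length(unique(labels)) < 2) next
    scores <- sample(round(runif(n), 2))  # rounding induces ties
    expect_equal(auc_rank(scores, labels), oracle_auc_pairs(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("ROC metrics are invariant under monotone score transforms", {
  set.seed(52)
  labels <- rep(c("case", "control"), each = 20)
  scores <- c(rnorm(20, 1), rnorm(20, 0))
  m1 <- roc_metrics(scores, labels, threshold = 0.5)
  m2 <- roc_metrics(exp(scores), labels, threshold = exp(0.5))
  expect_equal(m1$auc, m2$auc, tolerance = 1e-12)
  expect_equal(m1$sensitivity, m2$sensitivity)
  expect_equal(m1$specificity, m2$specificity)
})

test_that("the reference classifier learns separable panels and not noise", {
  # perfectly separated feature -> perfect training accuracy
  set.seed(50)
  x <- cbind(sep = c(rnorm(20, 5), rnorm(20, -5)), noise = rnorm(40))
  y <- rep(c("case", "control"), each = 20)
  m <- train_classifier(x, y)
  scores <- predict(m, x)
  th <- mrmpanel:::youden_threshold(scores, y)
  expect_equal(mean((scores >= th) == (y == "case")), 1)

  # a single label-tracking feature gives high test AUC
  set.seed(53)
  lab <- rep(c("case", "control"), each = 50)
  feat <- matrix((lab == "case") + rnorm(100, 0, 0.4), ncol = 1,
                 dimnames = list(NULL, "f1"))
  tr <- sample(100, 70)
  m2 <- train_classifier(feat[tr, , drop = FALSE], lab[tr])
  expect_gt(auc_rank(predict(m2, feat[-tr, , drop = FALSE]), lab[-tr]), 0.9)

  # zero-variance features are dropped with a warning
  x3 <- cbind(x, const = 1)
  expect_warning(m3 <- train_classifier(x3, y), "zero-variance")
  expect_false("const" %in% m3$kept)
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(54)
  out <- panel_cohort(40, 40, 5, seed = 9)
  agg <- aggregate_replicates(out$quant)
  feats <- log10(agg$values)
  aucs <- replicate(20, {
    lab <- sample(agg$sample_meta$group)
    tr <- sample(nrow(feats), 56)
    m <- train_classifier(feats[tr, ], lab[tr])
    auc_rank(predict(m, feats[-tr, ]), lab[-tr])
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("panel evaluation reports per-state rows plus their exact mean", {
  out <- panel_cohort(60, 60, 6, seed = 11)
  ev <- evaluate_panel(out$quant, eval_config(random_states = 1:5))
  expect_equal(nrow(ev), 6)
  states <- ev[seq_len(5), ]
  avg <- ev[6, ]
  for (col in c("auc", "sensitivity", "specificity", "accuracy")) {
    expect_equal(avg[[col]], mean(states[[col]]), tolerance = 1e-12)
    expect_true(all(ev[[col]] >= 0 & ev[[col]] <= 1))
  }
})

test_that("a strong planted panel discriminates well on held-out data", {
  out <- panel_cohort(200, 200, 9, fc = 1.5, cv = 0.3, seed = 13)
  ev <- evaluate_panel(out$quant, eval_config(random_states = 1:5))
  expect_gt(ev$auc[nrow(ev)], 0.85)
})

test_that("non-binary groups are scored but excluded from metrics", {
  out <- panel_cohort(30, 30, 4, seed = 15)
  qm <- out$quant
  # relabel a third of the controls as an other-cancer group
  other <- grepl("ctrl0(0[1-9]|10)_", qm$sample_meta$sample_id)
  qm$sample_meta$group[other] <- "other_cancer"
  ev <- evaluate_panel(qm, eval_config(random_states = 1:2))
  gs <- attr(ev, "group_scores")
  expect_true("other_cancer" %in% gs$group)
  expect_true(all(gs$score >= 0 & gs$score <= 1))
  expect_false(any(gs$in_test[gs$group == "other_cancer"]))
})
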