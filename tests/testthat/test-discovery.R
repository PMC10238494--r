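make_qm <- function(values, group, replicate_of = NULL, ids = NULL) {
  ids <- ids %||% sprintf("S%02d", seq_len(nrow(values)))
  rownames(values) <- ids
  quant_matrix(values, data.frame(
    sample_id = ids, group = group,
    replicate_of = replicate_of %||% ids, batch = "b1",
    stringsAsFactors = FALSE
  ))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("technical replicates aggregate to their mean", {
  v <- matrix(c(100, 120, 50, 70), nrow = 2,
              dimnames = list(NULL, c("p1", "p2")))
  qm <- make_qm(v, group = c("case", "case"),
                replicate_of = c("A", "A"), ids = c("A_r1", "A_r2"))
  agg <- aggregate_replicates(qm)
  expect_equal(unname(agg$values["A", ]), c(110, 60))
  expect_equal(nrow(agg$values), 1)

  # no replicates: identity
  qm2 <- make_qm(v, group = c("case", "control"))
  expect_equal(aggregate_replicates(qm2)$values, qm2$values)

  # a missing replicate falls back to the surviving value
  v3 <- v; v3[2, 1] <- NA
  qm3 <- make_qm(v3, group = c("case", "case"),
                 replicate_of = c("A", "A"), ids = c("A_r1", "A_r2"))
  expect_equal(unname(aggregate_replicates(qm3)$values["A", "p1"]), 100)
})

test_that("fold change is two-sided and inclusive at the threshold", {
  fc <- fold_change(rep(12, 3), rep(10, 3))
  expect_equal(fc$fc, 1.2)
  expect_true(mrmpanel:::passes_fc(fc$fc, 1.2))  # inclusive

  down <- fold_change(rep(10, 3), rep(12, 3))
  expect_equal(down$fc, 1 / 1.2, tolerance = 1e-12)
  expect_true(mrmpanel:::passes_fc(down$fc, 1.2))

  expect_false(mrmpanel:::passes_fc(fold_change(rep(10, 3), rep(10, 3))$fc, 1.2))

  bad <- fold_change(c(1, 2, 3), c(0, 0, 0))
  expect_false(bad$valid)
  expect_equal(bad$reason, "nonpositive_center")
})

test_that("rank-sum test is exact on small untied groups", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6)), 0.1, tolerance = 1e-12)
  expect_equal(rank_sum_test(c(5, 5, 5), c(5, 5, 5)), 1)
  set.seed(31)
  for (i in 1:20) {
    a <- runif(sample(3:6, 1))
    b <- runif(sample(3:6, 1))
    expect_equal(rank_sum_test(a, b), oracle_ranksum_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("normal approximation stays close to exact enumeration", {
  set.seed(32)
  for (i in 1:10) {
    a <- round(runif(8), 1)  # rounding forces ties -> approximation path
    b <- round(runif(8), 1)
    if (length(unique(c(a, b))) == 16 || length(unique(c(a, b))) == 1) next
    expect_lt(abs(rank_sum_test(a, b) - oracle_ranksum_p(a, b)), 0.05)
  }
})

test_that("null p-values are approximately uniform", {
  # group size 60 so the p-value lattice is fine enough for a KS check
  set.seed(33)
  p <- replicate(1000, rank_sum_test(rnorm(60), rnorm(60)))
  # p-values sit on a fine lattice; suppress the KS tie warning it causes
  suppressWarnings(ks <- stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("label swap inverts fold change and preserves p-values", {
  set.seed(34)
  a <- rlnorm(10, 5); b <- rlnorm(10, 5.2)
  expect_equal(fold_change(a, b)$fc, 1 / fold_change(b, a)$fc,
               tolerance = 1e-12)
  expect_equal(rank_sum_test(a, b), rank_sum_test(b, a), tolerance = 1e-12)
})

test_that("cascade recovers planted markers and respects direction", {
  sp <- function(ncase, nctrl, seed) {
    cohort_spec(ncase, nctrl, n_peptides = 40, n_differential = 5,
                planted_fc = 1.6, cv_biological = 0.15, cv_technical = 0.1,
                seed = seed)
  }
  ids <- sprintf("PEP%04d", 1:40)
  diff_ids <- c("PEP0003", "PEP0010", "PEP0020", "PEP0030", "PEP0040")
  disc <- generate_cohort(sp(30, 30, 1), ids, diff_ids)
  vali <- generate_cohort(sp(40, 40, 2), ids, diff_ids)
  res <- run_cascade(disc$quant, vali$quant)
  expect_setequal(res$peptide_id[res$passed_validation], diff_ids)

  # flipping the validation effect direction kills validation
  flipped <- vali$quant
  g <- flipped$sample_meta$group
  flipped$sample_meta$group <- ifelse(g == "case", "control",
                                      ifelse(g == "control", "case", g))
  res2 <- run_cascade(disc$quant, flipped)
  expect_false(any(res2$passed_validation[res2$peptide_id %in% diff_ids]))

  # peptide missing from validation fails with not_measured
  vsub <- vali$quant
  keep <- setdiff(colnames(vsub$values), "PEP0003")
  vsub <- quant_matrix(vsub$values[, keep], vsub$sample_meta)
  res3 <- run_cascade(disc$quant, vsub)
  row <- res3[res3$peptide_id == "PEP0003", ]
  expect_true(row$passed_discovery)
  expect_false(row$passed_validation)
  expect_equal(row$reason, "not_measured")
})

test_that("raising the fold-change threshold never adds survivors", {
  ids <- sprintf("PEP%04d", 1:30)
  out <- generate_cohort(cohort_spec(25, 25, 30, 6, planted_fc = 1.4,
                                     seed = 4), ids)
  counts <- vapply(c(1.1, 1.2, 1.4, 1.8), function(th) {
    res <- run_cascade(out$quant, out$quant,
                       discovery_config(fc_threshold = th))
    sum(res$passed_discovery)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("z-score tables are standardized per peptide", {
  ids <- sprintf("PEP%04d", 1:5)
  out <- generate_cohort(cohort_spec(10, 10, 5, 2, seed = 6), ids)
  agg <- aggregate_replicates(out$quant)
  tab <- zscore_heatmap_table(agg, ids)
  for (p in ids) {
    z <- tab$z[tab$peptide_id == p]
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(stats::sd(z), 1, tolerance = 1e-9)
  }
  # constant peptide -> z = 0 with a warning
  cq <- agg
  cq$values[, 1] <- 5
  expect_warning(t2 <- zscore_heatmap_table(cq, ids[1]), "zero SD")
  expect_true(all(t2$z == 0))
})
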