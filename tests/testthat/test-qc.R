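exact_pts <- function() generate_calibration_series(slope = 2, intercept = 1)

test_that("linearity fit is exact on a noiseless line", {
  r <- fit_linearity(exact_pts())
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$per_point_accuracy, rep(100, 6), tolerance = 1e-9)
  expect_true(r$accuracy_pass)
})

test_that("the 5-of-6 accuracy rule accepts one bad point, rejects two", {
  one <- exact_pts(); one$response[3] <- one$response[3] * 1.3
  r1 <- fit_linearity(one)
  expect_true(r1$accuracy_pass)
  expect_equal(sum(abs(r1$per_point_accuracy - 100) > 20), 1)

  two <- exact_pts(); two$response[c(2, 5)] <- two$response[c(2, 5)] * 1.3
  expect_false(fit_linearity(two)$accuracy_pass)

  expect_error(fit_linearity(exact_pts()[1:5, ]), ">= 6")
  flat <- data.frame(nominal_conc = rep(1, 6), response = 1:6)
  expect_error(fit_linearity(flat), "zero variance")
})

test_that("R-squared degrades monotonically with calibration noise", {
  mean_r2 <- function(cv) {
    mean(vapply(1:40, function(s) {
      fit_linearity(generate_calibration_series(slope = 2, intercept = 1,
                                                error_cv = cv,
                                                seed = s))$r_squared
    }, numeric(1)))
  }
  r2 <- vapply(c(0.02, 0.1, 0.3), mean_r2, numeric(1))
  expect_true(all(diff(r2) < 0))
})

test_that("precision CVs follow the SD/mean definition", {
  r <- assess_precision(list(day1 = c(90, 95, 100, 105, 110)))
  expect_equal(r$intra_day_cv, sd(c(90, 95, 100, 105, 110)) / 100 * 100,
               tolerance = 1e-12)
  expect_equal(round(r$intra_day_cv, 1), 7.9)
  expect_true(r$pass)

  same <- assess_precision(list(day1 = rep(50, 5), day2 = rep(50, 5)))
  expect_equal(same$intra_day_cv, 0)
  expect_equal(same$inter_day_cv, 0)
  expect_true(same$pass)

  # one noisy day fails the intra-day gate (worst day is reported)
  noisy <- assess_precision(list(day1 = rep(100, 5),
                                 day2 = c(40, 80, 100, 140, 180)))
  expect_gt(noisy$intra_day_cv, 20)
  expect_false(noisy$pass)
})

test_that("stability recovery gates at the tolerance", {
  expect_true(assess_stability(100, 100)$pass)
  r <- assess_stability(100, 70)
  expect_equal(r$recovery, 70)
  expect_false(r$pass)
  expect_true(assess_stability(100, 115)$pass)
  bad <- assess_stability(0, 50)
  expect_false(bad$pass)
  expect_equal(bad$reason, "nonpositive_day0")
})

test_that("IS quantification is the area ratio times the IS amount", {
  expect_equal(quantify_with_is(2000, 1000, 5), 10)
  expect_equal(quantify_with_is(0, 1000, 5), 0)
  expect_equal(quantify_with_is(1500, 3000, 10), 5)
  expect_error(quantify_with_is(100, 0, 5), "is_area")
  # linear in analyte area and IS amount; invariant under common scaling
  expect_equal(quantify_with_is(2 * 800, 400, 3),
               2 * quantify_with_is(800, 400, 3))
  expect_equal(quantify_with_is(800 * 7, 400 * 7, 3),
               quantify_with_is(800, 400, 3))
})

test_that("the QC gate is an AND over components with failure reasons", {
  cal_ok <- fit_linearity(exact_pts(), peptide_id = "A")
  prec_ok <- assess_precision(list(rep(100, 5)), peptide_id = "A")
  stab_ok <- assess_stability(100, 98, peptide_id = "A")
  stab_bad <- assess_stability(100, 60, peptide_id = "B")

  rep1 <- qc_gate("A", list(A = cal_ok), list(A = prec_ok), list(A = stab_ok))
  expect_true(rep1$validated)

  rep2 <- qc_gate("B", list(B = cal_ok), list(B = prec_ok), list(B = stab_bad))
  expect_false(rep2$validated)
  expect_equal(rep2$failed_tests, "stability")

  rep3 <- qc_gate("C", list(C = cal_ok), list(), list(C = stab_ok))
  expect_false(rep3$validated)
  expect_equal(rep3$failed_tests, "incomplete_qc")
})

test_that("relaxing a tolerance never de-validates a marker", {
  set.seed(41)
  ids <- sprintf("M%02d", 1:10)
  # fixed data; only the tolerances vary between the two gates
  data <- lapply(seq_along(ids), function(i) {
    list(pts = generate_calibration_series(slope = 2, intercept = 1,
                                           error_cv = 0.1, seed = i),
         reps = list(rnorm(5, 100, 8), rnorm(5, 100, 8)),
         day7 = 100 - 3 * i)
  })
  mk <- function(cfg) {
    cal <- list(); prec <- list(); stab <- list()
    for (i in seq_along(ids)) {
      cal[[ids[i]]] <- fit_linearity(data[[i]]$pts, cfg)
      prec[[ids[i]]] <- assess_precision(data[[i]]$reps, cfg)
      stab[[ids[i]]] <- assess_stability(100, data[[i]]$day7, cfg = cfg)
    }
    qc_gate(ids, cal, prec, stab)
  }
  strict <- mk(qc_config(accuracy_tolerance_pct = 15, cv_threshold_pct = 10,
                         stability_tolerance_pct = 10))
  lax <- mk(qc_config(accuracy_tolerance_pct = 25, cv_threshold_pct = 25,
                      stability_tolerance_pct = 25))
  expect_true(all(lax$validated[strict$validated]))
})
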