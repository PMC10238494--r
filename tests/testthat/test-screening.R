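test_that("peak detection recovers a noiseless Gaussian", {
  g <- make_gaussian_trace(height = 100, rt = 5)
  suppressWarnings(pk <- detect_peak(g$trace, g$time))
  expect_equal(pk$height, 100, tolerance = 2)   # 5-point smoothing bias
  expect_equal(pk$rt_min, 5, tolerance = 0.05)
  expect_gt(pk$area, 0)
  expect_true(pk$flat_noise)
  expect_identical(pk$snr, Inf)  # zero-noise sentinel, not a crash

  flat <- rep(0, 100)
  suppressWarnings(pf <- detect_peak(flat, seq(0, 10, length.out = 100)))
  expect_equal(pf$height, 0)
  expect_error(detect_peak(1:5, 1:5), ">= 10 samples")
})

test_that("SNR estimate is unbiased to within 30% at planted SNR 30", {
  snrs <- vapply(1:100, function(s) {
    g <- make_gaussian_trace(height = 300, rt = 5)
    set.seed(s)
    trace <- g$trace + rnorm(length(g$trace), 0, 10)
    detect_peak(trace, g$time)$snr
  }, numeric(1))
  expect_lt(abs(mean(snrs) - 30) / 30, 0.3)
  expect_gt(mean(abs(snrs - 30) / 30 <= 0.3), 0.9)
})

test_that("SNR and ratio similarity are scale invariant", {
  ch <- simulate_chromatogram(chromatogram_spec(peak_height = 200,
                                                noise_sd = 5, seed = 9))
  pk1 <- detect_peaks(ch)
  ch2 <- ch
  ch2$intensity <- ch$intensity * 7.5
  pk2 <- detect_peaks(ch2)
  expect_equal(vapply(pk1, `[[`, numeric(1), "snr"),
               vapply(pk2, `[[`, numeric(1), "snr"), tolerance = 1e-9)
  a1 <- vapply(pk1, `[[`, numeric(1), "area")
  a2 <- vapply(pk2, `[[`, numeric(1), "area")
  expect_equal(compare_transition_ratios(a1, a1),
               compare_transition_ratios(a1, a2), tolerance = 1e-9)
})

test_that("more noise never raises the expected SNR", {
  mean_snr <- function(noise) {
    mean(vapply(1:30, function(s) {
      ch <- simulate_chromatogram(chromatogram_spec(peak_height = 200,
                                                    noise_sd = noise,
                                                    seed = s))
      max(vapply(detect_peaks(ch), `[[`, numeric(1), "snr"))
    }, numeric(1)))
  }
  m <- vapply(c(5, 10, 20), mean_snr, numeric(1))
  expect_true(all(diff(m) < 0))
})

test_that("retention-time matching is inclusive at the tolerance", {
  pk <- function(rt) structure(list(rt_min = rt), class = "peak_call")
  cfg <- screening_config(rt_tolerance_min = 0.2)
  expect_true(match_retention_time(pk(5.00), pk(5.02), pk(5.01), cfg)$pass)
  expect_false(match_retention_time(pk(5.0), pk(7.0), pk(5.0), cfg)$pass)
  # boundary is inclusive
  expect_true(match_retention_time(pk(5.0), pk(5.2), pk(5.1), cfg)$pass)
  miss <- match_retention_time(pk(5.0), NULL, pk(5.0), cfg)
  expect_false(miss$pass)
  expect_equal(miss$reason, "missing_peak")
})

test_that("transition-ratio cosine behaves at identity, orthogonal and mixed", {
  expect_equal(compare_transition_ratios(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2)), 1)
  expect_equal(compare_transition_ratios(c(1, 0, 0), c(0, 1, 0)), 0)
  # hand-computed: dot 0.29 over norms sqrt(0.38)*sqrt(0.38)
  expect_equal(compare_transition_ratios(c(0.5, 0.3, 0.2), c(0.2, 0.3, 0.5)),
               0.29 / 0.38, tolerance = 1e-12)
  expect_equal(compare_transition_ratios(c(0, 0, 0), c(1, 1, 1)), 0)
})

test_that("quantifiability calls combine the three gates with reasons", {
  cfg <- screening_config()
  ok_rt <- list(rt_delta_min = 0.01, pass = TRUE, reason = NA_character_)
  good <- call_quantifiable("P", snr = 30, ok_rt, 0.99, cfg)
  expect_true(good$quantifiable)
  expect_true(good$high_confidence)

  low <- call_quantifiable("P", snr = 2.9, ok_rt, 0.99, cfg)
  expect_false(low$quantifiable)
  expect_equal(low$reasons, "low_snr")

  mism <- call_quantifiable("P", snr = 5, ok_rt, 0.5, cfg)
  expect_false(mism$quantifiable)
  expect_equal(mism$reasons, "ratio_mismatch")
  expect_false(call_quantifiable("P", snr = 5, ok_rt, 0.99, cfg)$high_confidence)
})

test_that("panel screening recovers planted quantifiability", {
  panel <- simulate_screening_panel(60, seed = 21)
  calls <- screen_panel(panel)
  expect_gte(mean(calls$quantifiable == panel$truth$quantifiable), 0.9)
})
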