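# MRM quantifiability screening.
#
# Decides which library peptides are quantifiable from chromatogram
# evidence. A peptide passes when (i) its best-transition SNR exceeds the
# threshold (3) inside the run window, (ii) retention times of the synthetic
# standard, the endogenous peptide and the standard spiked into sample
# agree, and (iii) the relative abundances of the top-3 product ions match
# between standard and sample. SNR is defined as apex height above a robust
# baseline divided by the robust baseline SD — instrument software does not
# publish its formula, so the definition is fixed here and config-exposed.

#' Screening configuration
#'
#' @param snr_threshold Quantifiability SNR gate (default 3).
#' @param snr_high High-confidence SNR gate (default 10).
#' @param rt_tolerance_min Maximum pairwise RT difference, minutes
#'   (inclusive boundary).
#' @param ratio_threshold Minimum cosine similarity of top-3 transition
#'   ratio vectors.
#' @param baseline_exclusion_halfwidth Minutes around the apex excluded from
#'   baseline/noise estimation.
#' @param smooth_points Moving-average window (samples) applied before apex
#'   detection.
#' @return An object of class `screening_config`.
#' @export
screening_config <- function(snr_threshold = 3, snr_high = 10,
                             rt_tolerance_min = 0.2, ratio_threshold = 0.95,
                             baseline_exclusion_halfwidth = 0.5,
                             smooth_points = 5L) {
  stopifnot_scalar_number(snr_threshold, "snr_threshold", lower = 1e-12)
  stopifnot_scalar_number(rt_tolerance_min, "rt_tolerance_min", lower = 1e-12)
  structure(list(snr_threshold = snr_threshold, snr_high = snr_high,
                 rt_tolerance_min = rt_tolerance_min,
                 ratio_threshold = ratio_threshold,
                 baseline_exclusion_halfwidth = baseline_exclusion_halfwidth,
                 smooth_points = as.integer(smooth_points)),
            class = "screening_config")
}

moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2)) -> sm
  # edges: fall back to the raw values where the window is incomplete
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

#' Detect the main peak in a single transition trace
#'
#' Apex = maximum of the smoothed trace. Baseline and noise are estimated
#' robustly (median and 1.4826*MAD) from the samples farther than
#' `baseline_exclusion_halfwidth` minutes from the apex. Peak area is the
#' trapezoidal integral of the baseline-subtracted trace (floored at 0) over
#' apex +/- 3 fitted sigmas, where sigma comes from the full width at half
#' maximum of the smoothed peak.
#'
#' @param trace Numeric intensity vector.
#' @param time_min Sample times in minutes, strictly increasing, same
#'   length as `trace` (>= 10 samples).
#' @param cfg A [screening_config()].
#' @param transition_id Identifier carried on the output.
#' @return An object of class `peak_call`: `transition_id`, `rt_min`,
#'   `height`, `area`, `noise_sd`, `snr`, `flat_noise` (TRUE when the
#'   baseline had zero dispersion and SNR is reported as `Inf`).
#' @export
detect_peak <- function(trace, time_min, cfg = screening_config(),
                        transition_id = NA_character_) {
  if (length(trace) < 10L) stop("trace needs >= 10 samples", call. = FALSE)
  if (length(trace) != length(time_min)) {
    stop("`trace` and `time_min` lengths differ", call. = FALSE)
  }
  if (any(!is.finite(trace))) stop("intensities must be finite", call. = FALSE)
  if (any(diff(time_min) <= 0)) {
    stop("`time_min` must be strictly increasing", call. = FALSE)
  }
  sm <- moving_average(trace, cfg$smooth_points)
  apex_i <- which.max(sm)
  rt <- time_min[apex_i]
  off_peak <- abs(time_min - rt) > cfg$baseline_exclusion_halfwidth
  if (!any(off_peak)) off_peak <- rep(TRUE, length(trace))  # degenerate window
  baseline <- stats::median(trace[off_peak])
  noise_sd <- stats::mad(trace[off_peak])  # 1.4826 * MAD
  height <- sm[apex_i] - baseline

  # sigma from FWHM of the smoothed, baseline-subtracted peak
  half <- baseline + height / 2
  above <- sm >= half
  left <- apex_i
  while (left > 1L && above[left - 1L]) left <- left - 1L
  right <- apex_i
  while (right < length(sm) && above[right + 1L]) right <- right + 1L
  fwhm <- time_min[right] - time_min[left]
  sigma_fit <- if (fwhm > 0) fwhm / 2.3548 else mean(diff(time_min))

  in_win <- abs(time_min - rt) <= 3 * sigma_fit
  y <- pmax(trace[in_win] - baseline, 0)
  t <- time_min[in_win]
  area <- if (length(t) > 1L) sum(diff(t) * (y[-1] + y[-length(y)]) / 2) else 0

  flat <- noise_sd == 0
  if (flat) warning("zero baseline dispersion; SNR reported as Inf")
  structure(list(transition_id = transition_id, rt_min = rt,
                 height = height, area = max(area, 0), noise_sd = noise_sd,
                 snr = if (flat) Inf else max(height, 0) / noise_sd,
                 flat_noise = flat),
            class = "peak_call")
}

#' Detect peaks on every transition of a chromatogram
#'
#' @param chrom A `chromatogram` (see [simulate_chromatogram()]).
#' @param cfg A [screening_config()].
#' @return A list of [detect_peak()] calls, one per transition, named by
#'   transition id.
#' @export
detect_peaks <- function(chrom, cfg = screening_config()) {
  stopifnot(inherits(chrom, "chromatogram"))
  calls <- lapply(seq_along(chrom$transitions), function(i) {
    detect_peak(chrom$intensity[, i], chrom$time_min, cfg,
                transition_id = chrom$transitions[i])
  })
  names(calls) <- chrom$transitions
  calls
}

#' Compare retention times across standard, sample and spiked runs
#'
#' @param standard,endogenous,spiked [detect_peak()] calls for the same
#'   peptide (any may be `NULL` when the peak is missing).
#' @param cfg A [screening_config()].
#' @return List with `rt_delta_min` (max pairwise absolute difference),
#'   `pass` (inclusive at the tolerance boundary) and `reason`.
#' @export
match_retention_time <- function(standard, endogenous, spiked,
                                 cfg = screening_config()) {
  peaks <- list(standard, endogenous, spiked)
  if (any(vapply(peaks, is.null, logical(1)))) {
    return(list(rt_delta_min = NA_real_, pass = FALSE, reason = "missing_peak"))
  }
  rts <- vapply(peaks, `[[`, numeric(1), "rt_min")
  delta <- max(stats::dist(rts))
  # inclusive boundary, robust to floating-point representation of times
  ok <- delta <= cfg$rt_tolerance_min + 1e-9
  list(rt_delta_min = delta, pass = ok,
       reason = if (ok) NA_character_ else "rt_mismatch")
}

#' Cosine similarity of top-3 transition ratio vectors
#'
#' Normalized dot product of the standard's and the sample's relative
#' product-ion abundances; 1 means identical fragmentation pattern, 0 means
#' orthogonal (or an all-zero vector).
#'
#' @param standard_areas,sample_areas Nonnegative length-3 area vectors.
#' @return Similarity in \[0, 1\].
#' @examples
#' compare_transition_ratios(c(0.5, 0.3, 0.2), c(0.2, 0.3, 0.5))
#' @export
compare_transition_ratios <- function(standard_areas, sample_areas) {
  if (length(standard_areas) != 3L || length(sample_areas) != 3L) {
    stop("expected length-3 area vectors", call. = FALSE)
  }
  if (any(standard_areas < 0) || any(sample_areas < 0)) {
    stop("areas must be nonnegative", call. = FALSE)
  }
  na <- sqrt(sum(standard_areas^2))
  nb <- sqrt(sum(sample_areas^2))
  if (na == 0 || nb == 0) return(0)
  sum(standard_areas * sample_areas) / (na * nb)
}

#' Assemble a quantifiability call from screening evidence
#'
#' @param peptide_id Identifier.
#' @param snr Best-transition SNR of the endogenous peptide.
#' @param rt_match Output of [match_retention_time()].
#' @param ratio_similarity Output of [compare_transition_ratios()].
#' @param cfg A [screening_config()].
#' @return An object of class `quantifiability_call` with fields
#'   `peptide_id`, `snr`, `rt_delta_min`, `ratio_similarity`,
#'   `quantifiable`, `high_confidence` and `reasons` (machine-readable
#'   failure codes, empty when quantifiable).
#' @export
call_quantifiable <- function(peptide_id, snr, rt_match, ratio_similarity,
                              cfg = screening_config()) {
  reasons <- character(0)
  if (!(snr > cfg$snr_threshold)) reasons <- c(reasons, "low_snr")
  if (!isTRUE(rt_match$pass)) {
    reasons <- c(reasons, rt_match$reason %||% "rt_mismatch")
  }
  if (!(ratio_similarity >= cfg$ratio_threshold)) {
    reasons <- c(reasons, "ratio_mismatch")
  }
  structure(list(peptide_id = peptide_id, snr = snr,
                 rt_delta_min = rt_match$rt_delta_min,
                 ratio_similarity = ratio_similarity,
                 quantifiable = length(reasons) == 0L,
                 high_confidence = length(reasons) == 0L && snr > cfg$snr_high,
                 reasons = reasons),
            class = "quantifiability_call")
}

#' Screen one peptide from its three chromatograms
#'
#' Runs peak detection on the standard, endogenous-sample and spiked
#' chromatograms, compares retention times and transition ratios, and emits
#' the quantifiability call. The endogenous chromatogram's best-transition
#' SNR decides the SNR gate; areas of all three transitions define the
#' ratio vectors.
#'
#' @param standard,sample,spiked `chromatogram` objects for one peptide.
#' @param cfg A [screening_config()].
#' @return A `quantifiability_call` (see [call_quantifiable()]).
#' @export
screen_peptide <- function(standard, sample, spiked,
                           cfg = screening_config()) {
  pk_std <- detect_peaks(standard, cfg)
  pk_sam <- detect_peaks(sample, cfg)
  pk_spk <- detect_peaks(spiked, cfg)
  snrs <- vapply(pk_sam, `[[`, numeric(1), "snr")
  best <- which.max(snrs)
  rtm <- match_retention_time(pk_std[[best]], pk_sam[[best]], pk_spk[[best]], cfg)
  sim <- compare_transition_ratios(
    vapply(pk_std, `[[`, numeric(1), "area"),
    vapply(pk_sam, `[[`, numeric(1), "area")
  )
  call_quantifiable(sample$peptide_id, snrs[[best]], rtm, sim, cfg)
}

#' Screen a whole panel
#'
#' @param panel Output of [simulate_screening_panel()] (or any list of
#'   per-peptide `standard`/`sample`/`spiked` chromatogram triplets).
#' @param cfg A [screening_config()].
#' @return Data frame with one row per peptide: `peptide_id`, `snr`,
#'   `rt_delta_min`, `ratio_similarity`, `quantifiable`, `high_confidence`,
#'   `reasons` (collapsed with `;`).
#' @export
screen_panel <- function(panel, cfg = screening_config()) {
  peptides <- panel$peptides %||% panel
  rows <- lapply(peptides, function(p) {
    cl <- screen_peptide(p$standard, p$sample, p$spiked, cfg)
    data.frame(peptide_id = cl$peptide_id, snr = cl$snr,
               rt_delta_min = cl$rt_delta_min,
               ratio_similarity = cl$ratio_similarity,
               quantifiable = cl$quantifiable,
               high_confidence = cl$high_confidence,
               reasons = paste(cl$reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
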