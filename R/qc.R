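# Analytical performance evaluation.
#
# Converts biomarker candidates into validated assays: calibration-curve
# linearity with back-calculated accuracy (>= 5 of 6 points within +/-20%),
# intra-/inter-day precision from 5-replicate series, 7-day storage
# stability, and internal-standard-ratio quantification. A candidate is
# validated only when every component test passes (AND gate).

#' QC tolerances
#'
#' @param accuracy_tolerance_pct Back-calculated accuracy window around
#'   100% (default 20, i.e. 80-120%).
#' @param accuracy_min_points Minimum points within tolerance; `NULL` means
#'   the generalized `n - 1` of `n` rule (5 of 6 for a 6-point curve).
#' @param cv_threshold_pct Intra- and inter-day CV acceptance (default 20,
#'   the usual bioanalytical convention; not dictated by the workflow
#'   itself).
#' @param stability_tolerance_pct Allowed deviation of 7-day recovery from
#'   100% (default 20).
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(accuracy_tolerance_pct = 20, accuracy_min_points = NULL,
                      cv_threshold_pct = 20, stability_tolerance_pct = 20) {
  structure(list(accuracy_tolerance_pct = accuracy_tolerance_pct,
                 accuracy_min_points = accuracy_min_points,
                 cv_threshold_pct = cv_threshold_pct,
                 stability_tolerance_pct = stability_tolerance_pct),
            class = "qc_config")
}

#' Calibration-curve linearity and accuracy
#'
#' Ordinary least-squares line through (nominal concentration, response);
#' per-point accuracy is the ratio of the value estimated from the linear
#' equation to the quantified (measured) value, as a percent. The curve is
#' acceptable when at least `n - 1` of the `n` points (5 of 6 for the
#' standard 6-point series) fall within the tolerance window.
#'
#' @param points Data frame with `nominal_conc` and `response` (>= 6 rows,
#'   distinct concentrations).
#' @param cfg A [qc_config()].
#' @param weighted Use 1/x weighting instead of unweighted OLS.
#' @param peptide_id Identifier carried on the result.
#' @return An object of class `calibration_result`: `slope`, `intercept`,
#'   `r_squared`, `per_point_accuracy` (percent), `accuracy_pass`,
#'   `n_points`.
#' @export
fit_linearity <- function(points, cfg = qc_config(), weighted = FALSE,
                          peptide_id = NA_character_) {
  stopifnot(is.data.frame(points),
            all(c("nominal_conc", "response") %in% names(points)))
  if (nrow(points) < 6L) stop("need >= 6 calibration points", call. = FALSE)
  if (length(unique(points$nominal_conc)) < 2L ||
      stats::var(points$nominal_conc) == 0) {
    stop("concentrations have zero variance", call. = FALSE)
  }
  w <- if (weighted) 1 / points$nominal_conc else NULL
  fit <- stats::lm(response ~ nominal_conc, data = points, weights = w)
  coefs <- stats::coef(fit)
  intercept <- unname(coefs[1]); slope <- unname(coefs[2])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((points$response - mean(points$response))^2)
  r2 <- 1 - ss_res / ss_tot
  acc <- unname(stats::fitted(fit)) / points$response * 100
  min_pts <- cfg$accuracy_min_points %||% (nrow(points) - 1L)
  within <- abs(acc - 100) <= cfg$accuracy_tolerance_pct
  structure(list(peptide_id = peptide_id, slope = slope,
                 intercept = intercept, r_squared = r2,
                 per_point_accuracy = acc,
                 accuracy_pass = sum(within) >= min_pts,
                 n_points = nrow(points)),
            class = "calibration_result")
}

#' Intra- and inter-day precision
#'
#' Intra-day CV is SD/mean within a day (the worst day is reported);
#' inter-day CV is SD/mean of the daily means. Five replicates per day is
#' the standard design.
#'
#' @param replicates_by_day List (one element per day) of numeric replicate
#'   vectors at one concentration level.
#' @param cfg A [qc_config()].
#' @param peptide_id,level Identifiers carried on the result.
#' @return An object of class `precision_result`: `intra_day_cv`,
#'   `inter_day_cv` (percent), `n_replicates`, `pass`.
#' @examples
#' assess_precision(list(day1 = c(90, 95, 100, 105, 110)))$intra_day_cv
#' @export
assess_precision <- function(replicates_by_day, cfg = qc_config(),
                             peptide_id = NA_character_, level = NA_real_) {
  stopifnot(is.list(replicates_by_day), length(replicates_by_day) >= 1L)
  cvs <- vapply(replicates_by_day, function(v) {
    m <- mean(v)
    if (!is.finite(m) || m <= 0) return(NA_real_)
    stats::sd(v) / m * 100
  }, numeric(1))
  intra <- if (anyNA(cvs)) NA_real_ else max(cvs)
  day_means <- vapply(replicates_by_day, mean, numeric(1))
  inter <- if (length(day_means) >= 2L) {
    m <- mean(day_means)
    if (m <= 0) NA_real_ else stats::sd(day_means) / m * 100
  } else 0
  pass <- !is.na(intra) && !is.na(inter) &&
    intra <= cfg$cv_threshold_pct && inter <= cfg$cv_threshold_pct
  structure(list(peptide_id = peptide_id, level = level,
                 intra_day_cv = intra, inter_day_cv = inter,
                 n_replicates = lengths(replicates_by_day),
                 pass = pass),
            class = "precision_result")
}

#' Seven-day storage stability
#'
#' Recovery = day-7 value as percent of day 0; pass when within
#' `100 +/- tolerance`. Conditions are labels (deep-freeze -80 C storage
#' and 4 C fridge storage); the temperature itself is metadata.
#'
#' @param day0,day7 Paired measurements.
#' @param condition `"deep_freeze"` or `"fridge_4C"`.
#' @param cfg A [qc_config()].
#' @param peptide_id Identifier.
#' @return An object of class `stability_result`: `recovery` (percent),
#'   `pass`, `reason`.
#' @export
assess_stability <- function(day0, day7,
                             condition = c("deep_freeze", "fridge_4C"),
                             cfg = qc_config(), peptide_id = NA_character_) {
  condition <- match.arg(condition)
  if (!is.finite(day0) || day0 <= 0) {
    return(structure(list(peptide_id = peptide_id, condition = condition,
                          day0_value = day0, day7_value = day7,
                          recovery = NA_real_, pass = FALSE,
                          reason = "nonpositive_day0"),
                     class = "stability_result"))
  }
  recovery <- day7 / day0 * 100
  structure(list(peptide_id = peptide_id, condition = condition,
                 day0_value = day0, day7_value = day7, recovery = recovery,
                 pass = abs(recovery - 100) <= cfg$stability_tolerance_pct,
                 reason = NA_character_),
            class = "stability_result")
}

#' Internal-standard-ratio quantification
#'
#' The analyte concentration is the analyte/IS peak-area ratio multiplied
#' by the known spiked amount of the heavy-isotope internal standard, in
#' the units of that amount.
#'
#' @param analyte_area,is_area Peak areas (IS area must be > 0).
#' @param is_amount Known IS amount (e.g. fmol).
#' @return Concentration in the units of `is_amount`.
#' @examples
#' quantify_with_is(2000, 1000, 5)  # 10
#' @export
quantify_with_is <- function(analyte_area, is_area, is_amount) {
  if (any(is_area <= 0)) stop("`is_area` must be > 0", call. = FALSE)
  if (any(analyte_area < 0)) stop("`analyte_area` must be >= 0", call. = FALSE)
  analyte_area / is_area * is_amount
}

#' AND-gate over the analytical QC components
#'
#' A candidate is validated only when its calibration accuracy, precision
#' and stability all pass; rejected candidates carry the failing test
#' names. Candidates with missing component results are rejected with
#' reason `incomplete_qc`.
#'
#' @param markers Character vector of candidate peptide ids.
#' @param calibration,precision,stability Named lists (by peptide id) of
#'   the corresponding result objects; `stability` may hold a list of
#'   results per peptide (one per condition), all of which must pass.
#' @return An object of class `qc_report`: data frame with `peptide_id`,
#'   `validated` and `failed_tests`.
#' @export
qc_gate <- function(markers, calibration, precision, stability) {
  rows <- lapply(markers, function(p) {
    comp <- list(calibration = calibration[[p]], precision = precision[[p]],
                 stability = stability[[p]])
    if (any(vapply(comp, is.null, logical(1)))) {
      return(data.frame(peptide_id = p, validated = FALSE,
                        failed_tests = "incomplete_qc",
                        stringsAsFactors = FALSE))
    }
    fails <- character(0)
    if (!isTRUE(comp$calibration$accuracy_pass)) fails <- c(fails, "accuracy")
    if (!isTRUE(comp$precision$pass)) fails <- c(fails, "precision")
    stab <- comp$stability
    if (inherits(stab, "stability_result")) stab <- list(stab)
    if (!all(vapply(stab, function(s) isTRUE(s$pass), logical(1)))) {
      fails <- c(fails, "stability")
    }
    data.frame(peptide_id = p, validated = length(fails) == 0L,
               failed_tests = paste(fails, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("qc_report", class(out))
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d candidates, %d validated\n",
              nrow(x), sum(x$validated)))
  NextMethod()
}
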