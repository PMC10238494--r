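# Two-stage biomarker discovery/validation cascade.
#
# Stage 1 (discovery cohort): a peptide survives when its case/control fold
# change is at least the threshold in either direction AND the two-sided
# Wilcoxon rank-sum p-value is below alpha. Stage 2 (validation cohort):
# stage-1 survivors must reproduce the fold-change criterion in the same
# direction. No multiple-testing correction is applied by default (raw
# p < 0.05); Benjamini-Hochberg is available but off by default.

#' Discovery configuration
#'
#' @param fc_threshold Fold-change gate, applied two-sided and inclusive
#'   (`fc >= threshold` or `fc <= 1/threshold`). Must be >= 1.
#' @param alpha Two-sided rank-sum significance level.
#' @param aggregate `"mean"` or `"median"`: how group centers are summarised
#'   for the fold change.
#' @param adjust_p Apply Benjamini-Hochberg correction before the alpha gate
#'   (default FALSE: raw p-values).
#' @return An object of class `discovery_config`.
#' @export
discovery_config <- function(fc_threshold = 1.2, alpha = 0.05,
                             aggregate = c("mean", "median"),
                             adjust_p = FALSE) {
  if (fc_threshold < 1) stop("`fc_threshold` must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  structure(list(fc_threshold = fc_threshold, alpha = alpha,
                 aggregate = match.arg(aggregate), adjust_p = adjust_p),
            class = "discovery_config")
}

#' Collapse technical replicates to biological samples
#'
#' Technical replicates (rows sharing `replicate_of`) are averaged per
#' peptide; missing replicate values fall back to the surviving value(s).
#'
#' @param qm A [quant_matrix()].
#' @return A [quant_matrix()] with one row per biological sample
#'   (`replicate_of == sample_id`).
#' @export
aggregate_replicates <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  meta <- qm$sample_meta
  if (anyNA(meta$replicate_of)) {
    stop("`replicate_of` must be defined for every sample", call. = FALSE)
  }
  bio_ids <- unique(meta$replicate_of)
  vals <- rowsum(qm$values, group = meta$replicate_of, na.rm = TRUE)
  counts <- rowsum((!is.na(qm$values)) * 1, group = meta$replicate_of)
  vals <- vals / counts
  vals[counts == 0] <- NA_real_
  vals <- vals[bio_ids, , drop = FALSE]
  new_meta <- meta[!duplicated(meta$replicate_of),
                   c("group", "batch"), drop = FALSE]
  new_meta <- data.frame(sample_id = bio_ids, group = new_meta$group,
                         replicate_of = bio_ids, batch = new_meta$batch,
                         stringsAsFactors = FALSE)
  rownames(vals) <- bio_ids
  quant_matrix(vals, new_meta)
}

#' Case/control fold change
#'
#' Ratio of group centers on the linear abundance scale. The gate is
#' two-sided: a peptide passes at threshold `f` when `fc >= f` or
#' `fc <= 1/f` (both inclusive).
#'
#' @param case_values,control_values Numeric abundances (>= 3 non-missing
#'   values each).
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return List with `fc`, `log2_fc` and `valid` (FALSE with a `reason`
#'   when a group center is nonpositive or a group is too small).
#' @examples
#' fold_change(c(12, 12, 12), c(10, 10, 10))$fc
#' @export
fold_change <- function(case_values, control_values,
                        aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  f <- if (aggregate == "mean") mean else stats::median
  case_values <- case_values[!is.na(case_values)]
  control_values <- control_values[!is.na(control_values)]
  if (length(case_values) < 3L || length(control_values) < 3L) {
    return(list(fc = NA_real_, log2_fc = NA_real_, valid = FALSE,
                reason = "too_few_values"))
  }
  mc <- f(case_values)
  m0 <- f(control_values)
  if (!is.finite(m0) || m0 <= 0 || mc <= 0) {
    return(list(fc = NA_real_, log2_fc = NA_real_, valid = FALSE,
                reason = "nonpositive_center"))
  }
  fc <- mc / m0
  list(fc = fc, log2_fc = log2(fc), valid = TRUE, reason = NA_character_)
}

passes_fc <- function(fc, threshold) {
  is.finite(fc) && (fc >= threshold || fc <= 1 / threshold)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when both groups have <= 50 observations and no ties;
#' otherwise the normal approximation with tie and continuity correction.
#' Degenerate all-identical input returns p = 1.
#'
#' @param case_values,control_values Numeric vectors (>= 3 values each).
#' @return Two-sided p-value.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
rank_sum_test <- function(case_values, control_values) {
  case_values <- case_values[!is.na(case_values)]
  control_values <- control_values[!is.na(control_values)]
  if (length(case_values) < 3L || length(control_values) < 3L) {
    stop("need >= 3 values per group", call. = FALSE)
  }
  if (length(unique(c(case_values, control_values))) == 1L) return(1)
  suppressWarnings(
    stats::wilcox.test(case_values, control_values, exact = NULL,
                       correct = TRUE)$p.value
  )
}

group_split <- function(qm) {
  g <- qm$sample_meta$group
  list(case = which(g == "case"), control = which(g == "control"))
}

marker_table_stage1 <- function(qm, cfg) {
  idx <- group_split(qm)
  peps <- colnames(qm$values)
  rows <- lapply(peps, function(p) {
    cv <- qm$values[idx$case, p]
    nv <- qm$values[idx$control, p]
    fcres <- fold_change(cv, nv, cfg$aggregate)
    p_val <- if (fcres$valid) rank_sum_test(cv, nv) else NA_real_
    data.frame(peptide_id = p, fold_change = fcres$fc,
               log2_fc = fcres$log2_fc, p_value = p_val,
               valid = fcres$valid, reason = fcres$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the two-stage discovery/validation cascade
#'
#' Stage 1 applies the fold-change and rank-sum filters on the discovery
#' cohort; stage 2 re-applies the fold-change filter (same direction as
#' stage 1) on the validation cohort, only for stage-1 survivors. Technical
#' replicates are aggregated first. Peptides absent from the validation
#' matrix fail validation with reason `not_measured`.
#'
#' @param discovery,validation [quant_matrix()] objects sharing peptide ids.
#' @param cfg A [discovery_config()].
#' @return An object of class `marker_results`: data frame with one row per
#'   peptide (`fold_change`, `log2_fc`, `p_value`, `fold_change_validation`,
#'   `passed_discovery`, `passed_validation`, `reason`).
#' @export
run_cascade <- function(discovery, validation, cfg = discovery_config()) {
  stopifnot(inherits(discovery, "quant_matrix"),
            inherits(validation, "quant_matrix"))
  disc <- aggregate_replicates(discovery)
  vali <- aggregate_replicates(validation)
  tab <- marker_table_stage1(disc, cfg)
  p_use <- if (cfg$adjust_p) stats::p.adjust(tab$p_value, "BH") else tab$p_value
  tab$passed_discovery <- tab$valid &
    vapply(tab$fold_change, passes_fc, logical(1), cfg$fc_threshold) &
    !is.na(p_use) & p_use < cfg$alpha

  vidx <- group_split(vali)
  tab$fold_change_validation <- NA_real_
  tab$passed_validation <- FALSE
  for (i in which(tab$passed_discovery)) {
    p <- tab$peptide_id[i]
    if (!p %in% colnames(vali$values)) {
      tab$reason[i] <- "not_measured"
      next
    }
    fcres <- fold_change(vali$values[vidx$case, p], vali$values[vidx$control, p],
                         cfg$aggregate)
    tab$fold_change_validation[i] <- fcres$fc
    same_direction <- fcres$valid &&
      sign(log(fcres$fc)) == sign(log(tab$fold_change[i]))
    tab$passed_validation[i] <- fcres$valid &&
      passes_fc(fcres$fc, cfg$fc_threshold) && same_direction
    if (!tab$passed_validation[i] && is.na(tab$reason[i])) {
      tab$reason[i] <- if (!fcres$valid) fcres$reason
                       else if (!same_direction) "direction_flip"
                       else "fc_below_threshold"
    }
  }
  rownames(tab) <- NULL
  class(tab) <- c("marker_results", class(tab))
  tab
}

#' @export
print.marker_results <- function(x, ...) {
  cat(sprintf("marker_results: %d peptides; %d passed discovery; %d passed validation\n",
              nrow(x), sum(x$passed_discovery), sum(x$passed_validation)))
  NextMethod()
}

#' Per-sample z-score table for marker heatmaps
#'
#' Standardises each marker peptide across all samples (z = (value - mean)
#' / SD) and returns a plot-ready long table with the fold change attached.
#' Zero-SD peptides get z = 0 with a warning.
#'
#' @param qm A [quant_matrix()] (aggregate replicates first if desired).
#' @param markers Character vector of peptide ids (or a `marker_results`
#'   object, in which case discovery survivors are used).
#' @return Long data frame: `peptide_id`, `sample_id`, `group`, `z`,
#'   `fold_change` (NA when unknown).
#' @export
zscore_heatmap_table <- function(qm, markers) {
  stopifnot(inherits(qm, "quant_matrix"))
  fc <- NULL
  if (inherits(markers, "marker_results")) {
    fc <- stats::setNames(markers$fold_change, markers$peptide_id)
    markers <- markers$peptide_id[markers$passed_discovery]
  }
  if (!length(markers)) stop("`markers` is empty", call. = FALSE)
  missing <- setdiff(markers, colnames(qm$values))
  if (length(missing)) {
    stop("markers not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(markers, function(p) {
    v <- qm$values[, p]
    s <- stats::sd(v)
    if (is.na(s) || s == 0) {
      warning("zero SD for peptide ", p, "; z set to 0")
      z <- rep(0, length(v))
    } else {
      z <- (v - mean(v)) / s
    }
    data.frame(peptide_id = p, sample_id = qm$sample_meta$sample_id,
               group = qm$sample_meta$group, z = z,
               fold_change = if (is.null(fc)) NA_real_ else unname(fc[p]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
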