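# End-to-end pipeline driver.
#
# Chains the stages on synthetic inputs: simulate a proteome, build the
# surrogate-peptide library (digest / score / select / compute transitions),
# screen for quantifiability, run the two-stage discovery/validation
# cascade, evaluate analytical QC, and train/evaluate the hold-out
# classifier. Every stage logs its input and output counts, so the
# library-to-validated-marker funnel is auditable from the run log.

#' Build a surrogate-peptide library from a proteome
#'
#' Digest, score, select one surrogate per protein, and compute light and
#' heavy transition sets.
#'
#' @param proteome Data frame with `protein_id`, `sequence`.
#' @param cfg A [selection_config()].
#' @return List with `candidates` (all scored tryptic candidates),
#'   `selected` (chosen surrogates) and `transitions` (named list of
#'   light/heavy `transition_set` pairs per selected peptide).
#' @export
build_library <- function(proteome, cfg = selection_config()) {
  digested <- do.call(rbind, lapply(seq_len(nrow(proteome)), function(i) {
    digest_tryptic(proteome$sequence[i], proteome$protein_id[i])
  }))
  scored <- score_candidate(digested[digested$tryptic, , drop = FALSE], cfg)
  selected <- select_surrogates(scored, cfg)
  transitions <- list()
  for (i in seq_len(nrow(selected))) {
    seqs <- selected$sequence[i]
    labels <- if (substring(seqs, nchar(seqs), nchar(seqs)) %in% c("K", "R")) {
      c("light", "heavy")
    } else "light"
    for (lb in labels) {
      transitions[[length(transitions) + 1L]] <- compute_mz(seqs, label_state = lb)
      names(transitions)[length(transitions)] <- selected$protein_id[i]
    }
  }
  list(candidates = scored, selected = selected, transitions = transitions)
}

log_stage <- function(log_lines, stage, n_in, n_out, note = "") {
  line <- sprintf("[%s] in=%d out=%d %s", stage, n_in, n_out, note)
  message(line)
  c(log_lines, line)
}

#' Run the full pipeline on synthetic data
#'
#' Executes every stage with the given configuration and seed, writing all
#' outputs (FASTA, transition list, screening table, marker table, QC
#' report, hold-out metrics, resolved config, run log) into `out_dir`.
#' Identical config + seed reproduce identical outputs.
#'
#' @param config Path to a JSON config, a config list from
#'   [read_pipeline_config()], or `NULL` for the packaged defaults.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the config seed.
#' @return Invisibly, a list with the stage results and the funnel counts.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("mrmpanel_run_"),
                         seed = NULL) {
  cfg <- if (is.list(config)) config else read_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  validate_pipeline_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)

  # stage 1: proteome
  prot <- generate_proteome(proteome_spec(
    n_proteins = cfg$proteome$n_proteins,
    length_range = c(cfg$proteome$length_min, cfg$proteome$length_max),
    seed = derive_seed(cfg$seed, 1L)
  ))
  write_fasta(prot, file.path(out_dir, "proteome.fasta"))
  log_lines <- log_stage(log_lines, "proteome", cfg$proteome$n_proteins,
                         nrow(prot))

  # stage 2: library construction
  sel_cfg <- selection_config(
    length_min = cfg$selection$length_min,
    length_max = cfg$selection$length_max,
    gravy_bounds = c(cfg$selection$gravy_low, cfg$selection$gravy_high),
    max_peptides_per_protein = cfg$selection$max_peptides_per_protein,
    seed = derive_seed(cfg$seed, 2L)
  )
  lib <- build_library(prot, sel_cfg)
  write_transition_list(lib$transitions, file.path(out_dir, "transitions.csv"))
  log_lines <- log_stage(log_lines, "library", nrow(lib$candidates),
                         nrow(lib$selected), "candidates -> surrogates")

  # stage 3: quantifiability screening (simulated chromatogram evidence)
  scr_cfg <- screening_config(snr_threshold = cfg$screening$snr_threshold,
                              snr_high = cfg$screening$snr_high,
                              rt_tolerance_min = cfg$screening$rt_tolerance_min,
                              ratio_threshold = cfg$screening$ratio_threshold)
  panel <- simulate_screening_panel(
    n_peptides = nrow(lib$selected),
    snr_levels = cfg$screening$snr_levels,
    noise_sd = cfg$screening$noise_sd,
    seed = derive_seed(cfg$seed, 3L)
  )
  calls <- screen_panel(panel, scr_cfg)
  calls$sequence <- lib$selected$sequence[seq_len(nrow(calls))]
  utils::write.csv(calls, file.path(out_dir, "screening.csv"),
                   row.names = FALSE)
  quantifiable <- calls$sequence[calls$quantifiable]
  log_lines <- log_stage(log_lines, "screening", nrow(calls),
                         length(quantifiable), "quantifiable peptides")

  # stage 4: discovery/validation cascade on planted cohorts
  n_pep <- length(quantifiable)
  if (n_pep < 4L) stop("too few quantifiable peptides to run the cascade")
  n_diff <- min(cfg$cohort$n_differential, max(n_pep %/% 2L, 1L))
  diff_ids <- with_seed(derive_seed(cfg$seed, 4L),
                        sample(quantifiable, n_diff))
  mk_cohort <- function(n_cases, n_controls, stream) {
    generate_cohort(
      cohort_spec(n_cases = n_cases, n_controls = n_controls,
                  n_peptides = n_pep, n_differential = n_diff,
                  planted_fc = cfg$cohort$planted_fc,
                  cv_biological = cfg$cohort$cv_biological,
                  cv_technical = cfg$cohort$cv_technical,
                  n_tech_reps = cfg$cohort$n_tech_reps,
                  seed = derive_seed(cfg$seed, stream)),
      peptide_ids = quantifiable, differential_ids = diff_ids
    )
  }
  disc <- mk_cohort(cfg$cohort$n_cases_discovery,
                    cfg$cohort$n_controls_discovery, 5L)
  vali <- mk_cohort(cfg$cohort$n_cases_validation,
                    cfg$cohort$n_controls_validation, 6L)
  disc_cfg <- discovery_config(fc_threshold = cfg$discovery$fc_threshold,
                               alpha = cfg$discovery$alpha)
  markers <- run_cascade(disc$quant, vali$quant, disc_cfg)
  utils::write.table(markers, file.path(out_dir, "markers.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  survivors <- markers$peptide_id[markers$passed_validation]
  log_lines <- log_stage(log_lines, "cascade", n_pep,
                         length(survivors),
                         sprintf("(stage1=%d)", sum(markers$passed_discovery)))

  # stage 5: analytical QC on cascade survivors
  qcfg <- qc_config(accuracy_tolerance_pct = cfg$qc$accuracy_tolerance_pct,
                    cv_threshold_pct = cfg$qc$cv_threshold_pct,
                    stability_tolerance_pct = cfg$qc$stability_tolerance_pct)
  qc_seed <- derive_seed(cfg$seed, 7L)
  n_fail <- min(cfg$qc$n_fail_qc, length(survivors))
  fail_set <- utils::head(survivors, n_fail)  # engineered stability failures
  calib <- list(); precis <- list(); stab <- list()
  for (i in seq_along(survivors)) {
    p <- survivors[i]
    pts <- generate_calibration_series(error_cv = cfg$qc$calibration_error_cv,
                                       slope = 2, intercept = 1,
                                       seed = derive_seed(qc_seed, i))
    calib[[p]] <- fit_linearity(pts, qcfg, peptide_id = p)
    reps <- with_seed(derive_seed(qc_seed, 100L + i), {
      lapply(1:3, function(d) 100 * rlnorm_cv(5L, cfg$qc$precision_cv))
    })
    precis[[p]] <- assess_precision(reps, qcfg, peptide_id = p)
    recov <- if (p %in% fail_set) 0.7 else 1.0
    stab[[p]] <- list(
      assess_stability(100, 100 * recov, "deep_freeze", qcfg, p),
      assess_stability(100, 100 * min(recov + 0.02, 1), "fridge_4C", qcfg, p)
    )
  }
  report <- qc_gate(survivors, calib, precis, stab)
  utils::write.csv(report, file.path(out_dir, "qc_report.csv"),
                   row.names = FALSE)
  validated <- report$peptide_id[report$validated]
  log_lines <- log_stage(log_lines, "qc", length(survivors), length(validated))

  # stage 6: hold-out classifier evaluation on the validated panel
  if (length(validated) >= 1L) {
    panel_qm <- vali$quant
    panel_qm <- quant_matrix(panel_qm$values[, validated, drop = FALSE],
                             panel_qm$sample_meta)
    ev_cfg <- eval_config(train_fraction = cfg$evaluation$train_fraction,
                          random_states = vapply(
                            cfg$evaluation$random_states,
                            function(s) derive_seed(cfg$seed, 200L + s),
                            integer(1)),
                          lambda = cfg$evaluation$lambda)
    metrics <- evaluate_panel(panel_qm, ev_cfg)
    utils::write.csv(as.data.frame(metrics)[, c("label", "specificity",
                                                "sensitivity", "auc",
                                                "accuracy")],
                     file.path(out_dir, "metrics.csv"), row.names = FALSE)
    log_lines <- log_stage(log_lines, "evaluate", length(validated),
                           nrow(metrics) - 1L, "random states")
  } else {
    metrics <- NULL
    log_lines <- log_stage(log_lines, "evaluate", 0L, 0L, "skipped: no panel")
  }

  jsonlite::write_json(cfg, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(
    proteome = prot, library = lib, screening = calls, markers = markers,
    qc_report = report, metrics = metrics, out_dir = out_dir,
    funnel = c(proteins = nrow(prot), candidates = nrow(lib$candidates),
               surrogates = nrow(lib$selected),
               quantifiable = length(quantifiable),
               discovery = sum(markers$passed_discovery),
               validation = length(survivors),
               validated = length(validated))
  ))
}
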