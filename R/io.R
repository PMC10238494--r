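# File formats: FASTA, Skyline-style transition lists, long-format
# chromatogram CSV, quantification TSV, and the JSON pipeline config.

#' Read a protein FASTA file
#'
#' Sequences are uppercased; duplicate ids are an error. The id is the
#' first whitespace-delimited token of the header.
#'
#' @param path FASTA file path.
#' @return Data frame with `protein_id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  aas <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aas), "\\s+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  data.frame(protein_id = unname(ids),
             sequence = unname(toupper(as.character(aas))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a protein FASTA file
#'
#' @param proteins Data frame with `protein_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  aas <- Biostrings::AAStringSet(proteins$sequence)
  names(aas) <- proteins$protein_id
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}

fmt6 <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))

#' Write a Skyline-style transition list
#'
#' One row per (peptide, product ion); numeric m/z columns are written with
#' six decimals so that write/read/write round-trips byte-identically.
#'
#' @param transition_sets List of `transition_set` objects (see
#'   [compute_mz()]); names (or an attached `protein_id` attribute per set)
#'   populate the `protein_id` column.
#' @param path Output CSV path.
#' @param collision_energy Optional numeric vector (recycled) carried as an
#'   opaque metadata column.
#' @return `path`, invisibly.
#' @export
write_transition_list <- function(transition_sets, path,
                                  collision_energy = NA_real_) {
  prot <- names(transition_sets) %||% rep(NA_character_, length(transition_sets))
  ce <- rep_len(collision_energy, length(transition_sets))
  rows <- lapply(seq_along(transition_sets), function(i) {
    ts <- transition_sets[[i]]
    pi <- ts$product_ions
    k <- nrow(pi)  # 0 for peptides too short to fragment
    data.frame(
      protein_id = rep(prot[i], k),
      peptide = rep(ts$sequence, k),
      precursor_mz = rep(fmt6(ts$precursor_mz), k),
      precursor_charge = rep(ts$precursor_charge, k),
      fragment_ion = paste0(pi$ion_type, pi$index),
      product_mz = fmt6(pi$mz),
      label_state = rep(ts$label_state, k),
      heavy_shift = rep(fmt6(ts$heavy_shift), k),
      collision_energy = rep(fmt6(ce[i]), k),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a transition list written by [write_transition_list()]
#'
#' @param path CSV path.
#' @return Data frame with numeric m/z columns.
#' @export
read_transition_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(precursor_mz = "numeric",
                                       product_mz = "numeric",
                                       heavy_shift = "numeric"))
  df
}

#' Write chromatograms as long-format CSV
#'
#' Columns: `peptide_id`, `transition_id`, `time_min`, `intensity`.
#'
#' @param chromatograms List of `chromatogram` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_chromatogram_csv <- function(chromatograms, path) {
  rows <- lapply(chromatograms, function(ch) {
    do.call(rbind, lapply(seq_along(ch$transitions), function(i) {
      data.frame(peptide_id = ch$peptide_id,
                 transition_id = ch$transitions[i],
                 time_min = ch$time_min,
                 intensity = ch$intensity[, i],
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a quantification matrix as TSV (values + sample metadata)
#'
#' @param qm A [quant_matrix()].
#' @param path Values TSV path (first column `sample_id`); the companion
#'   metadata file is written next to it with suffix `.meta.tsv`.
#' @return `path`, invisibly.
#' @export
write_quant_matrix <- function(qm, path) {
  stopifnot(inherits(qm, "quant_matrix"))
  df <- data.frame(sample_id = rownames(qm$values), qm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(qm$sample_meta, paste0(path, ".meta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a quantification matrix written by [write_quant_matrix()]
#'
#' @param path Values TSV path.
#' @return A [quant_matrix()].
#' @export
read_quant_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.delim(paste0(path, ".meta.tsv"),
                            stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$sample_id
  quant_matrix(vals, meta)
}

# ---- pipeline configuration -------------------------------------------------

default_pipeline_config <- function() {
  list(
    seed = 1L,
    proteome = list(n_proteins = 40L, length_min = 80L, length_max = 300L),
    selection = list(length_min = 6L, length_max = 16L,
                     gravy_low = -2, gravy_high = 2,
                     max_peptides_per_protein = 1L),
    screening = list(snr_threshold = 3, snr_high = 10, rt_tolerance_min = 0.2,
                     ratio_threshold = 0.95, noise_sd = 10,
                     snr_levels = c(0.5, 2, 5, 20, 100)),
    cohort = list(n_cases_discovery = 50L, n_controls_discovery = 50L,
                  n_cases_validation = 96L, n_controls_validation = 95L,
                  n_differential = 8L, planted_fc = 1.5,
                  cv_biological = 0.2, cv_technical = 0.2, n_tech_reps = 2L),
    discovery = list(fc_threshold = 1.2, alpha = 0.05),
    qc = list(accuracy_tolerance_pct = 20, cv_threshold_pct = 20,
              stability_tolerance_pct = 20, calibration_error_cv = 0.05,
              precision_cv = 0.05, n_fail_qc = 2L),
    evaluation = list(train_fraction = 0.7, random_states = 1:5,
                      lambda = 0.01)
  )
}

#' Read and validate a pipeline configuration (JSON)
#'
#' Unknown keys at the top or section level are rejected; missing keys fall
#' back to package defaults. The resolved configuration is what
#' [run_pipeline()] writes next to its outputs.
#'
#' @param path JSON config path, or `NULL` for the packaged defaults.
#' @return A named list of section configs.
#' @export
read_pipeline_config <- function(path = NULL) {
  defaults <- default_pipeline_config()
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("no such config: ", path, call. = FALSE)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (section in names(user)) {
    if (is.list(defaults[[section]])) {
      bad <- setdiff(names(user[[section]]), names(defaults[[section]]))
      if (length(bad)) {
        stop(sprintf("unknown key(s) in `%s`: %s", section,
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
      defaults[[section]][names(user[[section]])] <- user[[section]]
    } else {
      defaults[[section]] <- user[[section]]
    }
  }
  validate_pipeline_config(defaults)
  defaults
}

validate_pipeline_config <- function(cfg) {
  if (cfg$discovery$fc_threshold < 1) {
    stop("discovery.fc_threshold must be >= 1", call. = FALSE)
  }
  if (cfg$cohort$planted_fc <= 0) {
    stop("cohort.planted_fc must be > 0", call. = FALSE)
  }
  if (cfg$screening$snr_threshold <= 0) {
    stop("screening.snr_threshold must be > 0", call. = FALSE)
  }
  invisible(cfg)
}
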