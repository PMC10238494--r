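# Synthetic-data generators.
#
# Every downstream stage (library construction, MRM screening, the
# discovery/validation cascade, analytical QC, classifier evaluation) can be
# exercised on data produced here, with the ground truth recorded so that
# estimator output can be compared to planted values. The generators emulate:
# a blood-like proteome, Gaussian elution peaks with baseline noise inside a
# 10-minute MRM window, case/control serum cohorts with planted fold
# changes, and 6-point calibration plus 5-replicate precision series.

#' Specification of a synthetic proteome
#'
#' @param n_proteins Number of proteins to generate (>= 0).
#' @param length_range Integer vector (min, max) protein length in residues.
#' @param aa_frequencies Optional named numeric vector of amino-acid
#'   sampling probabilities over the 20 standard residues; must be
#'   nonnegative and sum to 1 (within 1e-9). Default: uniform.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `proteome_spec`.
#' @export
proteome_spec <- function(n_proteins, length_range = c(50L, 400L),
                          aa_frequencies = NULL, seed = 1L) {
  if (!is_count(n_proteins)) stop("`n_proteins` must be a count >= 0", call. = FALSE)
  if (length(length_range) != 2L || any(length_range < 1) ||
      length_range[1] > length_range[2]) {
    stop("`length_range` must be (min, max) with min >= 1", call. = FALSE)
  }
  if (is.null(aa_frequencies)) {
    aa_frequencies <- stats::setNames(rep(1 / 20, 20), AA_LETTERS)
  }
  if (is.null(names(aa_frequencies)) ||
      !setequal(names(aa_frequencies), AA_LETTERS)) {
    stop("`aa_frequencies` must be named by the 20 standard residues",
         call. = FALSE)
  }
  aa_frequencies <- aa_frequencies[AA_LETTERS]
  if (any(aa_frequencies < 0) || abs(sum(aa_frequencies) - 1) > 1e-9) {
    stop("`aa_frequencies` must be nonnegative and sum to 1", call. = FALSE)
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 aa_frequencies = aa_frequencies,
                 seed = as.integer(seed)),
            class = "proteome_spec")
}

#' Generate a synthetic proteome
#'
#' Draws protein sequences i.i.d. from the spec's amino-acid frequencies, as
#' a stand-in for a curated blood-detectable protein list.
#'
#' @param spec A [proteome_spec()].
#' @return A data frame with columns `protein_id` and `sequence`.
#' @examples
#' prot <- generate_proteome(proteome_spec(n_proteins = 3, seed = 42))
#' prot$protein_id
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "proteome_spec"))
  if (spec$n_proteins == 0L) {
    return(data.frame(protein_id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  with_seed(spec$seed, {
    lens <- sample(seq.int(spec$length_range[1], spec$length_range[2]),
                   spec$n_proteins, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_LETTERS, L, replace = TRUE,
                   prob = spec$aa_frequencies), collapse = "")
    }, character(1))
    data.frame(
      protein_id = sprintf("PROT%04d", seq_len(spec$n_proteins)),
      sequence = seqs,
      stringsAsFactors = FALSE
    )
  })
}

#' Specification of a simulated MRM chromatogram
#'
#' Describes one peptide's elution in a short-gradient MRM run: a Gaussian
#' peak split across the top-3 product-ion transitions, over additive
#' Gaussian baseline noise. The noise model is a package choice; instrument
#' baselines are not strictly Gaussian but this is adequate for screening
#' logic.
#'
#' @param run_minutes Run length in minutes (default 10, the short-gradient
#'   window used for quantifiability screening).
#' @param sampling_hz Sampling rate in points per second.
#' @param peak_rt Apex retention time in minutes, within `[0, run_minutes]`.
#' @param peak_width_sigma Gaussian peak sigma in minutes.
#' @param peak_height Total apex intensity summed over transitions.
#' @param noise_sd Baseline noise standard deviation (intensity units).
#' @param transition_ratios Length-3 nonnegative fractions of the top-3
#'   product ions; must sum to 1.
#' @param seed Integer seed.
#' @return An object of class `chromatogram_spec`.
#' @export
chromatogram_spec <- function(run_minutes = 10, sampling_hz = 2,
                              peak_rt = 5, peak_width_sigma = 0.05,
                              peak_height = 100, noise_sd = 0,
                              transition_ratios = c(0.5, 0.3, 0.2),
                              seed = 1L) {
  if (!is.numeric(sampling_hz) || sampling_hz <= 0) {
    stop("`sampling_hz` must be > 0", call. = FALSE)
  }
  stopifnot_scalar_number(run_minutes, "run_minutes", lower = 1e-6)
  stopifnot_scalar_number(peak_rt, "peak_rt", lower = 0, upper = run_minutes)
  stopifnot_scalar_number(peak_width_sigma, "peak_width_sigma", lower = 1e-9)
  stopifnot_scalar_number(peak_height, "peak_height", lower = 0)
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (length(transition_ratios) != 3L || any(transition_ratios < 0) ||
      abs(sum(transition_ratios) - 1) > 1e-9) {
    stop("`transition_ratios` must be 3 nonnegative fractions summing to 1",
         call. = FALSE)
  }
  structure(list(run_minutes = run_minutes, sampling_hz = sampling_hz,
                 peak_rt = peak_rt, peak_width_sigma = peak_width_sigma,
                 peak_height = peak_height, noise_sd = noise_sd,
                 transition_ratios = transition_ratios,
                 seed = as.integer(seed)),
            class = "chromatogram_spec")
}

#' Simulate an MRM chromatogram
#'
#' @param spec A [chromatogram_spec()].
#' @param peptide_id Identifier carried on the output.
#' @return An object of class `chromatogram`: list with `peptide_id`,
#'   `transitions` (ids), `time_min`, `intensity` (matrix, one column per
#'   transition) and `run_minutes`.
#' @examples
#' chrom <- simulate_chromatogram(chromatogram_spec(peak_height = 100))
#' round(apply(chrom$intensity, 2, max))
#' @export
simulate_chromatogram <- function(spec, peptide_id = "PEP1") {
  stopifnot(inherits(spec, "chromatogram_spec"))
  n <- floor(spec$run_minutes * 60 * spec$sampling_hz) + 1L
  time_min <- seq(0, spec$run_minutes, length.out = n)
  shape <- exp(-(time_min - spec$peak_rt)^2 / (2 * spec$peak_width_sigma^2))
  transitions <- paste0("y", seq_len(3L))
  intensity <- with_seed(spec$seed, {
    vapply(seq_len(3L), function(i) {
      spec$peak_height * spec$transition_ratios[i] * shape +
        stats::rnorm(n, 0, spec$noise_sd)
    }, numeric(n))
  })
  colnames(intensity) <- transitions
  structure(list(peptide_id = peptide_id, transitions = transitions,
                 time_min = time_min, intensity = intensity,
                 run_minutes = spec$run_minutes),
            class = "chromatogram")
}

#' Specification of a synthetic case/control cohort
#'
#' Emulates serum MRM quantification of a peptide panel over cases and
#' controls: per-peptide base abundances are log10-uniform over \[3, 8\]
#' (matching the observed MRM intensity dynamic range of blood peptides),
#' a chosen subset of peptides is multiplied by `planted_fc` in cases, and
#' biological/technical variability enters as mean-one multiplicative
#' log-normal noise.
#'
#' @param n_cases,n_controls Biological sample counts per group.
#' @param n_peptides Panel size.
#' @param n_differential Number of peptides carrying the planted effect
#'   (<= `n_peptides`).
#' @param planted_fc Case/control fold change planted on differential
#'   peptides (> 0; 1 means no effect).
#' @param cv_biological,cv_technical Coefficients of variation (fractions)
#'   of the biological and technical log-normal noise.
#' @param n_tech_reps Technical replicates per biological sample (default 2,
#'   the usual shuffled-duplicate MRM design).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases, n_controls, n_peptides, n_differential,
                        planted_fc = 1.5, cv_biological = 0.2,
                        cv_technical = 0.2, n_tech_reps = 2L, seed = 1L) {
  for (nm in c("n_cases", "n_controls", "n_peptides", "n_differential")) {
    if (!is_count(get(nm))) stop(sprintf("`%s` must be a count", nm), call. = FALSE)
  }
  if (n_differential > n_peptides) {
    stop("`n_differential` must not exceed `n_peptides`", call. = FALSE)
  }
  stopifnot_scalar_number(planted_fc, "planted_fc", lower = 1e-12)
  stopifnot_scalar_number(cv_biological, "cv_biological", lower = 0)
  stopifnot_scalar_number(cv_technical, "cv_technical", lower = 0)
  if (!is_count(n_tech_reps, min = 1L)) {
    stop("`n_tech_reps` must be a count >= 1", call. = FALSE)
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_peptides = as.integer(n_peptides),
                 n_differential = as.integer(n_differential),
                 planted_fc = planted_fc, cv_biological = cv_biological,
                 cv_technical = cv_technical,
                 n_tech_reps = as.integer(n_tech_reps),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# mean-one multiplicative log-normal draws with coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic case/control cohort with known ground truth
#'
#' @param spec A [cohort_spec()].
#' @param peptide_ids Optional character vector of `n_peptides` peptide ids
#'   (default `PEP0001...`).
#' @param differential_ids Optional subset of `peptide_ids` to carry the
#'   planted effect; when `NULL`, `n_differential` peptides are drawn at
#'   random. Supplying the same set to two calls builds paired
#'   discovery/validation cohorts sharing their ground truth.
#' @return A list with `quant` (a [quant_matrix()]) and `truth`, a list with
#'   `differential_peptide_ids` and `true_fc` (named per-peptide fold
#'   changes; 1 for non-differential peptides). When `planted_fc == 1` the
#'   differential set is empty by definition.
#' @export
generate_cohort <- function(spec, peptide_ids = NULL, differential_ids = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(peptide_ids)) {
    peptide_ids <- sprintf("PEP%04d", seq_len(spec$n_peptides))
  }
  stopifnot(length(peptide_ids) == spec$n_peptides)
  if (!is.null(differential_ids) &&
      !all(differential_ids %in% peptide_ids)) {
    stop("`differential_ids` must be a subset of `peptide_ids`", call. = FALSE)
  }
  bio_ids <- c(sprintf("case%03d", seq_len(spec$n_cases)),
               sprintf("ctrl%03d", seq_len(spec$n_controls)))
  group <- rep(c("case", "control"), c(spec$n_cases, spec$n_controls))

  with_seed(spec$seed, {
    diff_idx <- if (!is.null(differential_ids)) {
      sort(match(differential_ids, peptide_ids))
    } else if (spec$n_differential > 0) {
      sort(sample.int(spec$n_peptides, spec$n_differential))
    } else integer(0)
    base <- 10^stats::runif(spec$n_peptides, 3, 8)
    fc_vec <- rep(1, spec$n_peptides)
    fc_vec[diff_idx] <- spec$planted_fc

    n_bio <- length(bio_ids)
    # biological truth per sample x peptide
    bio_vals <- matrix(rep(base, each = n_bio), nrow = n_bio)
    case_rows <- group == "case"
    bio_vals[case_rows, ] <- sweep(bio_vals[case_rows, , drop = FALSE], 2,
                                   fc_vec, `*`)
    bio_vals <- bio_vals *
      matrix(rlnorm_cv(n_bio * spec$n_peptides, spec$cv_biological),
             nrow = n_bio)

    # technical replicates share the biological draw
    rep_rows <- rep(seq_len(n_bio), each = spec$n_tech_reps)
    values <- bio_vals[rep_rows, , drop = FALSE] *
      matrix(rlnorm_cv(length(rep_rows) * spec$n_peptides, spec$cv_technical),
             nrow = length(rep_rows))
    sample_id <- paste0(bio_ids[rep_rows], "_r",
                        rep(seq_len(spec$n_tech_reps), times = n_bio))
    rownames(values) <- sample_id
    colnames(values) <- peptide_ids

    meta <- data.frame(
      sample_id = sample_id,
      group = group[rep_rows],
      replicate_of = bio_ids[rep_rows],
      batch = "batch1",
      stringsAsFactors = FALSE
    )
    truth_ids <- if (spec$planted_fc == 1) character(0) else peptide_ids[diff_idx]
    truth_fc <- stats::setNames(rep(1, spec$n_peptides), peptide_ids)
    truth_fc[truth_ids] <- spec$planted_fc
    list(
      quant = quant_matrix(values, meta),
      truth = list(differential_peptide_ids = truth_ids, true_fc = truth_fc)
    )
  })
}

#' Simulate a quantifiability-screening panel with planted SNR truth
#'
#' For each peptide, three chromatograms are generated (synthetic standard,
#' endogenous sample, standard spiked into sample) sharing retention time
#' and transition ratios. Planted SNR refers to the best (most intense)
#' transition — the same convention the screening module estimates — so the
#' endogenous best-transition peak height is `true_snr * noise_sd`. Ground
#' truth labels a peptide quantifiable when its planted SNR exceeds the
#' screening threshold of 3.
#'
#' @param n_peptides Panel size.
#' @param snr_levels Planted SNR values sampled uniformly per peptide.
#' @param noise_sd Baseline noise SD for all traces.
#' @param standard_snr Planted SNR of the synthetic-standard traces (high:
#'   standards are injected at comfortable amounts).
#' @param seed Integer seed.
#' @return A list with `peptides` (list per peptide of `standard`, `sample`,
#'   `spiked` chromatograms and `rt`) and `truth` (data frame with
#'   `peptide_id`, `true_snr`, `quantifiable`).
#' @export
simulate_screening_panel <- function(n_peptides, snr_levels = c(0.5, 2, 5, 20, 100),
                                     noise_sd = 10, standard_snr = 100,
                                     seed = 1L) {
  stopifnot(is_count(n_peptides, min = 1L))
  with_seed(seed, {
    ids <- sprintf("PEP%04d", seq_len(n_peptides))
    true_snr <- sample(snr_levels, n_peptides, replace = TRUE)
    rts <- stats::runif(n_peptides, 1, 9)
    seeds <- sample.int(2^30, 3L * n_peptides)
    peptides <- vector("list", n_peptides)
    for (i in seq_len(n_peptides)) {
      mk <- function(height, s) {
        simulate_chromatogram(
          chromatogram_spec(peak_rt = rts[i], peak_height = height,
                            noise_sd = noise_sd, seed = s),
          peptide_id = ids[i]
        )
      }
      # peak_height is the summed peptide signal; the best transition gets
      # max(ratios) of it, so scale heights to plant a best-transition SNR
      ratio_max <- 0.5
      h_sample <- true_snr[i] * noise_sd / ratio_max
      h_std <- standard_snr * noise_sd / ratio_max
      peptides[[i]] <- list(
        standard = mk(h_std, seeds[3 * i - 2]),
        sample   = mk(h_sample, seeds[3 * i - 1]),
        spiked   = mk(h_std + h_sample, seeds[3 * i]),
        rt = rts[i]
      )
    }
    names(peptides) <- ids
    list(
      peptides = peptides,
      truth = data.frame(peptide_id = ids, true_snr = true_snr,
                         quantifiable = true_snr > 3,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Generate a calibration series
#'
#' Linear response over at least six nominal concentrations, with optional
#' multiplicative measurement error, for downstream linearity and accuracy
#' evaluation.
#'
#' @param n_points Number of concentration points (>= 2; assays use >= 6).
#' @param concentrations Optional explicit nominal concentrations (positive);
#'   default is log-spaced over two decades.
#' @param slope,intercept Parameters of the true response line.
#' @param error_cv Multiplicative CV applied to responses (0 = exact).
#' @param seed Integer seed.
#' @return Data frame with `nominal_conc` and `response`.
#' @export
generate_calibration_series <- function(n_points = 6L, concentrations = NULL,
                                        slope = 1, intercept = 0,
                                        error_cv = 0, seed = 1L) {
  if (!is_count(n_points, min = 2L)) {
    stop("`n_points` must be a count >= 2", call. = FALSE)
  }
  if (is.null(concentrations)) {
    concentrations <- 10^seq(0, 2, length.out = n_points)
  }
  if (any(concentrations <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  stopifnot_scalar_number(error_cv, "error_cv", lower = 0)
  response <- slope * concentrations + intercept
  if (error_cv > 0) {
    response <- with_seed(seed, response * rlnorm_cv(length(response), error_cv))
  }
  data.frame(nominal_conc = concentrations, response = response)
}

#' Default composition of the quantifiability-screening sample mixture
#'
#' The screening pool mixes serum from six cancer types (40 breast, 20
#' pancreatic, 20 thyroid, 20 ovarian, 18 lung, 20 colorectal — 138 cancer
#' samples in total) with 30 disease-free samples, to expose the candidate
#' peptides to diverse blood backgrounds.
#'
#' @return Data frame with `group`, `role` (cancer/healthy) and `n`.
#' @export
screening_mixture_default <- function() {
  data.frame(
    group = c("breast", "pancreatic", "thyroid", "ovarian", "lung",
              "colorectal", "healthy"),
    role = c(rep("cancer", 6L), "healthy"),
    n = c(40L, 20L, 20L, 20L, 18L, 20L, 30L),
    stringsAsFactors = FALSE
  )
}
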