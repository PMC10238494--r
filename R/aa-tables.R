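# Amino-acid reference tables.
#
# Monoisotopic residue masses (Da) for the 20 standard residues, plus the
# constants needed for peptide and fragment m/z arithmetic. Values are the
# standard monoisotopic masses used throughout targeted proteomics.

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_MONO_MASS <- c(
  A =  71.037114, R = 156.101111, N = 114.042927, D = 115.026943,
  C = 103.009185, Q = 128.058578, E = 129.042593, G =  57.021464,
  H = 137.058912, I = 113.084064, L = 113.084064, K = 128.094963,
  M = 131.040485, F = 147.068414, P =  97.052764, S =  87.032028,
  T = 101.047679, W = 186.079313, Y = 163.063329, V =  99.068414
)

MASS_H2O    <- 18.0105646
MASS_PROTON <- 1.00727646

# Isotope mass differences for stable-isotope labels
DELTA_13C <- 1.003355   # 13C - 12C
DELTA_15N <- 0.997035   # 15N - 14N

# Heavy-label mass shifts: C-terminal Lys (13C6,15N2) or Arg (13C6,15N4)
HEAVY_SHIFT_K <- 6 * DELTA_13C + 2 * DELTA_15N  # 8.01420 Da
HEAVY_SHIFT_R <- 6 * DELTA_13C + 4 * DELTA_15N  # 10.00827 Da

# Kyte-Doolittle hydropathy values; GRAVY = mean over residues
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

check_sequence <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop(sprintf("`%s` must be a single string", what), call. = FALSE)
  }
  if (!nzchar(sequence)) {
    stop(sprintf("`%s` must be non-empty", what), call. = FALSE)
  }
  residues <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(residues), AA_LETTERS)
  if (length(bad)) {
    stop(sprintf("invalid residue letter(s) in %s: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  residues
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte--Doolittle hydropathy over the residues of a peptide. Used to
#' flag extremely hydrophilic or hydrophobic surrogate-peptide candidates,
#' whose retention times reproduce poorly on short LC gradients.
#'
#' @param sequence Peptide sequence (uppercase, 20 standard residues).
#' @return Numeric GRAVY score.
#' @examples
#' gravy("TPDVSSALDK")
#' @export
gravy <- function(sequence) {
  residues <- check_sequence(sequence, "peptide")
  mean(KYTE_DOOLITTLE[residues])
}
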