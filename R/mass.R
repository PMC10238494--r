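# Peptide and fragment mass arithmetic.

#' Monoisotopic peptide mass
#'
#' Sum of monoisotopic residue masses plus one water. For heavy peptides the
#' stable-isotope label sits on the C-terminal residue: Lys carries
#' 13C6,15N2 (+8.01420 Da) and Arg carries 13C6,15N4 (+10.00827 Da).
#'
#' @param sequence Peptide sequence.
#' @param label_state `"light"` or `"heavy"`.
#' @return Monoisotopic mass in Da.
#' @export
peptide_mass <- function(sequence, label_state = c("light", "heavy")) {
  label_state <- match.arg(label_state)
  residues <- check_sequence(sequence, "peptide")
  m <- sum(AA_MONO_MASS[residues]) + MASS_H2O
  if (label_state == "heavy") m <- m + heavy_shift_for(sequence)
  m
}

heavy_shift_for <- function(sequence) {
  cterm <- substring(sequence, nchar(sequence), nchar(sequence))
  if (cterm == "K") return(HEAVY_SHIFT_K)
  if (cterm == "R") return(HEAVY_SHIFT_R)
  stop("heavy label requires a C-terminal K or R (got '", cterm, "')",
       call. = FALSE)
}

#' Compute precursor and y-ion transitions for a peptide
#'
#' Builds the MRM transition set: precursor m/z at the requested charge and
#' the top product y-ions. Without measured spectra the "top three" product
#' ions are taken as the three longest y-ions (y\[n-1\], y\[n-2\], y\[n-3\]),
#' a deterministic stand-in for intensity ranking. The heavy label shifts
#' the precursor and every y-ion (the label is C-terminal, which every
#' y-ion contains).
#'
#' @param sequence Peptide sequence.
#' @param charge Precursor charge (>= 1; default 2, the dominant charge
#'   state for tryptic peptides of library length).
#' @param label_state `"light"` or `"heavy"` (heavy requires C-terminal
#'   K/R).
#' @param n_products Number of y-ions to emit (capped at length - 1).
#' @param product_charge Charge of the product ions (default 1).
#' @return An object of class `transition_set`: list with `sequence`,
#'   `precursor_charge`, `precursor_mz`, `product_ions` (data frame:
#'   `ion_type`, `index`, `charge`, `mz`), `label_state`, `heavy_shift`
#'   (0 for light).
#' @examples
#' ts <- compute_mz("AVIDDAFAR", charge = 2)
#' round(ts$precursor_mz, 3)
#' @export
compute_mz <- function(sequence, charge = 2L,
                       label_state = c("light", "heavy"),
                       n_products = 3L, product_charge = 1L) {
  label_state <- match.arg(label_state)
  if (!is_count(charge, min = 1L)) stop("`charge` must be >= 1", call. = FALSE)
  if (!is_count(product_charge, min = 1L)) {
    stop("`product_charge` must be >= 1", call. = FALSE)
  }
  residues <- check_sequence(sequence, "peptide")
  n <- length(residues)
  shift <- if (label_state == "heavy") heavy_shift_for(sequence) else 0
  mass <- sum(AA_MONO_MASS[residues]) + MASS_H2O + shift
  precursor_mz <- (mass + charge * MASS_PROTON) / charge

  idx <- seq.int(n - 1L, by = -1L, length.out = max(min(n_products, n - 1L), 0L))
  # y_k = C-terminal k residues + H2O (+ label, which is C-terminal)
  y_mass <- vapply(idx, function(k) {
    sum(AA_MONO_MASS[residues[(n - k + 1L):n]]) + MASS_H2O + shift
  }, numeric(1))
  product_ions <- data.frame(
    ion_type = rep("y", length(idx)), index = idx,
    charge = rep(as.integer(product_charge), length(idx)),
    mz = (y_mass + product_charge * MASS_PROTON) / product_charge,
    stringsAsFactors = FALSE
  )
  structure(list(sequence = sequence, precursor_charge = as.integer(charge),
                 precursor_mz = precursor_mz, product_ions = product_ions,
                 label_state = label_state, heavy_shift = shift),
            class = "transition_set")
}

#' @export
print.transition_set <- function(x, ...) {
  cat(sprintf("transition_set %s (%s, %d+): precursor m/z %.4f\n",
              x$sequence, x$label_state, x$precursor_charge, x$precursor_mz))
  for (i in seq_len(nrow(x$product_ions))) {
    p <- x$product_ions[i, ]
    cat(sprintf("  %s%d^%d+  %.4f\n", p$ion_type, p$index, p$charge, p$mz))
  }
  invisible(x)
}
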