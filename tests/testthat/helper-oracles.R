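# Independent oracles used to freeze expected values. These are written
# from first principles (substring enumeration, elemental composition,
# exhaustive permutation, pair counting) and never call the code paths they
# check.

# Brute-force tryptic digestion: test every substring against the cleavage
# rules (cut after K/R unless followed by P; zero missed cleavages).
oracle_digest <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  cuts_after <- function(k) res[k] %in% c("K", "R") && res[k + 1] != "P"
  frags <- character(0)
  for (i in seq_len(n)) {
    for (j in i:n) {
      left_ok <- i == 1 || cuts_after(i - 1)
      right_ok <- j == n || cuts_after(j)
      internal <- FALSE
      if (j > i) {
        for (k in i:(j - 1)) if (cuts_after(k)) { internal <- TRUE; break }
      }
      if (left_ok && right_ok && !internal) {
        frags <- c(frags, substring(sequence, i, j))
      }
    }
  }
  frags
}

# Monoisotopic mass from elemental composition and isotope masses, fully
# independent of the package's residue-mass table.
ORACLE_ELEMENT <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
                    O = 15.9949146221, S = 31.97207069)
ORACLE_AA_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

oracle_formula_mass <- function(formula) {
  sum(ORACLE_ELEMENT[names(formula)] * formula)
}

oracle_peptide_mass <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  sum(vapply(res, function(a) oracle_formula_mass(ORACLE_AA_FORMULA[[a]]),
             numeric(1))) +
    oracle_formula_mass(c(H = 2, O = 1))
}

oracle_proton <- ORACLE_ELEMENT[["H"]] - 0.00054858  # H atom minus electron

oracle_precursor_mz <- function(sequence, charge) {
  (oracle_peptide_mass(sequence) + charge * oracle_proton) / charge
}

# Exhaustive two-sided rank-sum p-value over all group assignments, using
# midranks (handles ties). p = min(1, 2 * min(P(W <= w), P(W >= w))).
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(pooled), na)
  w_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - na * (na + 1) / 2
  })
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# AUC by explicit pair counting: concordant pairs + half ties.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == "case"]
  neg <- scores[labels != "case"]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Noiseless Gaussian trace for peak-detection tests.
make_gaussian_trace <- function(height = 100, rt = 5, sigma = 0.05,
                                run_minutes = 10, hz = 2, baseline = 0) {
  t <- seq(0, run_minutes, by = 1 / (60 * hz))
  list(time = t,
       trace = baseline + height * exp(-(t - rt)^2 / (2 * sigma^2)))
}

random_protein <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}
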