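# Surrogate-peptide candidate generation.
#
# In-silico tryptic digestion (zero missed cleavages, proline rule), scoring
# of candidates against detectability criteria, and per-protein surrogate
# selection. Priorities follow the rule set used for short-gradient MRM
# library design: lengths 6-16 preferred; extreme hydrophilicity or
# hydrophobicity penalised (poor RT reproducibility); Cys/Met and N-terminal
# Trp penalised (chemically unstable); N-glycosylation sequons penalised
# (occupancy makes the unmodified peptide unreliable); ragged C-terminal
# basic pairs penalised (variable digestion).

#' Selection configuration for surrogate-peptide candidates
#'
#' @param length_min,length_max Preferred peptide length range in residues.
#' @param gravy_bounds Numeric (low, high); GRAVY outside this range flags
#'   the candidate as hydrophobicity-extreme.
#' @param cleavage_resistant_pairs C-terminal dipeptides treated as
#'   trypsin-resistant/ragged. `KP`/`RP` act during digestion (cleavage
#'   suppression before proline); the basic pairs `RR`, `KK`, `RK`, `KR`
#'   act during scoring as ragged-end flags.
#' @param max_peptides_per_protein Surrogates selected per protein.
#' @param seed Integer seed for random tie-breaking among equal priorities.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(length_min = 6L, length_max = 16L,
                             gravy_bounds = c(-2, 2),
                             cleavage_resistant_pairs = c("RR", "KK", "RK",
                                                          "KR", "KP", "RP"),
                             max_peptides_per_protein = 1L, seed = 1L) {
  if (length_min > length_max) stop("length_min must be <= length_max", call. = FALSE)
  if (length(gravy_bounds) != 2L || gravy_bounds[1] >= gravy_bounds[2]) {
    stop("`gravy_bounds` must be (low, high) with low < high", call. = FALSE)
  }
  structure(list(length_min = as.integer(length_min),
                 length_max = as.integer(length_max),
                 gravy_bounds = as.numeric(gravy_bounds),
                 cleavage_resistant_pairs = cleavage_resistant_pairs,
                 max_peptides_per_protein = as.integer(max_peptides_per_protein),
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' In-silico tryptic digestion
#'
#' Fully tryptic digestion with zero missed cleavages: the backbone is cut
#' after every K or R except when the next residue is proline (KP/RP
#' resistance). Every fragment is returned with 0-based half-open
#' coordinates; concatenating all fragments reconstructs the protein. The
#' protein's N-terminal fragment is a valid candidate (its left boundary is
#' the protein start); the C-terminal fragment is tryptic only if it itself
#' ends in K or R, otherwise it is flagged `tryptic = FALSE` and excluded
#' from candidacy downstream.
#'
#' @param sequence Protein sequence (uppercase standard residues).
#' @param protein_id Identifier carried on the output.
#' @return Data frame with columns `protein_id`, `sequence`, `start`, `end`,
#'   `length`, `tryptic`.
#' @examples
#' digest_tryptic("TPDVSSALDKAVIDDAFARK")$sequence
#' digest_tryptic("AGKPLR")$sequence  # no cleavage before proline
#' @export
digest_tryptic <- function(sequence, protein_id = NA_character_) {
  residues <- check_sequence(sequence, "protein sequence")
  n <- length(residues)
  # cut after position i iff residue is K/R and next residue exists and != P
  is_kr <- residues %in% c("K", "R")
  cut_after <- which(is_kr[-n] & residues[-1] != "P")
  starts <- c(0L, cut_after)               # 0-based
  ends <- c(cut_after, n)
  frags <- substring(sequence, starts + 1L, ends)
  tryptic <- substring(frags, nchar(frags), nchar(frags)) %in% c("K", "R")
  data.frame(protein_id = protein_id, sequence = frags,
             start = starts, end = ends, length = nchar(frags),
             tryptic = tryptic, stringsAsFactors = FALSE)
}

# N-glycosylation sequon N-X-[S/T] with X != P, scanned within the peptide
has_glyco_sequon <- function(sequence) {
  grepl("N[^P][ST]", sequence, perl = TRUE)
}

#' Score surrogate-peptide candidates
#'
#' Sets the detectability flags and the priority tier for each digested
#' candidate. The tier is ordinal: `1 + number of flag categories
#' triggered`, so an unflagged candidate has tier 1 and each additional
#' violated criterion demotes by one tier.
#'
#' @param candidates Data frame from [digest_tryptic()] (any data frame with
#'   a `sequence` column works).
#' @param cfg A [selection_config()].
#' @return The input with columns `gravy`, the individual flag columns
#'   (`has_cys`, `has_met`, `nterm_trp`, `glyco_sequon`,
#'   `length_out_of_range`, `hydrophobicity_extreme`, `ragged_end`),
#'   `n_flags` and `priority_tier` appended.
#' @examples
#' cands <- digest_tryptic("TPDVSSALDKAVIDDAFARK")
#' score_candidate(cands, selection_config())[, c("sequence", "priority_tier")]
#' @export
score_candidate <- function(candidates, cfg = selection_config()) {
  stopifnot(is.data.frame(candidates), "sequence" %in% names(candidates))
  seqs <- candidates$sequence
  len <- nchar(seqs)
  candidates$gravy <- vapply(seqs, gravy, numeric(1), USE.NAMES = FALSE)
  candidates$has_cys <- grepl("C", seqs, fixed = TRUE)
  candidates$has_met <- grepl("M", seqs, fixed = TRUE)
  candidates$nterm_trp <- substring(seqs, 1L, 1L) == "W"
  candidates$glyco_sequon <- has_glyco_sequon(seqs)
  candidates$length_out_of_range <- len < cfg$length_min | len > cfg$length_max
  candidates$hydrophobicity_extreme <- candidates$gravy < cfg$gravy_bounds[1] |
    candidates$gravy > cfg$gravy_bounds[2]
  ragged_pairs <- intersect(cfg$cleavage_resistant_pairs,
                            c("RR", "KK", "RK", "KR"))
  cterm2 <- substring(seqs, pmax(len - 1L, 1L), len)
  candidates$ragged_end <- len >= 2L & cterm2 %in% ragged_pairs
  flag_cols <- c("has_cys", "has_met", "nterm_trp", "glyco_sequon",
                 "length_out_of_range", "hydrophobicity_extreme", "ragged_end")
  candidates$n_flags <- rowSums(candidates[flag_cols])
  candidates$priority_tier <- 1L + as.integer(candidates$n_flags)
  candidates
}

#' Select surrogate peptides per protein
#'
#' Picks up to `max_peptides_per_protein` candidates per protein from the
#' best available priority tier, breaking ties by seeded random choice.
#' Proteins whose best candidates are low-tier still get a surrogate (a
#' lower-priority peptide is better than none); proteins with no tryptic
#' candidate at all yield no selection and are reported via the
#' `proteins_without_candidates` attribute.
#'
#' @param candidates Scored candidates ([score_candidate()] output) with a
#'   `protein_id` column; non-tryptic fragments (`tryptic == FALSE`) are
#'   ignored if present.
#' @param cfg A [selection_config()]; `cfg$seed` fixes the tie-breaks.
#' @return The selected candidate rows (`selected = TRUE`), one block per
#'   protein, with attribute `proteins_without_candidates`.
#' @export
select_surrogates <- function(candidates, cfg = selection_config()) {
  stopifnot(is.data.frame(candidates),
            all(c("protein_id", "priority_tier") %in% names(candidates)))
  if (!is.null(candidates$tryptic)) {
    pool <- candidates[candidates$tryptic, , drop = FALSE]
  } else {
    pool <- candidates
  }
  proteins <- unique(candidates$protein_id)
  empty <- setdiff(proteins, unique(pool$protein_id))
  if (nrow(pool) == 0L) {
    out <- pool
    out$selected <- logical(0)
    attr(out, "proteins_without_candidates") <- empty
    return(out)
  }
  picks <- with_seed(cfg$seed, {
    lapply(split(pool, pool$protein_id), function(df) {
      best <- df[df$priority_tier == min(df$priority_tier), , drop = FALSE]
      k <- min(cfg$max_peptides_per_protein, nrow(best))
      best[sample.int(nrow(best))[seq_len(k)], , drop = FALSE]
    })
  })
  out <- do.call(rbind, c(picks, list(make.row.names = FALSE)))
  out <- out[order(match(out$protein_id, proteins)), , drop = FALSE]
  rownames(out) <- NULL
  out$selected <- TRUE
  attr(out, "proteins_without_candidates") <- empty
  out
}
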