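test_that("tryptic digestion applies the cleavage and proline rules", {
  d <- digest_tryptic("TPDVSSALDKAVIDDAFARK")
  expect_equal(d$sequence, c("TPDVSSALDK", "AVIDDAFAR", "K"))
  expect_true(all(d$tryptic))
  expect_equal(d$start, c(0, 10, 19))
  expect_equal(d$end, c(10, 19, 20))

  # no cleavage after K when followed by P
  expect_equal(digest_tryptic("AGKPLR")$sequence, "AGKPLR")

  # C-terminal fragment not ending in K/R is flagged non-tryptic
  d2 <- digest_tryptic("AAKGGG")
  expect_equal(d2$sequence, c("AAK", "GGG"))
  expect_equal(d2$tryptic, c(TRUE, FALSE))

  expect_error(digest_tryptic(""), "non-empty")
  expect_error(digest_tryptic("ABZ"), "invalid residue")
})

test_that("digestion matches the brute-force substring oracle", {
  set.seed(101)
  for (i in 1:200) {
    s <- random_protein(sample(5:60, 1))
    expect_identical(digest_tryptic(s)$sequence, oracle_digest(s),
                     info = s)
  }
})

test_that("digestion fragments reconstruct the protein exactly", {
  set.seed(7)
  for (i in 1:50) {
    s <- random_protein(sample(10:80, 1))
    d <- digest_tryptic(s)
    expect_identical(paste(d$sequence, collapse = ""), s)
    expect_equal(d$end - d$start, d$length)
    expect_identical(substring(s, d$start + 1, d$end), d$sequence)
  }
})

test_that("candidate scoring sets flags and tiers per rule", {
  sc <- function(s) score_candidate(data.frame(sequence = s))
  clean <- sc("TPDVSSALDK")
  expect_equal(clean$n_flags, 0)
  expect_equal(clean$priority_tier, 1L)

  cys <- sc("ACDEFGHIK")
  expect_true(cys$has_cys)
  expect_equal(cys$priority_tier, 2L)

  glyco <- sc("NGSAVLLK")
  expect_true(glyco$glyco_sequon)
  expect_equal(glyco$priority_tier, 2L)
  # sequon requires X != P and S/T third
  expect_false(sc("NPSAVLLK")$glyco_sequon)
  expect_false(sc("NGGAVLLK")$glyco_sequon)

  expect_true(sc("WAVLDSTK")$nterm_trp)
  expect_true(sc("AAAAK")$length_out_of_range)
  expect_true(sc("ILLVVILLVVIAK")$hydrophobicity_extreme)
  expect_true(sc("AVLDSTKK")$ragged_end)
  expect_false(sc("TTSGIHPK")$ragged_end)  # PK is not a ragged pair
})

test_that("tier is monotone in the number of triggered flags", {
  seqs <- c("TPDVSSALDK",    # 0 flags
            "ACDEFGHIK",     # C
            "ACDEFGHMK",     # C + M
            "WCDEFGHMK")     # C + M + N-term W
  tiers <- score_candidate(data.frame(sequence = seqs))$priority_tier
  expect_equal(tiers, c(1L, 2L, 3L, 4L))
  scored <- score_candidate(data.frame(sequence = seqs))
  expect_equal(scored$priority_tier, 1L + scored$n_flags)
})

test_that("surrogate selection prefers the best tier and is seeded", {
  cands <- score_candidate(data.frame(
    protein_id = "P1",
    sequence = c("TPDVSSALDK", "ACDEFGHIK", "MCDEFGHIK"),
    tryptic = TRUE
  ))
  sel <- select_surrogates(cands, selection_config(seed = 1))
  expect_equal(sel$sequence, "TPDVSSALDK")  # the lone tier-1 wins

  # a protein with only low-tier candidates still gets a surrogate
  low <- score_candidate(data.frame(
    protein_id = "P2", sequence = c("ACDEFGHMK", "WCDEFGHMK"), tryptic = TRUE
  ))
  sel2 <- select_surrogates(low, selection_config(seed = 1))
  expect_equal(nrow(sel2), 1)
  expect_gt(sel2$priority_tier, 1)

  # seeded tie-break is deterministic
  ties <- score_candidate(data.frame(
    protein_id = "P3", sequence = c("TPDVSSALDK", "AVIDDAFAR"), tryptic = TRUE
  ))
  s1 <- select_surrogates(ties, selection_config(seed = 5))
  s2 <- select_surrogates(ties, selection_config(seed = 5))
  expect_identical(s1$sequence, s2$sequence)

  # proteins with zero candidates are reported
  none <- cands[0, ]
  mixed <- rbind(cands, none)
  got <- select_surrogates(
    score_candidate(data.frame(protein_id = c("P1", "P1"),
                               sequence = c("GGG", "AAA"),
                               tryptic = FALSE)),
    selection_config())
  expect_equal(attr(got, "proteins_without_candidates"), "P1")
  expect_equal(nrow(got), 0)
})
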