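idmat <- substitution_matrix("identity")
b62 <- substitution_matrix("BLOSUM62")

test_that("substitution matrices are symmetric complete lookups", {
  expect_identical(rownames(b62), colnames(b62))
  expect_true(isSymmetric(unname(b62)))
  expect_equal(unname(idmat["A", "A"]), 1)
  expect_equal(unname(idmat["A", "D"]), 0)
  expect_true(all(immunosig:::AA20 %in% rownames(b62)))
})

test_that("gapless alignment finds the best full-length placement", {
  al <- gapless_local_align("ACD", "ACD", idmat, linker = "")
  expect_identical(al$offset, 0L)
  expect_equal(al$score, 3)
  expect_equal(al$per_position, c(1, 1, 1))

  al2 <- gapless_local_align("ACD", "XACDY", b62, linker = "")
  expect_identical(al2$offset, 1L)
  expect_equal(al2$score,
               unname(b62["A", "A"] + b62["C", "C"] + b62["D", "D"]))
  expect_equal(sum(al2$per_position), al2$score)

  # two equally scoring placements: the smaller offset wins
  al3 <- gapless_local_align("AC", "ACWAC", idmat, linker = "")
  expect_identical(al3$offset, 0L)

  expect_error(gapless_local_align("ACDEF", "ACD", idmat, linker = ""),
               "shorter")
})

test_that("the linker is trimmed before alignment by default", {
  expect_identical(trim_linker("AAAGSC"), "AAA")
  expect_identical(trim_linker("AAAGSC", ""), "AAAGSC")
  prot <- "WWAAAWW"
  with_trim <- gapless_local_align("AAAGSC", prot, idmat)
  expect_identical(with_trim$peptide, "AAA")
  expect_equal(with_trim$score,
               gapless_local_align("AAA", prot, idmat, linker = "")$score)
})

test_that("alignment equals exhaustive offset enumeration on random pairs", {
  withr::with_seed(11, {
    for (i in 1:60) {
      plen <- sample(3:20, 1)
      qlen <- plen + sample(0:30, 1)
      pep <- random_aa_string(plen, alphabet = immunosig:::AA20)
      prot <- random_aa_string(qlen, alphabet = immunosig:::AA20)
      got <- gapless_local_align(pep, prot, b62, linker = "")
      want <- brute_align_oracle(pep, prot, b62)
      expect_identical(got$offset, want$offset)
      expect_equal(got$score, want$score)
    }
  })
})

test_that("proteome scoring accumulates placements positionally", {
  # one peptide, one protein: summary is that placement's score
  prot1 <- tibble::tibble(protein_id = "q1", description = "",
                          sequence = "WWACDWW", has_ambiguous = FALSE)
  ps <- score_proteome("ACD", prot1, idmat, linker = "")
  expect_equal(ps$summary_score, 3)
  expect_identical(ps$rank, 1L)

  # overlapping placements add; disjoint placements take the larger
  toy <- tibble::tibble(protein_id = "q1", description = "",
                        sequence = paste(rep("W", 30), collapse = ""),
                        has_ambiguous = FALSE)
  toy$sequence <- "ACDEFWWWWWWWWWWWWWWWWWWWWWWWWW"
  overlap <- score_proteome(c("ACDE", "CDEF"), toy, idmat, linker = "")
  expect_equal(overlap$summary_score, 4 + 4)   # share positions 2-4
  toy$sequence <- "ACDEWWWWWWWWWWWWWWWKLMNWWWWWWW"
  disjoint <- score_proteome(c("ACDE", "KLMN"), toy, idmat, linker = "")
  expect_equal(disjoint$summary_score, 4)

  # brute-force profile oracle on random input, plus mass conservation
  withr::with_seed(12, {
    peps <- vapply(1:5, function(i) paste0(random_aa_string(8), "GSC"),
                   character(1))
    prot <- make_toy_proteome(n = 3, seed = 13)
  })
  got <- score_proteome(peps, prot, b62, profiles = TRUE)
  for (k in seq_len(nrow(got))) {
    id <- got$protein_id[k]
    oracle_prof <- brute_profile_oracle(peps, prot$sequence[prot$protein_id == id],
                                        b62)
    expect_equal(got$profile[[k]], oracle_prof)
    expect_equal(got$summary_score[k], max(oracle_prof))
  }
  # sum(profile) = sum over peptides of placement score x covered length
  placement_mass <- sum(vapply(peps, function(pep) {
    al <- brute_align_oracle(trim_linker(pep), prot$sequence[1], b62)
    al$score * nchar(trim_linker(pep))
  }, numeric(1)))
  expect_equal(sum(got$profile[[which(got$protein_id == "prot001")]]),
               placement_mass)

  # peptide order cannot change the ranking
  got2 <- score_proteome(rev(peps), prot, b62)
  expect_identical(got2$protein_id, got$protein_id)
  expect_equal(got2$summary_score, got$summary_score)

  # sum summary mode: plain sum of best placement scores
  toy$sequence <- "ACDEFWWWWWWWWWWWWWWWWWWWWWWWWW"
  ssum <- score_proteome(c("ACDE", "CDEF"), toy, idmat, linker = "",
                         summary = "sum")
  expect_equal(ssum$summary_score, 8)
})

test_that("empirical p-values use the add-one estimator and are exact in the extreme", {
  lib <- tiny_library(seqs = c("AAAAAAAAAAAAAAAAAGSC", "DDDDDDDDDDDDDDDDDGSC",
                               "EEEEEEEEEEEEEEEEEGSC", "FFFFFFFFFFFFFFFFFGSC"))
  # protein matches only peptide 1: a test set containing it scores maximally
  prot <- tibble::tibble(protein_id = "q1", description = "",
                         sequence = paste(rep("A", 25), collapse = ""),
                         has_ambiguous = FALSE)
  res <- empirical_pvalues(c("p1"), lib, prot, idmat, n_perm = 40, seed = 1)
  # observed summary 17 (self-match); draws of size 1 hit it 1/4 of the time
  expect_equal(res$summary_score, 17)
  expect_gte(res$p_value, 1 / 41)

  # exhaustive enumeration oracle: library of 4, test of 2, all 6 draws
  withr::with_seed(21, {
    lib2 <- tiny_library(seqs = vapply(1:4, function(i) {
      paste0(random_aa_string(17), "GSC")
    }, character(1)))
    prot2 <- make_toy_proteome(n = 4, len_range = c(40, 60), seed = 22)
  })
  res2 <- empirical_pvalues(c("p1", "p3"), lib2, prot2, b62, n_perm = 3000,
                            seed = 2)
  combos <- utils::combn(4, 2)
  for (k in seq_len(nrow(res2))) {
    id <- res2$protein_id[k]
    seqp <- prot2$sequence[prot2$protein_id == id]
    draw_scores <- vapply(seq_len(ncol(combos)), function(j) {
      max(brute_profile_oracle(lib2$sequence[combos[, j]], seqp, b62))
    }, numeric(1))
    obs <- max(brute_profile_oracle(lib2$sequence[c(1, 3)], seqp, b62))
    expect_equal(res2$summary_score[k], obs)
    exact_p <- mean(draw_scores >= obs)
    expect_lt(abs(res2$p_value[k] - exact_p), 0.035)
  }

  # deterministic per seed
  resA <- empirical_pvalues(c("p1", "p3"), lib2, prot2, b62, n_perm = 50,
                            seed = 7)
  resB <- empirical_pvalues(c("p1", "p3"), lib2, prot2, b62, n_perm = 50,
                            seed = 7)
  expect_identical(resA, resB)
  expect_error(empirical_pvalues(c("p1"), lib2, prot2, b62, n_perm = 0),
               "n_perm")
  expect_error(empirical_pvalues(c("zz"), lib2, prot2, b62, n_perm = 5),
               "belong")
})
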