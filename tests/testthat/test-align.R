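test_that("identity alignment scores the diagonal substitution sum", {
  aln <- smith_waterman("ACDE", "ACDE")
  B <- blosum62()
  expect_equal(aln$score, B["A", "A"] + B["C", "C"] + B["D", "D"] +
                 B["E", "E"])
  expect_equal(aln$identity, 1)
  expect_equal(aln$a_start, 1); expect_equal(aln$a_end, 4)
  expect_error(smith_waterman("", "ACDE"), "empty")
})

test_that("an alignment with no positive-scoring path is empty with score 0", {
  # tryptophan versus glycine scores negative everywhere
  aln <- smith_waterman("WWWW", "GGGG")
  expect_equal(aln$score, 0)
  expect_equal(aln$n_aligned, 0)
  expect_true(is.na(aln$a_start))
  expect_true(is.na(aln$identity))
})

test_that("local alignment is symmetric and monotone under extension", {
  set.seed(101)
  for (i in 1:25) {
    a <- random_seq(sample(10:40, 1)); b <- random_seq(sample(10:40, 1))
    expect_equal(smith_waterman(a, b)$score, smith_waterman(b, a)$score)
    expect_gte(smith_waterman(paste0(a, random_seq(5)), b)$score,
               smith_waterman(a, b)$score)
  }
})

test_that("alignment scores match the independent DP oracle", {
  set.seed(7)
  for (i in 1:40) {
    a <- random_seq(sample(5:40, 1)); b <- random_seq(sample(5:40, 1))
    expect_equal(smith_waterman(a, b)$score, oracle_sw_score(a, b))
  }
})

test_that("Karlin-Altschul conversions follow the closed form", {
  K <- 0.041; lambda <- 0.267
  s0 <- log(K) / lambda  # lambda*score = ln K  =>  bitscore 0
  expect_equal(karlin_evalue(s0, 100, 100, K, lambda)$bitscore, 0)
  # doubling one length doubles the e-value at fixed score
  e1 <- karlin_evalue(100, 300, 300, K, lambda)$evalue
  e2 <- karlin_evalue(100, 300, 600, K, lambda)$evalue
  expect_equal(e2, 2 * e1)
  # hand-evaluated spot value at the default constants
  expect_equal(e1, 0.041 * 300 * 300 * exp(-0.267 * 100))
  expect_equal(karlin_evalue(100, 300, 300, K, lambda)$bitscore,
               (0.267 * 100 - log(0.041)) / log(2))
  expect_error(karlin_evalue(10, 0, 5), "positive")
  # monotone decreasing in score
  ev <- karlin_evalue(c(50, 100, 150), 200, 200)$evalue
  expect_true(all(diff(ev) < 0))
})

test_that("progressive MSA handles identical, inserted and random inputs", {
  two <- progressive_msa(tibble::tibble(protein_id = c("a", "b"),
                                        sequence = c("MKVDE", "MKVDE")))
  expect_equal(two$aligned, c("MKVDE", "MKVDE"))  # gap-free

  # one member has a single internal insertion: one gap block in the others
  tri <- progressive_msa(tibble::tibble(
    protein_id = c("a", "b", "c"),
    sequence = c("MKVLDTHE", "MKVLQQQDTHE", "MKVLDTHE")))
  expect_equal(nchar(tri$aligned[2]), 11)
  expect_equal(stringr::str_count(tri$aligned[1], "-"), 3)
  expect_equal(msa_degap(tri)[["b"]], "MKVLQQQDTHE")

  set.seed(11)
  base <- random_seq(60)
  recs <- tibble::tibble(
    protein_id = paste0("r", 1:10),
    sequence = vapply(1:10, function(i) mutate_sequence(base, 0.1),
                      character(1)))
  msa <- progressive_msa(recs)
  expect_equal(length(unique(nchar(msa$aligned))), 1)
  expect_equal(unname(msa_degap(msa)), recs$sequence)

  single <- progressive_msa(recs[1, ])
  expect_equal(single$aligned, recs$sequence[1])
})

test_that("reference-position mapping handles gaps and inverts", {
  msa <- immunotrace:::new_msa(c("r", "m"), c("AC-DE", "ACQDE"))
  expect_equal(map_reference_position(msa, "r", 3), 4)  # D pushed by gap
  ungapped <- immunotrace:::new_msa(c("r", "m"),
                                    c(random_seq(12), random_seq(12)))
  expect_equal(map_reference_position(ungapped, "r", 10), 10)
  expect_error(map_reference_position(msa, "r", 5), "beyond")
  expect_error(map_reference_position(msa, "zz", 1), "no such member")
  expect_true(is.na(map_alignment_column(msa, "r", 3)))
})

test_that("anchored residue states report letters and gap dashes", {
  msa <- immunotrace:::new_msa(
    c("REF", "ok", "sub", "gap"),
    c("MCKHAHE", "MCKHAHE", "MAKHAHE", "M-KHAHE"))
  anchor <- residue_anchor("triad", "REF", c(2L, 4L, 6L), c("C", "H", "H"))
  expect_true(residue_state_at_anchor(msa, "ok", anchor)$all_expected)
  sub <- residue_state_at_anchor(msa, "sub", anchor)
  expect_false(sub$all_expected)
  expect_equal(sub$states$observed[1], "A")
  gap <- residue_state_at_anchor(msa, "gap", anchor)
  expect_false(gap$all_expected)
  expect_equal(gap$states$observed[1], "-")
  expect_error(residue_state_at_anchor(msa, "nope", anchor), "absent")
  expect_error(residue_anchor("x", "REF", c(5L, 2L), c("C", "H")),
               "increasing")
})
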