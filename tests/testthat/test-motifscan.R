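NIM <- "CXPXCXXXCXNGXCXXPXXCXCXXGY"

test_that("degenerate motifs compile with validation", {
  m <- compile_degenerate_motif("GCGEQ")
  expect_equal(m$length, 5)
  expect_equal(length(m$fixed), 5)  # no X positions
  expect_equal(compile_degenerate_motif(NIM)$length, 26)
  expect_error(compile_degenerate_motif("XXX"), "fixed position")
  expect_error(compile_degenerate_motif("AC"), "length")
  expect_error(compile_degenerate_motif("GC!EQ"), "illegal")
})

test_that("motif scanning finds planted instances at exact coordinates", {
  inst <- gsub("X", "A", NIM)
  seq <- paste0(random_seq(50, setdiff(AA20_T, "C")), inst,
                random_seq(40, setdiff(AA20_T, "C")))
  hits <- scan_motif(seq, NIM)
  expect_equal(hits$start, 51)
  expect_equal(hits$end, 76)
  expect_equal(nrow(scan_motif(strrep("A", 100), NIM)), 0)
})

test_that("motif scanning equals the regex oracle on random sequences", {
  set.seed(23)
  for (pattern in c("GCGEQ", NIM, "HXXHH")) {
    for (i in 1:60) {
      s <- random_seq(sample(30:150, 1))
      if (i %% 3 == 0) {  # plant an instance so positives are exercised
        inst <- gsub("X", sample(AA20_T, 1), pattern)
        at <- sample(nchar(s) - nchar(inst), 1)
        s <- paste0(substr(s, 1, at), inst,
                    substr(s, at + nchar(inst) + 1, nchar(s)))
      }
      expect_equal(scan_motif(s, pattern)$start,
                   oracle_motif_starts(s, pattern))
    }
  }
})

test_that("scanning is position-covariant under prefixing", {
  set.seed(31)
  s <- paste0(random_seq(30), "GCGEQ", random_seq(30))
  h0 <- scan_motif(s, "GCGEQ")
  hk <- scan_motif(paste0(strrep("P", 17), s), "GCGEQ")
  expect_equal(hk$start, h0$start + 17)
})

test_that("PSSM construction: max letters, normalisation limit, self-scores", {
  rows <- c("MKVDE", "MKVDE")
  msa <- immunotrace:::new_msa(c("a", "b"), rows)
  bg <- stats::setNames(rep(0.05, 20), AA20_T)
  p <- build_pssm(msa, background = bg)
  chars <- strsplit("MKVDE", "")[[1]]
  for (j in 1:5) {
    expect_equal(names(which.max(p$mat[j, 1:20])), chars[j])
  }
  # pseudocount -> 0 limit: sum over letters of background * 2^score = 1
  p0 <- build_pssm(msa, pseudocount = 1e-9, background = bg)
  for (j in 1:5) {
    expect_equal(sum(bg * 2^p0$mat[j, 1:20]), 1, tolerance = 1e-6)
  }
  # majority-gap columns are dropped
  gappy <- immunotrace:::new_msa(c("a", "b", "c"),
                                 c("M-KVD", "M-KVD", "MAKVD"))
  expect_equal(build_pssm(gappy)$width, 4)
  expect_error(build_pssm(immunotrace:::new_msa(c("a", "b"),
                                                c("--", "--"))),
               "gap")

  # every training row scores at or above the calibrated threshold
  set.seed(40)
  tp <- random_pssm(width = 40, n_rows = 10)
  msa_rows <- vapply(1:10, function(i) mutate_sequence(tp$base, 0.1),
                     character(1))
  msa10 <- immunotrace:::new_msa(paste0("t", 1:10), msa_rows)
  p10 <- build_pssm(msa10, domain = "d")
  for (r in msa_rows) {
    expect_gte(max(scan_pssm(r, p10, reduce = FALSE)$score), p10$threshold)
  }
})

test_that("PSSM scanning equals the exhaustive window oracle", {
  set.seed(55)
  for (i in 1:30) {
    tp <- random_pssm(width = sample(10:25, 1))
    s <- random_seq(sample(40:120, 1))
    if (i %% 2 == 0) {  # implant the training base somewhere
      at <- sample(nchar(s) - nchar(tp$base), 1)
      s <- paste0(substr(s, 1, at), tp$base,
                  substr(s, at + nchar(tp$base) + 1, nchar(s)))
    }
    got <- scan_pssm(s, tp$pssm)
    want <- oracle_pssm_scan(s, tp$pssm)
    expect_equal(got$start, want$start)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("random sequences of equal composition yield no PSSM hits", {
  set.seed(60)
  tp <- random_pssm(width = 30, n_rows = 8)
  misses <- vapply(1:100, function(i) {
    nrow(scan_pssm(random_seq(120), tp$pssm)) == 0
  }, logical(1))
  expect_true(all(misses))
})

test_that("the training sequence hits its own model over the domain span", {
  set.seed(66)
  tp <- random_pssm(width = 30)
  flanked <- paste0(random_seq(20), tp$base, random_seq(20))
  h <- scan_pssm(flanked, tp$pssm)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 21)
  expect_equal(h$end, 50)
})

test_that("RHIM detection responds to the bundled consensus", {
  inst <- gsub("X", "S", rhim_consensus())
  expect_true(scan_rhim(paste0(random_seq(30), inst,
                               random_seq(30)))$present)
  expect_false(scan_rhim(strrep("G", 80))$present)
})

test_that("domain-hit tables round-trip", {
  hits <- tibble::tibble(species = "sp1", protein_id = c("a", "b"),
                         domain = c("PGRP", "TIR"), start = c(10L, 4L),
                         end = c(169L, 143L), score = c(300.25, 211.5))
  f <- withr::local_tempfile()
  write_domain_hits(hits, f)
  back <- read_domain_hits(f)
  expect_equal(back$domain, hits$domain)
  expect_equal(back$start, hits$start)
  expect_equal(back$score, hits$score, tolerance = 0.01)
})
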