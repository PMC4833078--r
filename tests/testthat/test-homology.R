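mk_hits <- function(evalue, identity, bitscore) {
  n <- length(evalue)
  tibble::tibble(
    query_species = "sp1", query_id = paste0("q", seq_len(n)),
    subject_species = "refsp", subject_id = paste0("s", seq_len(n)),
    identity = identity, align_length = 100L, mismatches = 0L,
    gap_opens = 0L, q_start = 1L, q_end = 100L, s_start = 1L,
    s_end = 100L, evalue = evalue, bitscore = bitscore)
}

test_that("whole-sequence filter applies the three strict thresholds", {
  h <- mk_hits(c(1e-7, 1e-5, 1e-7), c(0.35, 0.35, 0.15), c(100, 100, 100))
  kept <- filter_hits_blast(h)
  expect_equal(kept$query_id, "q1")
  expect_equal(nrow(filter_hits_blast(h[0, ])), 0)
  expect_equal(filter_hits_blast(kept), kept)  # idempotent
})

test_that("profile filter keeps strictly-below-threshold rows", {
  h <- mk_hits(c(9e-6, 1e-5, 1e-4), rep(0.5, 3), rep(100, 3))
  expect_equal(filter_hits_profile(h)$query_id, "q1")
  fixture <- mk_hits(10^-(1:20), rep(0.5, 20), rep(100, 20))
  expect_equal(nrow(filter_hits_profile(fixture)), sum(10^-(1:20) < 1e-5))
})

test_that("reciprocal best hits require mutual top ranking", {
  both_dirs <- function(df) {
    rev <- df
    rev[c("query_species", "query_id", "subject_species", "subject_id")] <-
      df[c("subject_species", "subject_id", "query_species", "query_id")]
    dplyr::bind_rows(df, rev)
  }
  mutual <- both_dirs(tibble::tibble(
    query_species = "sp1", query_id = "a1",
    subject_species = "refsp", subject_id = "r1",
    identity = 0.9, align_length = 100L, mismatches = 10L, gap_opens = 0L,
    q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
    evalue = 1e-30, bitscore = 200))
  expect_equal(nrow(best_reciprocal_hits(mutual, "refsp")), 1)

  # a1's best is r1, but r1's best in sp1 is a2: no pair for a1
  oneway <- dplyr::bind_rows(
    mutual,
    both_dirs(tibble::tibble(
      query_species = "sp1", query_id = "a2",
      subject_species = "refsp", subject_id = "r1",
      identity = 0.95, align_length = 100L, mismatches = 5L,
      gap_opens = 0L, q_start = 1L, q_end = 100L, s_start = 1L,
      s_end = 100L, evalue = 1e-40, bitscore = 300)))
  rbh <- best_reciprocal_hits(oneway, "refsp")
  expect_equal(rbh$protein_id, "a2")
})

test_that("orthogroups partition the proteins and propagate query labels", {
  proteins <- tibble::tibble(
    species = c("sp1", "sp1", "sp2", "sp2", "refsp", "refsp", "sp3"),
    protein_id = c("a", "b", "c", "d", "q", "q2", "lone"),
    sequence = "MKV")
  edge <- function(s1, i1, s2, i2) tibble::tibble(
    query_species = c(s1, s2), query_id = c(i1, i2),
    subject_species = c(s2, s1), subject_id = c(i2, i1),
    identity = 0.9, align_length = 10L, mismatches = 1L, gap_opens = 0L,
    q_start = 1L, q_end = 10L, s_start = 1L, s_end = 10L,
    evalue = 1e-20, bitscore = 150)
  # two components: {a, c, q} and {b, d}; "lone" is a singleton
  hits <- dplyr::bind_rows(edge("sp1", "a", "sp2", "c"),
                           edge("sp2", "c", "refsp", "q"),
                           edge("sp1", "b", "sp2", "d"))
  queries <- tibble::tibble(species = "refsp", protein_id = "q",
                            family = "PGRP")
  og <- cluster_orthogroups(hits, proteins, queries)
  expect_equal(nrow(og), nrow(proteins))            # covering
  expect_equal(anyDuplicated(paste(og$species, og$protein_id)), 0)
  sizes <- sort(table(og$group_id))
  expect_equal(unname(as.integer(sizes)), c(1L, 1L, 2L, 3L))
  labelled <- og[og$protein_id %in% c("a", "c", "q"), ]
  expect_true(all(labelled$family == "PGRP"))
  expect_true(all(is.na(og$family[og$protein_id %in% c("b", "d", "lone")])))

  # no edges: all singletons
  og0 <- cluster_orthogroups(hits[0, ], proteins, queries)
  expect_equal(length(unique(og0$group_id)), nrow(proteins))

  # conflicting labels flag the group as ambiguous, not silently resolved
  q2 <- dplyr::bind_rows(queries,
                         tibble::tibble(species = "refsp",
                                        protein_id = "q2",
                                        family = "TEP"))
  hits2 <- dplyr::bind_rows(hits, edge("refsp", "q2", "sp1", "a"))
  og2 <- cluster_orthogroups(hits2, proteins, q2)
  grp <- og2[og2$protein_id == "q", ]
  expect_true(grp$ambiguous)
  expect_true(is.na(grp$family))
})

test_that("haplotype collapse merges near-duplicates and keeps the longest", {
  base <- random_seq(120)
  twin <- tibble::tibble(species = "sp1", protein_id = c("p1", "p2"),
                         sequence = c(base, base))
  res <- collapse_haplotypes(twin)
  expect_equal(nrow(res$proteins), 1)
  expect_equal(res$report$removed_id, "p2")

  # identity 0.95 with threshold 0.99: no merge
  set.seed(5)
  pair95 <- tibble::tibble(species = "sp1", protein_id = c("p1", "p2"),
                           sequence = c(base, mutate_sequence(base, 0.05)))
  expect_equal(nrow(collapse_haplotypes(pair95)$proteins), 2)

  # 10 sequences with 3 planted near-duplicates (one substitution each,
  # identity 149/150 = 99.3%) -> 7 survivors
  set.seed(9)
  uniq <- vapply(1:7, function(i) random_seq(150), character(1))
  dups <- vapply(1:3, function(i) {
    old <- substr(uniq[i], 5, 5)
    immunotrace:::impose(uniq[i], 5L, setdiff(AA20_T, old)[1])
  }, character(1))
  ten <- tibble::tibble(species = "sp1",
                        protein_id = sprintf("p%02d", 1:10),
                        sequence = c(uniq, dups))
  res10 <- collapse_haplotypes(ten)
  expect_equal(nrow(res10$proteins), 7)
  expect_equal(nrow(res10$report), 3)
  expect_error(collapse_haplotypes(
    tibble::tibble(species = c("a", "b"), protein_id = c("x", "y"),
                   sequence = "MKV")), "one species")
})

test_that("global identity reflects gap-inclusive alignment columns", {
  expect_equal(global_identity("MKVDE", "MKVDE"), 1)
  expect_lt(global_identity("MKVDE", "MKVDEAAAAA"), 0.6)
})
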