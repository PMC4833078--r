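mk_rule <- function(family, req = character(0), min = integer(0),
                    forb = character(0), motifs = character(0),
                    loc = "any") {
  tibble::tibble(
    family = family,
    required_domains = list(tibble::tibble(domain = req,
                                           min_count = as.integer(min))),
    forbidden_domains = list(forb), required_motifs = list(motifs),
    residue_anchors = list(character(0)), localization = loc,
    classifier = "none", report_motifs = list(character(0)))
}

mk_structure <- function(signal = FALSE, loc = "intracellular", n_tm = 0,
                         n_lrr = 0, cys = NULL) {
  cys <- cys %||% tibble::tibble(start = integer(0), end = integer(0),
                                 n_cys = integer(0),
                                 juxtamembrane = logical(0))
  tibble::tibble(species = "sp1", protein_id = "p",
                 signal_peptide = signal, localization = loc,
                 n_tm = n_tm, n_lrr = n_lrr,
                 n_cys_clusters = nrow(cys),
                 tm = list(tibble::tibble(
                   start = if (n_tm > 0) 300L else integer(0),
                   end = if (n_tm > 0) 322L else integer(0),
                   hydropathy = if (n_tm > 0) 3 else numeric(0))),
                 lrrs = list(tibble::tibble()), cys_clusters = list(cys))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

no_hits <- tibble::tibble(domain = character(0), start = integer(0),
                          end = integer(0), score = numeric(0))
no_motifs <- tibble::tibble(motif_id = character(0), start = integer(0),
                            end = integer(0))

test_that("architecture checks report every failed clause", {
  rule <- mk_rule("TLR", req = c("TIR", "TM", "LRR"), min = c(1, 1, 1),
                  loc = "transmembrane")
  tir_hit <- tibble::tibble(domain = "TIR", start = 340L, end = 479L,
                            score = 200)
  full <- check_architecture(rule, tir_hit, no_motifs,
                             mk_structure(loc = "transmembrane",
                                          n_tm = 1, n_lrr = 10),
                             known_domains = "TIR")
  expect_true(full$pass)
  expect_equal(full$reasons, character(0))

  no_tir <- check_architecture(rule, no_hits, no_motifs,
                               mk_structure(loc = "transmembrane",
                                            n_tm = 1, n_lrr = 10),
                               known_domains = "TIR")
  expect_false(no_tir$pass)
  expect_match(no_tir$reasons, "TIR absent", all = FALSE)

  wrong_loc <- check_architecture(rule, tir_hit, no_motifs,
                                  mk_structure(loc = "secreted",
                                               n_tm = 1, n_lrr = 10),
                                  known_domains = "TIR")
  expect_false(wrong_loc$pass)
  expect_match(wrong_loc$reasons, "localization", all = FALSE)

  expect_error(check_architecture(mk_rule("X", req = "NOPE", min = 1),
                                  no_hits, no_motifs, mk_structure(),
                                  known_domains = "TIR"), "unknown")

  forb <- mk_rule("Y", req = "TM", min = 1, forb = "TIR")
  res <- check_architecture(forb, tir_hit, no_motifs,
                            mk_structure(n_tm = 1), known_domains = "TIR")
  expect_false(res$pass)
  expect_match(res$reasons, "forbidden", all = FALSE)

  motif_rule <- mk_rule("Nimrod", motifs = "NIM")
  res2 <- check_architecture(motif_rule, no_hits, no_motifs,
                             mk_structure(), known_domains = character(0))
  expect_match(res2$reasons, "NIM absent", all = FALSE)
})

test_that("amidase-triad calls follow the anchored residues", {
  msa <- immunotrace:::new_msa(
    c("PGRP_REF", "cat", "sub", "gap"),
    c("MMCDDHAHKK", "MMCDDHAHKK", "MMCDDYAHKK", "MMCDD-AHKK"))
  anchor <- residue_anchor("triad", "PGRP_REF", c(3L, 6L, 8L),
                           c("C", "H", "H"))
  expect_equal(pgrp_catalytic_call(msa, "PGRP_REF", anchor)$state,
               "catalytic")
  expect_equal(pgrp_catalytic_call(msa, "cat", anchor)$state, "catalytic")
  sub <- pgrp_catalytic_call(msa, "sub", anchor)
  expect_equal(sub$state, "non-catalytic")
  expect_equal(sub$states$observed[2], "Y")
  gap <- pgrp_catalytic_call(msa, "gap", anchor)
  expect_equal(gap$state, "non-catalytic")
  expect_equal(gap$states$observed[2], "-")
})

test_that("glucanase calls flag the asterisk class on glutamate loss", {
  msa <- immunotrace:::new_msa(
    c("GH16_REF", "active", "dead"),
    c("KKEDDDEKK", "KKEDDDEKK", "KKQDDDEKK"))
  anchor <- residue_anchor("glu_pair", "GH16_REF", c(3L, 7L), c("E", "E"))
  act <- glucanase_activity_call(msa, "active", anchor)
  expect_equal(act$state, "catalytic")
  expect_false(act$asterisk)
  dead <- glucanase_activity_call(msa, "dead", anchor)
  expect_equal(dead$state, "non-catalytic")
  expect_true(dead$asterisk)
})

test_that("thioester classification keys on GCGEQ and the critical cysteine", {
  flank <- random_seq(40, setdiff(AA20_T, "C"))
  tep <- tep_classify(paste0(flank, "GCGEQ", flank))
  expect_equal(tep$class, "TEP")
  expect_true(tep$thioester_motif_present)
  expect_true(tep$critical_cys_present)
  mcr <- tep_classify(paste0(flank, "GAGEQ", flank))
  expect_equal(mcr$class, "MCR-like")
  expect_false(mcr$critical_cys_present)
  # motif absent but a cysteine near the degenerate site still counts
  near <- tep_classify(paste0(flank, "CAAGAGEQ", flank))
  expect_equal(near$class, "MCR-like")
  expect_true(near$critical_cys_present)
})

test_that("TLR structural classes follow cluster count and position", {
  juxta <- tibble::tibble(start = 270L, end = 274L, n_cys = 2L,
                          juxtamembrane = TRUE)
  internal <- tibble::tibble(start = 100L, end = 104L, n_cys = 2L,
                             juxtamembrane = FALSE)
  scc <- classify_tlr(mk_structure(loc = "transmembrane", n_tm = 1,
                                   cys = juxta), TRUE)
  expect_equal(scc$class, "scc")
  mcc <- classify_tlr(mk_structure(loc = "transmembrane", n_tm = 1,
                                   cys = rbind(internal, juxta)), TRUE)
  expect_equal(mcc$class, "mcc")
  three <- classify_tlr(mk_structure(loc = "transmembrane", n_tm = 1,
                                     cys = rbind(internal, internal,
                                                 juxta)), TRUE)
  expect_equal(three$class, "atypical")
  expect_equal(three$n_clusters, 3)
  lone_internal <- classify_tlr(mk_structure(loc = "transmembrane",
                                             n_tm = 1, cys = internal),
                                TRUE)
  expect_equal(lone_internal$class, "atypical")
  expect_false(scc$truncated)  # TM at 300: ectodomain 299 >= 150
  expect_error(classify_tlr(mk_structure(), FALSE), "TIR")
})

test_that("Relish architecture needs C-terminal ankyrins after the RHD", {
  rhd <- tibble::tibble(domain = "RHD", start = 1L, end = 150L,
                        score = 400)
  anks <- tibble::tibble(domain = "ANK", start = c(171L, 204L, 237L, 270L),
                         end = c(203L, 236L, 269L, 302L), score = 60)
  full <- relish_architecture(dplyr::bind_rows(rhd, anks))
  expect_true(full$has_rhd); expect_true(full$has_ankyrin_region)
  only <- relish_architecture(rhd)
  expect_true(only$has_rhd); expect_false(only$has_ankyrin_region)
  # ankyrins N-terminal of the RHD do not count
  nterm <- anks; nterm$start <- nterm$start - 400L
  nterm$end <- nterm$end - 400L
  rhd_late <- rhd; rhd_late$start <- 500L; rhd_late$end <- 650L
  flipped <- relish_architecture(dplyr::bind_rows(rhd_late, nterm))
  expect_true(flipped$has_rhd); expect_false(flipped$has_ankyrin_region)
  none <- relish_architecture(no_hits)
  expect_false(none$has_rhd)
})

test_that("copy-number matrices are zero-filled exact tallies", {
  empty <- copy_number_matrix(
    tibble::tibble(species = character(0), family = character(0)),
    species = c("sp1", "sp2"), families = c("PGRP", "TEP"))
  expect_equal(dim(empty), c(2L, 3L))
  expect_true(all(empty$PGRP == 0) && all(empty$TEP == 0))

  nine <- tibble::tibble(
    species = c("sp1", "sp1", "sp1", "sp2", "sp2", "sp3", "sp3", "sp3",
                "sp3"),
    family = c("PGRP", "PGRP", "TEP", "PGRP", "TEP", "TEP", "TEP",
               "PGRP", "PGRP"))
  cnm <- copy_number_matrix(nine, species = c("sp1", "sp2", "sp3"),
                            families = c("PGRP", "TEP"))
  expect_equal(cnm$PGRP, c(2L, 1L, 2L))
  expect_equal(cnm$TEP, c(1L, 1L, 2L))
})

test_that("catalytic calls ignore alignment-preserving changes to non-anchor columns", {
  msa <- immunotrace:::new_msa(
    c("PGRP_REF", "m"),
    c("MMCDDHAHKK", "MMCDDHAHKK"))
  anchor <- residue_anchor("triad", "PGRP_REF", c(3L, 6L, 8L),
                           c("C", "H", "H"))
  before <- pgrp_catalytic_call(msa, "m", anchor)
  # substitute non-anchor columns in the member only
  msa2 <- immunotrace:::new_msa(
    c("PGRP_REF", "m"),
    c("MMCDDHAHKK", "WWCVVHYHWW"))
  after <- pgrp_catalytic_call(msa2, "m", anchor)
  expect_equal(before$state, after$state)
})
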