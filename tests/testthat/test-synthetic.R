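test_that("substitution respects rate extremes and protected positions", {
  s <- random_seq(200)
  expect_equal(mutate_sequence(s, 0), s)
  all_changed <- mutate_sequence(s, 1, seed = 3, protected = 1:10)
  a <- strsplit(s, "")[[1]]; b <- strsplit(all_changed, "")[[1]]
  expect_equal(b[1:10], a[1:10])
  expect_true(all(b[11:200] != a[11:200]))
  expect_error(mutate_sequence(s, 1.5), "rate")
})

test_that("realised substitution fraction matches the rate at 3 sigma", {
  set.seed(8)
  s <- random_seq(10000)
  rate <- 0.3
  m <- mutate_sequence(s, rate)
  frac <- mean(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  se <- sqrt(rate * (1 - rate) / 10000)
  expect_lt(abs(frac - rate), 3 * se)
})

test_that("copy numbers without duplication or loss equal the ancestral count", {
  tips <- evolve_family("((A:0.1,B:0.1):0.05,C:0.15);", n_ancestral = 3,
                        birth = 0, death = 0, seed = 1)
  counts <- table(tips$species)
  expect_equal(unname(as.integer(counts)), c(3L, 3L, 3L))
  expect_equal(sort(unique(tips$ancestral_copy)), 1:3)
})

test_that("overwhelming loss empties the tips", {
  set.seed(12)
  extinct <- vapply(1:200, function(i) {
    nrow(evolve_family("(A:1,B:1);", n_ancestral = 1, birth = 0,
                       death = 100))
  }, numeric(1))
  # P(survive a unit branch) = exp(-100); all replicates should be empty
  expect_true(all(extinct == 0))
})

test_that("mean tip copy number tracks the birth-death expectation", {
  set.seed(14)
  b <- 0.6; d <- 0.3; t <- 1; n0 <- 2
  tipcounts <- vapply(1:300, function(i) {
    tips <- evolve_family("(A:1,B:1);", n_ancestral = n0, birth = b,
                          death = d)
    sum(tips$species == "A")
  }, numeric(1))
  expected <- n0 * exp((b - d) * t)
  se <- stats::sd(tipcounts) / sqrt(length(tipcounts))
  expect_lt(abs(mean(tipcounts) - expected), 3 * se)
})

test_that("built proteins carry their planted diagnostics", {
  set.seed(16)
  doms <- immunotrace:::generate_domain_consensus()

  pgrp <- build_protein("PGRP", doms, opts = list(signal = TRUE))
  pos <- immunotrace:::anchor_positions(pgrp, "PGRP")
  chars <- strsplit(pgrp$sequence, "")[[1]]
  expect_equal(chars[pos], c("C", "H", "H"))
  expect_equal(pgrp$truth$localization, "secreted")

  gh16 <- build_protein("GH16", doms)
  gpos <- immunotrace:::anchor_positions(gh16, "GH16")
  expect_equal(strsplit(gh16$sequence, "")[[1]][gpos], c("E", "E"))

  scc <- build_protein("TLR", doms, opts = list(tlr_class = "scc"))
  st <- predict_structure(tibble::tibble(species = "x", protein_id = "t",
                                         sequence = scc$sequence))
  expect_equal(st$n_cys_clusters, 1)
  expect_true(st$cys_clusters[[1]]$juxtamembrane)
  expect_equal(st$localization, "transmembrane")
  mcc <- build_protein("TLR", doms, opts = list(tlr_class = "mcc"))
  st2 <- predict_structure(tibble::tibble(species = "x", protein_id = "t",
                                          sequence = mcc$sequence))
  expect_equal(st2$n_cys_clusters, 2)

  tep <- build_protein("TEP", doms)
  expect_equal(nrow(scan_motif(tep$sequence, "GCGEQ")), 1)

  nim <- build_protein("Nimrod", doms)
  expect_equal(nrow(scan_motif(nim$sequence,
                               immunotrace:::NIM_PATTERN)), 3)
  expect_error(build_protein("NOPE", doms), "unknown family")
})

test_that("thioester ablation leaves no GCGEQ substring anywhere", {
  ds <- run_simulate(default_generator_config(n_background = 0, seed = 2),
                     withr::local_tempdir())
  teps <- ds$proteins[ds$proteins$family %in% "TEP", ]
  truth <- ds$truth[match(paste(teps$species, teps$protein_id),
                          paste(ds$truth$species, ds$truth$protein_id)), ]
  ablated <- teps$sequence[truth$tep_class == "MCR-like"]
  expect_gt(length(ablated), 0)
  expect_false(any(grepl("GCGEQ", ablated, fixed = TRUE)))
  intact <- teps$sequence[truth$tep_class == "TEP"]
  expect_true(all(grepl("GCGEQ", intact, fixed = TRUE)))
})

test_that("emitted datasets are deterministic and internally consistent", {
  cfg <- default_generator_config(n_background = 5, seed = 31)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  ds1 <- run_simulate(cfg, d1); ds2 <- run_simulate(cfg, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
  # every truth row has a protein; families match the genealogy counts
  expect_setequal(paste(ds1$truth$species, ds1$truth$protein_id),
                  paste(ds1$proteins$species, ds1$proteins$protein_id))
  fam_truth <- ds1$truth[ds1$truth$family != "background", ]
  expect_equal(nrow(fam_truth), nrow(ds1$genealogy))
})

test_that("every planted feature is re-detectable at zero mutation", {
  cfg <- default_generator_config(divergence = 0, birth = 0, death = 0,
                                  n_background = 0, seed = 5)
  ds <- run_simulate(cfg, withr::local_tempdir())
  key <- paste(ds$proteins$species, ds$proteins$protein_id)
  for (r in seq_len(nrow(ds$features))) {
    ft <- ds$features[r, ]
    seq <- ds$proteins$sequence[key == paste(ft$species, ft$protein_id)]
    span <- substr(seq, ft$start, ft$end)
    if (ft$feature == "GCGEQ_site") {
      truth_row <- ds$truth[ds$truth$protein_id == ft$protein_id &
                              ds$truth$species == ft$species, ]
      if (truth_row$tep_class == "TEP") {
        expect_equal(span, "GCGEQ")
      }
    } else if (ft$feature == "NIM") {
      expect_equal(nrow(scan_motif(span, immunotrace:::NIM_PATTERN)), 1)
    } else if (ft$feature == "RHIM") {
      expect_true(scan_rhim(span)$present)
    } else if (ft$feature == "TM") {
      tm <- predict_tm(seq)
      expect_true(any(tm$start <= ft$end & tm$end >= ft$start))
    } else if (ft$feature == "CYS_CLUSTER") {
      cc <- find_cys_clusters(span)
      expect_equal(nrow(cc), 1)
    } else if (ft$feature == "LRR") {
      expect_equal(nrow(find_lrrs(span)), 1)
    }
  }
})
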