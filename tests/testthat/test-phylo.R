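test_that("alignment distances equal the column-counting oracle", {
  msa <- immunotrace:::new_msa(c("a", "b", "c"),
                               c("AAAAAAAAAA", "AAAAAAAAAC", "AAAAAAAACC"))
  D <- msa_distances(msa, "p")
  expect_equal(D["a", "b"], 0.1)
  expect_equal(D["a", "a"], 0)
  expect_equal(msa_distances(msa, "poisson")["a", "b"], -log(0.9))

  set.seed(13)
  for (i in 1:20) {
    g <- random_gapped_msa(n_rows = 4, len = 25, n_gaps = 6)
    D <- msa_distances(g, "p")
    for (x in 1:3) for (y in (x + 1):4) {
      expect_equal(D[x, y],
                   oracle_p_distance(g$aligned[x], g$aligned[y]))
    }
  }
  allgap <- immunotrace:::new_msa(c("a", "b", "c"),
                                  c("A--", "-A-", "AAA"))
  expect_error(msa_distances(allgap), "coverage")
})

test_that("three-taxon neighbor joining matches the closed form", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  bl <- stats::setNames(tr$edge.length,
                        tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 1, 3))
  expect_error(neighbor_joining(D[1:2, 1:2]), "3 taxa")
  D2 <- D; D2[1, 2] <- 5
  expect_error(neighbor_joining(D2), "symmetric")
})

test_that("neighbor joining is exact on additive matrices", {
  set.seed(17)
  for (i in 1:20) {
    true_tree <- ape::rtree(8)
    D <- ape::cophenetic.phylo(true_tree)
    est <- neighbor_joining(D)
    expect_equal(phangorn::RF.dist(ape::unroot(true_tree), est), 0)
    De <- ape::cophenetic.phylo(est)
    expect_equal(De[rownames(D), colnames(D)], D, tolerance = 1e-9)
  }
})

test_that("a zero-distance pair becomes a zero-length cherry", {
  D <- matrix(c(0, 0, 3, 3,
                0, 0, 3, 3,
                3, 3, 0, 1,
                3, 3, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(D)
  tips <- match(c("a", "b"), tr$tip.label)
  bl <- tr$edge.length[match(tips, tr$edge[, 2])]
  expect_equal(bl, c(0, 0))
  expect_true(all(tr$edge.length >= 0))
})

test_that("midpoint rooting bisects the longest leaf-to-leaf path", {
  two <- ape::read.tree(text = "(A:1,B:3);")
  r2 <- midpoint_root(two)
  expect_equal(sort(r2$edge.length), c(2, 2))

  sym4 <- ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):2);")
  r4 <- midpoint_root(ape::unroot(sym4))
  d <- ape::node.depth.edgelength(r4)
  tipd <- d[seq_along(r4$tip.label)]
  expect_equal(max(tipd[c(1, 2)]), max(tipd[c(3, 4)]))

  set.seed(19)
  for (i in 1:20) {
    tr <- ape::unroot(ape::rtree(sample(5:12, 1)))
    rooted <- midpoint_root(tr)
    expect_equal(sum(rooted$edge.length), sum(tr$edge.length),
                 tolerance = 1e-9)
    expect_equal(phangorn::RF.dist(ape::unroot(rooted), tr), 0)
    d <- ape::node.depth.edgelength(rooted)
    ntip <- length(rooted$tip.label)
    root <- ntip + 1
    kids <- rooted$edge[rooted$edge[, 1] == root, 2]
    side_max <- vapply(kids, function(k) {
      tips <- if (k <= ntip) k else
        phangorn::Descendants(rooted, k, "tips")[[1]]
      max(d[tips])
    }, numeric(1))
    expect_lte(abs(max(side_max) - sort(side_max, decreasing = TRUE)[2]),
               1e-9)
  }

  flat <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  expect_warning(midpoint_root(ape::unroot(flat)), "zero")
})

test_that("bootstrap supports are deterministic integers in [0, 100]", {
  set.seed(21)
  base <- random_seq(80)
  rows <- vapply(1:6, function(i) mutate_sequence(base, 0.15),
                 character(1))
  msa <- immunotrace:::new_msa(paste0("t", 1:6), rows)
  t1 <- bootstrap_support(msa, n_replicates = 10, seed = 4)
  t2 <- bootstrap_support(msa, n_replicates = 10, seed = 4)
  expect_identical(t1$node.label, t2$node.label)
  expect_true(all(t1$node.label >= 0 & t1$node.label <= 100))
  one <- bootstrap_support(msa, n_replicates = 1, seed = 4)
  expect_true(all(one$node.label %in% c(0L, 100L)))
})

test_that("Newick round-trips preserve topology, lengths and supports", {
  set.seed(25)
  tr <- ape::rtree(10)
  tr$node.label <- as.integer(round(runif(tr$Nnode, 0, 100)))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_equal(phangorn::RF.dist(tr, back), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)
  expect_equal(as.integer(back$node.label), tr$node.label)
})
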