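# Pairwise distances from a character matrix (taxa x columns).
dist_from_char_matrix <- function(m, correction = c("p", "poisson")) {
  correction <- match.arg(correction)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(both)) {
        abort(paste0("zero mutual ungapped coverage between ",
                     rownames(m)[i], " and ", rownames(m)[j]))
      }
      p <- mean(m[i, both] != m[j, both])
      d <- if (correction == "poisson") -log(max(1 - p, 1e-10)) else p
      D[i, j] <- d; D[j, i] <- d
    }
  }
  D
}

#' Pairwise distances from a multiple alignment
#'
#' Mismatch fraction over mutually ungapped columns per pair, optionally
#' Poisson-corrected (`-ln(1 - p)`; p is capped just below 1 so corrected
#' distances stay finite). Pairs with zero mutual ungapped coverage are an
#' error.
#'
#' @param msa An `msa` tibble with at least 3 rows.
#' @param correction `"p"` (raw mismatch fraction) or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal, taxon ids as
#'   dimnames.
#' @export
msa_distances <- function(msa, correction = c("p", "poisson")) {
  if (nrow(msa) < 3) abort("need at least 3 rows")
  dist_from_char_matrix(msa_matrix(msa), match.arg(correction))
}

# Clamp negative branch lengths to zero, transferring the deficit to a
# sibling branch (standard neighbor-joining post-pass).
clamp_negative_branches <- function(tree) {
  for (pass in 1:10) {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0) break
    for (e in neg) {
      deficit <- -tree$edge.length[e]
      tree$edge.length[e] <- 0
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      sibs <- which(tree$edge[, 1] == parent & tree$edge[, 2] != child)
      if (length(sibs)) {
        tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] + deficit
      }
    }
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via ape), with taxa processed in
#' lexicographic label order for determinism and negative branch lengths
#' clamped to zero with the deficit moved to a sibling branch. Exact on
#' additive matrices.
#'
#' @param dist Symmetric distance matrix (or `dist` object) over at least
#'   3 taxa.
#' @return Unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dist) {
  D <- as.matrix(dist)
  if (nrow(D) < 3) abort("need at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-8) abort("distance matrix is not symmetric")
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  ord <- order(rownames(D))
  D <- D[ord, ord]
  tree <- ape::nj(stats::as.dist(D))
  clamp_negative_branches(tree)
}

# Leaf-to-leaf path lengths and the longest path of an unrooted tree.
longest_leaf_path <- function(tree) {
  dm <- ape::cophenetic.phylo(tree)
  idx <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  list(length = max(dm), tips = rownames(dm)[idx])
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path, so
#' the two root-side halves of that path are equal. A tree whose branch
#' lengths are all zero has no midpoint; it is rooted on a deterministic
#' edge (at the first tip in label order) with a warning.
#'
#' @param tree Unrooted `phylo` tree with branch lengths.
#' @return Rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (length(tree$tip.label) == 2) {
    # two leaves: the root bisects the single path
    half <- sum(tree$edge.length) / 2
    out <- ape::read.tree(text = sprintf(
      "(%s:%g,%s:%g);", tree$tip.label[1], half, tree$tip.label[2], half))
    return(out)
  }
  if (sum(tree$edge.length) == 0) {
    warn("all branch lengths are zero; rooting on an arbitrary edge")
    return(ape::root(tree, outgroup = sort(tree$tip.label)[1],
                     resolve.root = TRUE))
  }
  phangorn::midpoint(tree)
}

#' Bootstrap support for a distance tree
#'
#' Resamples alignment columns with replacement, rebuilds the tree for
#' each replicate, and reports for each internal bipartition of the full
#' tree the percentage of replicate trees containing it (integers 0-100).
#'
#' @param msa An `msa` tibble.
#' @param n_replicates Number of replicates (>= 1).
#' @param seed RNG seed (required for reproducibility; default 0).
#' @param correction Distance correction (see [msa_distances()]).
#' @param tree_builder Function from a character matrix (taxa x columns)
#'   to a `phylo` tree; default: distances + [neighbor_joining()].
#' @return The full-alignment tree with `node.label` set to integer
#'   support values.
#' @export
bootstrap_support <- function(msa, n_replicates = 100, seed = 0,
                              correction = "poisson",
                              tree_builder = NULL) {
  if (n_replicates < 1) abort("need at least one replicate")
  if (is.null(tree_builder)) {
    tree_builder <- function(m) {
      neighbor_joining(dist_from_char_matrix(m, correction))
    }
  }
  m <- msa_matrix(msa)
  phy <- tree_builder(m)
  set.seed(seed)
  counts <- ape::boot.phylo(phy, m, tree_builder, B = n_replicates,
                            quiet = TRUE, rooted = FALSE)
  # the basal node's trivial all-taxa split is not a bipartition and comes
  # back NA; every replicate trivially contains it
  counts[is.na(counts)] <- n_replicates
  phy$node.label <- as.integer(round(100 * counts / n_replicates))
  phy
}

#' Write a tree to a Newick file
#' @param tree A `phylo` tree (node labels, if any, are kept).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return A `phylo` tree.
#' @export
read_newick <- function(path) ape::read.tree(path)
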