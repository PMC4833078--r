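#' Smith-Waterman local alignment with affine gaps
#'
#' Optimal local alignment of two protein sequences under affine-gap
#' scoring. A gap of length `k` costs `gap_open + k * gap_extend` (so the
#' first gapped position costs `gap_open + gap_extend`, the BLAST
#' convention). Traceback is deterministic: ties prefer diagonal over up
#' over left, and among equal-scoring end cells the one with the smallest
#' (row, column) wins.
#'
#' @param seq_a,seq_b Non-empty amino-acid strings over the 21-letter
#'   alphabet (`X` scores 0 against everything).
#' @param matrix Substitution matrix over the 21-letter alphabet
#'   (default [blosum62()]).
#' @param gap_open,gap_extend Positive gap penalties (defaults 11 and 1,
#'   the standard protein-search defaults).
#' @return An object of class `pairwise_alignment`: a list with `score`,
#'   `identity` (fraction identical over aligned columns; `NA` for an empty
#'   alignment), `n_aligned`, `a_start`, `a_end`, `b_start`, `b_end`
#'   (1-based inclusive; `NA` when the optimal local alignment is empty)
#'   and `pairs`, a two-column matrix of aligned (a, b) positions.
#' @export
#' @examples
#' aln <- smith_waterman("ACDE", "ACDE")
#' aln$score  # 4 + 9 + 6 + 5 = 24
smith_waterman <- function(seq_a, seq_b, matrix = blosum62(),
                           gap_open = 11, gap_extend = 1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) abort("empty sequence")
  if (gap_open <= 0 || gap_extend <= 0) abort("gap penalties must be > 0")
  res <- sw_align_cpp(encode_seq(seq_a), encode_seq(seq_b),
                      matrix[AA_ALPHABET, AA_ALPHABET], gap_open, gap_extend)
  n_aln <- nrow(res$pairs)
  structure(list(
    score = res$score,
    identity = if (n_aln > 0) res$n_ident / n_aln else NA_real_,
    n_aligned = n_aln,
    a_start = res$a_start, a_end = res$a_end,
    b_start = res$b_start, b_end = res$b_end,
    pairs = res$pairs), class = "pairwise_alignment")
}

#' Karlin-Altschul bit score and e-value
#'
#' Converts a raw local-alignment score to a bit score and an e-value,
#' `bitscore = (lambda * score - ln K) / ln 2` and
#' `evalue = K * len_a * len_b * exp(-lambda * score)`. The default K and
#' lambda are the standard gapped BLOSUM62 (gap open 11, extend 1)
#' constants; they are fixed library values, used here only to apply
#' e-value thresholds, not fitted.
#'
#' @param score Raw alignment score(s).
#' @param len_a,len_b Sequence lengths (positive).
#' @param K,lambda Karlin-Altschul parameters (positive).
#' @return A tibble with columns `bitscore` and `evalue`.
#' @export
karlin_evalue <- function(score, len_a, len_b, K = 0.041, lambda = 0.267) {
  if (K <= 0 || lambda <= 0) abort("K and lambda must be positive")
  if (any(len_a <= 0) || any(len_b <= 0)) abort("lengths must be positive")
  tibble(bitscore = (lambda * score - log(K)) / log(2),
         evalue = K * len_a * len_b * exp(-lambda * score))
}

# ---- multiple alignment -------------------------------------------------

new_msa <- function(member_id, aligned) {
  stopifnot(length(unique(nchar(aligned))) <= 1)
  structure(tibble(member_id = member_id, aligned = aligned),
            class = c("msa", class(tibble())))
}

#' Convert a multiple alignment to a character matrix
#'
#' @param msa An `msa` tibble (columns `member_id`, `aligned`).
#' @return Character matrix, one row per member, one column per alignment
#'   column, rownames set to member ids.
#' @export
msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(msa$aligned, "", fixed = TRUE))
  rownames(m) <- msa$member_id
  m
}

# 21 x L frequency profile of a set of gapped rows (gap mass excluded).
msa_profile <- function(rows) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  L <- ncol(m)
  prof <- matrix(0, 21, L)
  for (k in seq_along(AA_ALPHABET)) {
    prof[k, ] <- colSums(m == AA_ALPHABET[k])
  }
  prof / nrow(m)
}

merge_by_ops <- function(rows_a, rows_b, ops) {
  ca <- strsplit(rows_a, "", fixed = TRUE)
  cb <- strsplit(rows_b, "", fixed = TRUE)
  na <- length(ops[ops != 3]); nb <- length(ops[ops != 2])
  out_a <- lapply(ca, function(x) {
    r <- character(length(ops)); r[ops == 3] <- "-"
    r[ops != 3] <- x; paste(r, collapse = "")
  })
  out_b <- lapply(cb, function(x) {
    r <- character(length(ops)); r[ops == 2] <- "-"
    r[ops != 2] <- x; paste(r, collapse = "")
  })
  c(unlist(out_a), unlist(out_b))
}

#' Progressive multiple sequence alignment
#'
#' Builds a multiple alignment by progressive profile merging along a guide
#' tree: pairwise local-alignment identities give distances
#' (`1 - identity`), neighbor joining builds the guide tree (midpoint-rooted
#' for traversal), and profiles are merged leaf-to-root with the same
#' affine scoring used for pairwise alignment. Degapping any output row
#' reproduces the corresponding input sequence exactly.
#'
#' @param proteins Tibble with columns `protein_id` and `sequence` (one or
#'   more rows).
#' @param matrix,gap_open,gap_extend Scoring parameters, as in
#'   [smith_waterman()].
#' @return An `msa` tibble (columns `member_id`, `aligned`) with members in
#'   input order.
#' @export
progressive_msa <- function(proteins, matrix = blosum62(), gap_open = 11,
                            gap_extend = 1) {
  ids <- proteins$protein_id
  seqs <- proteins$sequence
  if (anyDuplicated(ids)) abort("duplicate member ids")
  n <- length(seqs)
  if (n == 0) abort("no sequences")
  if (n == 1) return(new_msa(ids, seqs))
  S <- matrix[AA_ALPHABET, AA_ALPHABET]
  align_groups <- function(ga, gb) {
    pa <- msa_profile(ga$rows); pb <- msa_profile(gb$rows)
    ops <- profile_align_cpp(pa, pb, S, gap_open, gap_extend)
    merged <- merge_by_ops(ga$rows, gb$rows, ops)
    list(ids = c(ga$ids, gb$ids), rows = merged)
  }
  if (n == 2) {
    res <- align_groups(list(ids = ids[1], rows = seqs[1]),
                        list(ids = ids[2], rows = seqs[2]))
  } else {
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      aln <- smith_waterman(seqs[i], seqs[j], matrix, gap_open, gap_extend)
      d <- if (is.na(aln$identity)) 1 else 1 - aln$identity
      D[i, j] <- d; D[j, i] <- d
    }
    guide <- ape::nj(stats::as.dist(D))
    guide$edge.length[guide$edge.length < 0] <- 0
    guide <- phangorn::midpoint(guide)
    seq_of <- stats::setNames(seqs, ids)
    merge_node <- function(node) {
      ntip <- length(guide$tip.label)
      if (node <= ntip) {
        id <- guide$tip.label[node]
        return(list(ids = id, rows = unname(seq_of[id])))
      }
      kids <- guide$edge[guide$edge[, 1] == node, 2]
      acc <- merge_node(kids[1])
      for (k in kids[-1]) acc <- align_groups(acc, merge_node(k))
      acc
    }
    root <- length(guide$tip.label) + 1L
    res <- merge_node(root)
  }
  ord <- match(ids, res$ids)
  new_msa(ids, res$rows[ord])
}

#' Map a reference residue position to its alignment column
#'
#' @param msa An `msa` tibble.
#' @param reference_id Member id of the reference row.
#' @param ref_pos 1-based position(s) in the degapped reference sequence.
#' @return Integer alignment column(s), 1-based.
#' @export
map_reference_position <- function(msa, reference_id, ref_pos) {
  row <- msa$aligned[msa$member_id == reference_id]
  if (length(row) != 1) abort(paste0("no such member: ", reference_id))
  chars <- strsplit(row, "", fixed = TRUE)[[1]]
  residue_cols <- which(chars != "-")
  if (any(ref_pos < 1) || any(ref_pos > length(residue_cols))) {
    abort("position beyond reference length")
  }
  residue_cols[ref_pos]
}

#' Map an alignment column back to a member's sequence position
#'
#' Inverse of [map_reference_position()]: returns the 1-based degapped
#' position of `member_id`'s residue in the given column, or `NA` if the
#' member is gapped there.
#'
#' @param msa An `msa` tibble.
#' @param member_id Member id.
#' @param column 1-based alignment column(s).
#' @return Integer position(s) or `NA`.
#' @export
map_alignment_column <- function(msa, member_id, column) {
  row <- msa$aligned[msa$member_id == member_id]
  if (length(row) != 1) abort(paste0("no such member: ", member_id))
  chars <- strsplit(row, "", fixed = TRUE)[[1]]
  if (any(column < 1) || any(column > length(chars))) {
    abort("column beyond alignment width")
  }
  pos <- cumsum(chars != "-")
  ifelse(chars[column] == "-", NA_integer_, pos[column])
}

#' Construct a residue anchor
#'
#' A residue anchor names a set of functionally required positions on an
#' annotated reference sequence (e.g. the amidase zinc-binding triad, or
#' the glucanase active-site glutamates at reference positions 188 and
#' 193), together with the residue letters expected at each.
#'
#' @param anchor_id Anchor name.
#' @param reference_id Id of the annotated reference sequence.
#' @param positions Strictly increasing 1-based reference positions.
#' @param expected Character vector, one element per position; each element
#'   is a string of acceptable letters (e.g. `"E"` or `"HN"`).
#' @return One-row anchors tibble (`anchor_id`, `reference_id`, `positions`,
#'   `expected` as list-columns).
#' @export
residue_anchor <- function(anchor_id, reference_id, positions, expected) {
  positions <- as.integer(positions)
  if (is.unsorted(positions, strictly = TRUE)) {
    abort("anchor positions must be strictly increasing")
  }
  if (length(expected) != length(positions)) {
    abort("one expected-letter set per position required")
  }
  tibble(anchor_id = anchor_id, reference_id = reference_id,
         positions = list(positions), expected = list(expected))
}

#' Read the residue states of a member at an anchor
#'
#' Maps each anchored reference position to its alignment column and reads
#' off the member's letter there (`-` when gapped). This is the measurement
#' behind all residue-based functional calls (amidase triad, glucanase
#' glutamate pair).
#'
#' @param msa An `msa` tibble containing both the member and the anchor's
#'   reference.
#' @param member_id Member to read.
#' @param anchor One-row anchors tibble (see [residue_anchor()]).
#' @return A list with `states` (tibble: `position`, `column`, `expected`,
#'   `observed`, `ok`) and `all_expected` (TRUE iff every position holds an
#'   expected letter).
#' @export
residue_state_at_anchor <- function(msa, member_id, anchor) {
  if (!member_id %in% msa$member_id) {
    abort(paste0("member absent from msa: ", member_id))
  }
  positions <- anchor$positions[[1]]
  expected <- anchor$expected[[1]]
  cols <- map_reference_position(msa, anchor$reference_id, positions)
  row <- strsplit(msa$aligned[msa$member_id == member_id], "")[[1]]
  observed <- row[cols]
  ok <- mapply(function(obs, exp) {
    obs %in% strsplit(exp, "", fixed = TRUE)[[1]]
  }, observed, expected, USE.NAMES = FALSE)
  list(states = tibble(position = positions, column = cols,
                       expected = expected, observed = observed, ok = ok),
       all_expected = all(ok))
}

#' Degap an alignment row
#' @param msa An `msa` tibble.
#' @param member_id Member id (default: all members).
#' @return Named character vector of ungapped sequences.
#' @export
msa_degap <- function(msa, member_id = msa$member_id) {
  rows <- msa$aligned[match(member_id, msa$member_id)]
  stats::setNames(gsub("-", "", rows, fixed = TRUE), member_id)
}

#' Write a multiple alignment as aligned FASTA
#' @param msa An `msa` tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_msa <- function(msa, path) {
  write_fasta(tibble(protein_id = msa$member_id, sequence = msa$aligned),
              path)
}

#' Read an aligned FASTA file as an `msa`
#' @param path Path to aligned FASTA (rows may contain `-`).
#' @return An `msa` tibble.
#' @export
read_msa <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- which(startsWith(lines, ">"))
  ids <- sub("^>", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1)
  starts <- hdr + 1L; ends <- c(hdr[-1] - 1L, length(lines))
  rows <- vapply(seq_along(hdr), function(i) {
    toupper(paste(lines[starts[i]:ends[i]], collapse = ""))
  }, character(1))
  new_msa(ids, rows)
}
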