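#' Compile a degenerate protein motif
#'
#' Degenerate motifs are patterns over the 20 amino acids plus `X`, where
#' `X` matches any residue and every other letter matches exactly. Examples
#' are the thioester motif `GCGEQ` and the 26-residue NIM repeat motif
#' `CXPXCXXXCXNGXCXXPXXCXCXXGY`.
#'
#' @param pattern Pattern string; length at least 3 with at least one
#'   non-`X` position.
#' @param motif_id Motif name (defaults to the pattern itself).
#' @return An object of class `degenerate_motif` (list with `motif_id`,
#'   `pattern`, `length`, `fixed` — integer positions that must match).
#' @export
compile_degenerate_motif <- function(pattern, motif_id = pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  if (!all(chars %in% AA_ALPHABET)) {
    abort(paste0("illegal character in motif pattern: ",
                 paste(setdiff(unique(chars), AA_ALPHABET), collapse = ", ")))
  }
  if (length(chars) < 3) abort("motif pattern must have length >= 3")
  fixed <- which(chars != "X")
  if (length(fixed) == 0) abort("motif pattern needs at least one fixed position")
  structure(list(motif_id = motif_id, pattern = pattern,
                 length = length(chars), fixed = fixed,
                 fixed_letters = chars[fixed]),
            class = "degenerate_motif")
}

#' Scan a sequence for a degenerate motif
#'
#' Reports every (possibly overlapping) placement where all fixed motif
#' positions match exactly, left to right.
#'
#' @param sequence Amino-acid string, or a protein tibble row set with a
#'   `sequence` column (then hits carry `species`/`protein_id`).
#' @param motif A `degenerate_motif` (or pattern string, compiled on the
#'   fly).
#' @return Tibble of hits: `motif_id`, `start`, `end` (1-based inclusive),
#'   plus `species` and `protein_id` when a protein tibble was given.
#' @export
scan_motif <- function(sequence, motif) {
  if (is.character(motif)) motif <- compile_degenerate_motif(motif)
  if (is.data.frame(sequence)) {
    hits <- purrr::map_dfr(seq_len(nrow(sequence)), function(i) {
      h <- scan_motif(sequence$sequence[i], motif)
      if (nrow(h)) {
        h$species <- sequence$species[i]
        h$protein_id <- sequence$protein_id[i]
      }
      h
    })
    if (nrow(hits) == 0) {
      hits <- tibble(motif_id = character(0), start = integer(0),
                     end = integer(0), species = character(0),
                     protein_id = character(0))
    }
    return(hits)
  }
  n <- nchar(sequence)
  W <- motif$length
  if (n < W) {
    return(tibble(motif_id = character(0), start = integer(0),
                  end = integer(0)))
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  starts <- seq_len(n - W + 1)
  ok <- rep(TRUE, length(starts))
  for (k in seq_along(motif$fixed)) {
    off <- motif$fixed[k] - 1L
    ok <- ok & chars[starts + off] == motif$fixed_letters[k]
  }
  hit_starts <- starts[ok]
  tibble(motif_id = motif$motif_id, start = hit_starts,
         end = hit_starts + W - 1L)
}

#' Build a position-specific scoring matrix from an alignment
#'
#' Per-column log-odds scores against a background, with add-pseudocount
#' smoothing. Columns with more than 50% gaps are dropped. The detection
#' threshold is calibrated at build time as the minimum score of the
#' training rows on their own model minus `margin`, so every training
#' sequence is detectable by construction while random sequences fall far
#' below (each column of an unrelated sequence scores at its expected
#' negative log-odds).
#'
#' @param msa Training alignment (`msa` tibble, at least 2 rows).
#' @param pseudocount Added to every letter count per column (default 0.5).
#' @param background Named background frequencies over the 20 canonical
#'   letters; default is the training-set residue composition.
#' @param margin Per-column score margin: `margin * width` log2 units are
#'   subtracted from the minimum training self-score to form the
#'   threshold. A substituted column costs roughly 7-8 log2 units against
#'   a well-conserved model, so the default of 2 tolerates about 25%
#'   column divergence beyond the training rows, while an unrelated
#'   sequence (about -3 log2 units per column in expectation) stays far
#'   below threshold.
#' @param domain Domain name carried by hits.
#' @return An object of class `pssm`: list with `domain`, `mat`
#'   (columns x 21 log2-odds, X scores 0), `threshold`, `background`,
#'   `width`.
#' @export
build_pssm <- function(msa, pseudocount = 0.5, background = NULL,
                       margin = 2, domain = "domain") {
  if (nrow(msa) < 2) abort("PSSM training alignment needs >= 2 rows")
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  m <- msa_matrix(msa)
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac <= 0.5
  if (!any(keep)) abort("all alignment columns are majority-gap")
  m <- m[, keep, drop = FALSE]
  if (is.null(background)) {
    # training-set composition smoothed 1:1 with uniform: a small training
    # sample must not assign near-zero background to unseen letters, which
    # would make them score positive in every column
    letters_used <- m[m %in% AA20]
    tab <- table(factor(letters_used, levels = AA20))
    background <- 0.5 * as.numeric(tab) / sum(tab) + 0.5 / 20
    names(background) <- AA20
  } else {
    background <- background[AA20] / sum(background[AA20])
  }
  W <- ncol(m)
  mat <- matrix(0, W, 21, dimnames = list(NULL, AA_ALPHABET))
  for (j in seq_len(W)) {
    col <- m[, j]
    counts <- table(factor(col[col %in% AA20], levels = AA20))
    freqs <- (as.numeric(counts) + pseudocount) /
      (sum(counts) + 20 * pseudocount)
    mat[j, AA20] <- log2(freqs / background)
    mat[j, "X"] <- 0
  }
  pssm <- structure(list(domain = domain, mat = mat, width = W,
                         background = background, threshold = NA_real_),
                    class = "pssm")
  self <- vapply(msa_degap(msa), function(s) {
    sc <- pssm_window_scores_cpp(encode_seq(s), mat)
    if (length(sc) == 0) -Inf else max(sc)
  }, numeric(1))
  pssm$threshold <- min(self) - margin * W
  pssm
}

# Greedy reduction of scored windows to non-overlapping hits: descending
# score, ties to the leftmost start. Scores are compared at 1e-6
# resolution so the outcome does not depend on floating-point summation
# order.
reduce_hits_greedy <- function(starts, ends, scores) {
  ord <- order(-round(scores, 6), starts)
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) == 0 ||
        !any(starts[i] <= ends[sel] & ends[i] >= starts[sel])) {
      sel <- c(sel, i)
    }
  }
  sort(sel)
}

#' Scan a sequence with a PSSM
#'
#' Scores every window placement of the model along the sequence and keeps
#' placements at or above the model threshold, greedily reduced to
#' non-overlapping hits by descending score (compared at 1e-6 resolution;
#' ties to the leftmost).
#'
#' @param sequence Amino-acid string or protein tibble (as in
#'   [scan_motif()]).
#' @param pssm A `pssm` object.
#' @param reduce Apply the greedy non-overlap reduction (default TRUE).
#' @return Tibble of hits: `domain`, `start`, `end`, `score` (plus
#'   `species`/`protein_id` for tibble input).
#' @export
scan_pssm <- function(sequence, pssm, reduce = TRUE) {
  if (is.data.frame(sequence)) {
    hits <- purrr::map_dfr(seq_len(nrow(sequence)), function(i) {
      h <- scan_pssm(sequence$sequence[i], pssm, reduce)
      if (nrow(h)) {
        h$species <- sequence$species[i]
        h$protein_id <- sequence$protein_id[i]
      }
      h
    })
    if (nrow(hits) == 0) {
      hits <- tibble(domain = character(0), start = integer(0),
                     end = integer(0), score = numeric(0),
                     species = character(0), protein_id = character(0))
    }
    return(hits)
  }
  sc <- pssm_window_scores_cpp(encode_seq(sequence), pssm$mat)
  starts <- which(sc >= pssm$threshold)
  if (length(starts) == 0) {
    return(tibble(domain = character(0), start = integer(0),
                  end = integer(0), score = numeric(0)))
  }
  ends <- starts + pssm$width - 1L
  scores <- sc[starts]
  if (reduce) {
    sel <- reduce_hits_greedy(starts, ends, scores)
    starts <- starts[sel]; ends <- ends[sel]; scores <- scores[sel]
  }
  tibble(domain = pssm$domain, start = as.integer(starts),
         end = as.integer(ends), score = scores)
}

#' Default RHIM consensus pattern
#'
#' The bundled degenerate consensus for the RIP homotypic interaction
#' motif (the Imd-binding segment of transmembrane PGRPs), centred on the
#' conserved I-Q-I-G core. This is a configuration default, not a
#' literature constant; replace it via the `motif` argument of
#' [scan_rhim()] for a different model.
#'
#' @return Pattern string.
#' @export
rhim_consensus <- function() "XIQIGXXNXMX"

#' Scan for the RHIM (Imd-binding) segment
#'
#' @param sequence Amino-acid string or protein tibble.
#' @param motif Degenerate pattern for the RHIM consensus (default
#'   [rhim_consensus()]).
#' @return A list with `present` (TRUE iff at least one hit) and `hits`
#'   (motif-hit tibble).
#' @export
scan_rhim <- function(sequence, motif = rhim_consensus()) {
  hits <- scan_motif(sequence, compile_degenerate_motif(motif, "RHIM"))
  list(present = nrow(hits) > 0, hits = hits)
}

#' Write domain hits in a profile-search domain-table layout
#'
#' Columns: target id, domain name, start, end, score — the coordinate and
#' score fields of HMMER3 `--domtblout`-style rows, so externally produced
#' domain tables can be swapped in.
#'
#' @param hits Domain-hit tibble (`species`, `protein_id`, `domain`,
#'   `start`, `end`, `score`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_domain_hits <- function(hits, path) {
  df <- tibble(target = paste0(hits$species, "|", hits$protein_id),
               domain = hits$domain, start = hits$start, end = hits$end,
               score = sprintf("%.2f", hits$score))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a domain-hit table written by [write_domain_hits()]
#' @param path Path to the TSV.
#' @return Domain-hit tibble.
#' @export
read_domain_hits <- function(path) {
  df <- readr::read_tsv(path, col_types = "cciid", progress = FALSE)
  parts <- stringr::str_split_fixed(df$target, stringr::fixed("|"), 2)
  tibble(species = parts[, 1], protein_id = parts[, 2],
         domain = df$domain, start = df$start, end = df$end,
         score = df$score)
}
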