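#' Predict transmembrane helices by hydropathy
#'
#' Kyte-Doolittle sliding-window scan: a residue belongs to a candidate
#' segment when the mean hydropathy of the window centred on it exceeds
#' `threshold`; maximal runs shorter than 15 residues are discarded. This
#' is a deliberately simple heuristic detector for the strongly hydrophobic
#' single-pass helices the synthetic constructs carry; it does not model
#' helix topology.
#'
#' @param sequence Amino-acid string.
#' @param window Sliding-window width (odd, default 19).
#' @param threshold Mean-hydropathy cutoff (default 1.6).
#' @param min_len Minimum segment length (default 15).
#' @return Tibble of segments: `start`, `end` (1-based inclusive),
#'   `hydropathy` (mean over the segment). Empty for sequences shorter
#'   than `window`.
#' @export
predict_tm <- function(sequence, window = 19, threshold = 1.6,
                       min_len = 15) {
  n <- nchar(sequence)
  empty <- tibble(start = integer(0), end = integer(0),
                  hydropathy = numeric(0))
  if (n < window) return(empty)
  kd <- unname(KD_SCALE[strsplit(sequence, "", fixed = TRUE)[[1]]])
  win_mean <- as.numeric(stats::filter(kd, rep(1 / window, window),
                                       sides = 2))
  half <- (window - 1) %/% 2
  centers <- (half + 1):(n - half)
  hot <- win_mean[centers] > threshold
  r <- rle(hot)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1
  segs <- which(r$values & r$lengths >= min_len)
  if (length(segs) == 0) return(empty)
  out <- tibble(start = centers[starts_idx[segs]],
                end = centers[ends_idx[segs]])
  out$hydropathy <- vapply(seq_len(nrow(out)), function(i) {
    mean(kd[out$start[i]:out$end[i]])
  }, numeric(1))
  out
}

#' Predict an N-terminal signal peptide
#'
#' Heuristic stand-in for a dedicated signal-peptide predictor: the call is
#' TRUE when the first 30 residues contain a hydrophobic core of at least
#' `core` residues (a window of that width whose mean Kyte-Doolittle
#' hydropathy exceeds `threshold`), and the hydrophobic stretch is not the
#' start of a transmembrane segment extending past residue 35 (which marks
#' a signal anchor rather than a cleaved signal).
#'
#' @param sequence Amino-acid string (sequences shorter than 25 residues
#'   are called FALSE).
#' @param core Hydrophobic-core width (default 8).
#' @param threshold Mean-hydropathy cutoff (default 1.6).
#' @return Logical.
#' @export
predict_signal_peptide <- function(sequence, core = 8, threshold = 1.6) {
  n <- nchar(sequence)
  if (n < 25) return(FALSE)
  kd <- unname(KD_SCALE[strsplit(sequence, "", fixed = TRUE)[[1]]])
  last_start <- min(30 - core + 1, n - core + 1)
  if (last_start < 1) return(FALSE)
  core_means <- vapply(seq_len(last_start), function(i) {
    mean(kd[i:(i + core - 1)])
  }, numeric(1))
  if (!any(core_means > threshold)) return(FALSE)
  tm <- predict_tm(sequence)
  anchor <- nrow(tm) > 0 && any(tm$start <= 30 & tm$end > 35)
  !anchor
}

#' Derive the cellular localization call
#'
#' Rule precedence: a transmembrane segment outside the first 35 residues
#' makes the protein `transmembrane` regardless of signal peptide; otherwise
#' a signal peptide makes it `secreted`; otherwise it is `intracellular`.
#'
#' @param signal_peptide Logical.
#' @param tm_segments TM-segment tibble from [predict_tm()].
#' @return One of `"transmembrane"`, `"secreted"`, `"intracellular"`.
#' @export
localize <- function(signal_peptide, tm_segments) {
  if (!is.null(tm_segments) && nrow(tm_segments) > 0 &&
      any(tm_segments$start > 35)) {
    return("transmembrane")
  }
  if (isTRUE(signal_peptide)) return("secreted")
  "intracellular"
}

# Default LRR consensus classes: L-type and N-type position sets of the
# degenerate core consensus LxxLxLxxNxL.
LRR_L_CLASS <- c("L", "I", "V", "F")
LRR_N_CLASS <- c("N", "C", "T", "S")

#' Find leucine-rich repeats
#'
#' Matches the degenerate LRR core consensus `LxxLxLxxNxL` (`L` = any of
#' L/I/V/F, `N` = any of N/C/T/S, `x` = any residue) and merges matches
#' separated by at most `merge_gap` residues into repeat blocks.
#'
#' @param sequence Amino-acid string.
#' @param l_class,n_class Residue classes for the L and N consensus
#'   positions.
#' @param merge_gap Maximum separation for merging adjacent matches
#'   (default 5).
#' @return Tibble of repeat blocks: `start`, `end`, `n_repeats` (number of
#'   consensus matches in the block), in sequence order.
#' @export
find_lrrs <- function(sequence, l_class = LRR_L_CLASS,
                      n_class = LRR_N_CLASS, merge_gap = 5) {
  n <- nchar(sequence)
  W <- 11L
  empty <- tibble(start = integer(0), end = integer(0),
                  n_repeats = integer(0))
  if (n < W) return(empty)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  starts <- seq_len(n - W + 1)
  ok <- chars[starts] %in% l_class &
    chars[starts + 3L] %in% l_class &
    chars[starts + 5L] %in% l_class &
    chars[starts + 8L] %in% n_class &
    chars[starts + 10L] %in% l_class
  hit_starts <- starts[ok]
  if (length(hit_starts) == 0) return(empty)
  hit_ends <- hit_starts + W - 1L
  block_start <- hit_starts[1]; block_end <- hit_ends[1]; count <- 1L
  out <- list()
  for (i in seq_along(hit_starts)[-1]) {
    if (hit_starts[i] - block_end - 1L <= merge_gap) {
      block_end <- max(block_end, hit_ends[i]); count <- count + 1L
    } else {
      out[[length(out) + 1]] <- tibble(start = block_start,
                                       end = block_end, n_repeats = count)
      block_start <- hit_starts[i]; block_end <- hit_ends[i]; count <- 1L
    }
  }
  out[[length(out) + 1]] <- tibble(start = block_start, end = block_end,
                                   n_repeats = count)
  dplyr::bind_rows(out)
}

#' Find cysteine clusters
#'
#' Greedy left-to-right detection of cysteine clusters: starting from each
#' unconsumed cysteine, all cysteines within `window` residues of it form a
#' candidate cluster, accepted when it holds at least `min_cys` cysteines.
#' A cluster is flagged juxtamembrane when its end lies within
#' `juxta_dist` residues of the first transmembrane-segment start.
#'
#' @param sequence Amino-acid string.
#' @param region Length-2 integer vector restricting the scan (1-based
#'   inclusive); default the whole sequence.
#' @param window Maximum cluster span (default 12).
#' @param min_cys Minimum cysteines per cluster (default 2).
#' @param tm_segments Optional TM tibble for the juxtamembrane flag.
#' @param juxta_dist Juxtamembrane distance (default 30).
#' @return Tibble: `start`, `end`, `n_cys`, `juxtamembrane`.
#' @export
find_cys_clusters <- function(sequence, region = NULL, window = 12,
                              min_cys = 2, tm_segments = NULL,
                              juxta_dist = 30) {
  n <- nchar(sequence)
  if (is.null(region)) region <- c(1L, n)
  if (region[1] < 1 || region[2] > n || region[1] > region[2]) {
    abort("region outside sequence")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  cys <- which(chars == "C")
  cys <- cys[cys >= region[1] & cys <= region[2]]
  out <- list()
  i <- 1L
  while (i <= length(cys)) {
    inwin <- cys[cys >= cys[i] & cys <= cys[i] + window - 1L]
    if (length(inwin) >= min_cys) {
      out[[length(out) + 1]] <- tibble(start = min(inwin), end = max(inwin),
                                       n_cys = length(inwin))
      i <- i + length(inwin)
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0) {
    return(tibble(start = integer(0), end = integer(0), n_cys = integer(0),
                  juxtamembrane = logical(0)))
  }
  res <- dplyr::bind_rows(out)
  tm_start <- if (!is.null(tm_segments) && nrow(tm_segments) > 0)
    min(tm_segments$start) else NA_integer_
  res$juxtamembrane <- if (is.na(tm_start)) FALSE else
    abs(tm_start - res$end) <= juxta_dist
  res
}

#' Compute the full structural profile of each protein
#'
#' Runs the transmembrane, signal-peptide, LRR and cysteine-cluster
#' predictors and derives the localization call. Cysteine clusters are
#' scanned in the ectodomain (the region N-terminal of the first
#' transmembrane segment when one exists past residue 35; otherwise the
#' whole sequence).
#'
#' @param proteins Protein tibble.
#' @param ... Passed to the individual predictors.
#' @return Tibble with one row per protein: `species`, `protein_id`,
#'   `signal_peptide`, `localization`, `n_tm`, `n_lrr`, `n_cys_clusters`,
#'   and list-columns `tm`, `lrrs`, `cys_clusters`.
#' @export
predict_structure <- function(proteins, ...) {
  purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    s <- proteins$sequence[i]
    tm <- predict_tm(s)
    sig <- predict_signal_peptide(s)
    lrr <- find_lrrs(s)
    ecto_tm <- tm[tm$start > 35, , drop = FALSE]
    region <- if (nrow(ecto_tm) > 0) c(1L, min(ecto_tm$start) - 1L) else
      c(1L, nchar(s))
    cys <- find_cys_clusters(s, region = region, tm_segments = ecto_tm)
    tibble(species = proteins$species[i],
           protein_id = proteins$protein_id[i],
           signal_peptide = sig,
           localization = localize(sig, tm),
           n_tm = nrow(tm),
           n_lrr = sum(lrr$n_repeats),
           n_cys_clusters = nrow(cys),
           tm = list(tm), lrrs = list(lrr), cys_clusters = list(cys))
  })
}
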