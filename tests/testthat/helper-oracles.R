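# Independent oracles, coded separately from the package implementations.

AA20_T <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
            "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(n, letters = AA20_T) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Full-matrix affine-gap local alignment score (Gotoh), plain R.
# Same convention as the package: a gap of length k costs open + k*extend.
oracle_sw_score <- function(a, b, S = blosum62(), go = 11, ge = 1) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  FF <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - go - ge, E[i, j - 1] - ge)
      FF[i, j] <- max(H[i - 1, j] - go - ge, FF[i - 1, j] - ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + S[A[i - 1], B[j - 1]],
                     E[i, j], FF[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Regular-expression oracle for degenerate motifs (overlapping matches via
# lookahead).
oracle_motif_starts <- function(seq, pattern) {
  rx <- gsub("X", ".", pattern, fixed = TRUE)
  m <- gregexpr(paste0("(?=", rx, ")"), seq, perl = TRUE)[[1]]
  s <- as.integer(m)
  if (length(s) == 1 && s == -1) integer(0) else s
}

# Brute-force sliding-window PSSM scan with an independently coded greedy
# non-overlap reduction (descending score, ties leftmost).
oracle_pssm_scan <- function(seq, pssm) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  W <- pssm$width
  L <- length(chars)
  if (L < W) return(data.frame(start = integer(0), score = numeric(0)))
  cand <- data.frame(start = integer(0), score = numeric(0))
  for (i in seq_len(L - W + 1)) {
    sc <- 0
    for (j in seq_len(W)) sc <- sc + pssm$mat[j, chars[i + j - 1]]
    if (sc >= pssm$threshold) {
      cand <- rbind(cand, data.frame(start = i, score = sc))
    }
  }
  kept <- data.frame(start = integer(0), score = numeric(0))
  while (nrow(cand) > 0) {
    rs <- round(cand$score, 6)  # tie resolution at 1e-6, as documented
    top <- which(rs == max(rs))
    top <- top[which.min(cand$start[top])]
    kept <- rbind(kept, cand[top, ])
    s <- cand$start[top]
    cand <- cand[cand$start + W - 1 < s | cand$start > s + W - 1, ,
                 drop = FALSE]
  }
  kept[order(kept$start), , drop = FALSE]
}

# Random gapped alignment row set built around one ungapped source per row.
random_gapped_msa <- function(n_rows = 3, len = 30, n_gaps = 8) {
  width <- len + n_gaps
  rows <- vapply(seq_len(n_rows), function(i) {
    chars <- rep("-", width)
    chars[sort(sample(width, len))] <- strsplit(random_seq(len), "")[[1]]
    paste(chars, collapse = "")
  }, character(1))
  immunotrace:::new_msa(paste0("m", seq_len(n_rows)), rows)
}

# Column-counting distance oracle for msa_distances.
oracle_p_distance <- function(row_a, row_b) {
  a <- strsplit(row_a, "", fixed = TRUE)[[1]]
  b <- strsplit(row_b, "", fixed = TRUE)[[1]]
  both <- a != "-" & b != "-"
  mean(a[both] != b[both])
}

# Small PSSM built from a random family for oracle tests.
random_pssm <- function(width = 20, n_rows = 5, margin = 2) {
  base <- random_seq(width)
  rows <- vapply(seq_len(n_rows), function(i) {
    mutate_sequence(base, 0.1)
  }, character(1))
  msa <- immunotrace:::new_msa(paste0("t", seq_len(n_rows)), rows)
  list(pssm = build_pssm(msa, margin = margin, domain = "toy"),
       base = base)
}
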