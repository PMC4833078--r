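#' @useDynLib immunotrace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import tibble
#' @importFrom rlang .data abort warn
#' @importFrom dplyr %>%
NULL

# 21-letter protein alphabet: the 20 canonical residues plus X (unknown).
# All integer encodings used by the C++ kernels index into this order.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

AA20 <- AA_ALPHABET[1:20]

# Kyte-Doolittle hydropathy scale (X neutral).
KD_SCALE <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
              H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
              P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
              W = -0.9, Y = -1.3, X = 0)

# Background amino-acid frequencies used for linker/background synthesis
# and as the default PSSM background (Robinson & Robinson-style average
# composition, renormalised over the 20 canonical letters).
AA_BACKGROUND <- c(A = 0.0788, C = 0.0151, D = 0.0535, E = 0.0668,
                   F = 0.0397, G = 0.0696, H = 0.0229, I = 0.0590,
                   K = 0.0595, L = 0.0964, M = 0.0238, N = 0.0413,
                   P = 0.0457, Q = 0.0395, R = 0.0540, S = 0.0683,
                   T = 0.0541, V = 0.0673, W = 0.0114, Y = 0.0333)

#' BLOSUM62 substitution matrix over the 21-letter alphabet
#'
#' Standard BLOSUM62 substitution scores for the 20 canonical amino acids.
#' The unknown residue X scores 0 against everything (neutral), which keeps
#' masked positions from either rewarding or penalising an alignment.
#'
#' @return A 21 x 21 integer matrix with dimnames over
#'   `A C D E F G H I K L M N P Q R S T V W Y X`.
#' @export
#' @examples
#' blosum62()["W", "W"]  # 11
blosum62 <- function() {
  v <- c(
    4, 0, -2, -1, -2, 0, -2, -1, -1, -1, -1, -2, -1, -1, -1, 1, 0, 0, -3, -2,
    0, 9, -3, -4, -2, -3, -3, -1, -3, -1, -1, -3, -3, -3, -3, -1, -1, -1, -2, -2,
    -2, -3, 6, 2, -3, -1, -1, -3, -1, -4, -3, 1, -1, 0, -2, 0, -1, -3, -4, -3,
    -1, -4, 2, 5, -3, -2, 0, -3, 1, -3, -2, 0, -1, 2, 0, 0, -1, -2, -3, -2,
    -2, -2, -3, -3, 6, -3, -1, 0, -3, 0, 0, -3, -4, -3, -3, -2, -2, -1, 1, 3,
    0, -3, -1, -2, -3, 6, -2, -4, -2, -4, -3, 0, -2, -2, -2, 0, -2, -3, -2, -3,
    -2, -3, -1, 0, -1, -2, 8, -3, -1, -3, -2, 1, -2, 0, 0, -1, -2, -3, -2, 2,
    -1, -1, -3, -3, 0, -4, -3, 4, -3, 2, 1, -3, -3, -3, -3, -2, -1, 3, -3, -1,
    -1, -3, -1, 1, -3, -2, -1, -3, 5, -2, -1, 0, -1, 1, 2, 0, -1, -2, -3, -2,
    -1, -1, -4, -3, 0, -4, -3, 2, -2, 4, 2, -3, -3, -2, -2, -2, -1, 1, -2, -1,
    -1, -1, -3, -2, 0, -3, -2, 1, -1, 2, 5, -2, -2, 0, -1, -1, -1, 1, -1, -1,
    -2, -3, 1, 0, -3, 0, 1, -3, 0, -3, -2, 6, -2, 0, 0, 1, 0, -3, -4, -2,
    -1, -3, -1, -1, -4, -2, -2, -3, -1, -3, -2, -2, 7, -1, -2, -1, -1, -2, -4, -3,
    -1, -3, 0, 2, -3, -2, 0, -3, 1, -2, 0, 0, -1, 5, 1, 0, -1, -2, -2, -1,
    -1, -3, -2, 0, -3, -2, 0, -3, 2, -2, -1, 0, -2, 1, 5, -1, -1, -3, -3, -2,
    1, -1, 0, 0, -2, 0, -1, -2, 0, -2, -1, 1, -1, 0, -1, 4, 1, -2, -3, -2,
    0, -1, -1, -1, -2, -2, -2, -1, -1, -1, -1, 0, -1, -1, -1, 1, 5, 0, -2, -2,
    0, -1, -3, -2, -1, -3, -3, 3, -2, 1, 1, -3, -2, -2, -3, -2, 0, 4, -3, -1,
    -3, -2, -4, -3, 1, -2, -2, -3, -3, -2, -1, -4, -4, -2, -3, -3, -2, -3, 11, 2,
    -2, -2, -3, -2, 3, -3, 2, -1, -2, -1, -1, -2, -3, -1, -2, -2, -2, -1, 2, 7)
  m <- matrix(0L, 21, 21, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  m[1:20, 1:20] <- as.integer(v)
  m
}

# Encode a sequence string as 1-based integers over AA_ALPHABET.
encode_seq <- function(x) {
  idx <- match(strsplit(x, "", fixed = TRUE)[[1]], AA_ALPHABET)
  if (anyNA(idx)) {
    abort(paste0("sequence contains letters outside the 21-letter alphabet: ",
                 paste(unique(setdiff(strsplit(x, "")[[1]], AA_ALPHABET)),
                       collapse = ", ")))
  }
  idx
}

decode_seq <- function(idx) paste(AA_ALPHABET[idx], collapse = "")

# Validate an amino-acid sequence string; returns TRUE or a message.
valid_aa <- function(x) {
  all(strsplit(x, "", fixed = TRUE)[[1]] %in% AA_ALPHABET)
}
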