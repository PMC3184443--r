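# Substitution matrices and ungapped Karlin-Altschul statistics.

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")

.BLOSUM62_VALUES <- c(
   4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
  -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
  -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
  -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
   0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
  -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
  -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
   0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
  -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
  -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
  -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
  -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,
  -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,
  -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,
  -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,
   1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,
   0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,
  -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,
  -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,
   0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4)

#' BLOSUM62 substitution matrix
#'
#' The standard 20x20 BLOSUM62 values plus an `X` row/column scored -1
#' against everything.
#'
#' @return Integer matrix with dimnames over the 20 residues plus `X`.
#' @export
blosum62 <- function() {
  m <- matrix(.BLOSUM62_VALUES, 20, 20, byrow = TRUE,
              dimnames = list(.AA20, .AA20))
  m <- rbind(cbind(m, X = -1L), X = -1L)
  rownames(m)[21] <- "X"
  storage.mode(m) <- "integer"
  m
}

.PAM30_VALUES <- c(
    6, -7, -4, -3, -6, -4, -2, -2, -7, -5, -6, -7, -5, -8, -2,  0, -1,-13, -8, -2,
   -7,  8, -6,-10, -8, -2, -9, -9, -2, -5, -8,  0, -4, -9, -4, -3, -6, -2,-10, -8,
   -4, -6,  8,  2,-11, -3, -2, -3,  0, -5, -7, -1, -9, -9, -6,  0, -2, -8, -4, -8,
   -3,-10,  2,  8,-14, -2,  2, -3, -4, -7,-12, -4,-11,-15, -8, -4, -5,-15,-11, -8,
   -6, -8,-11,-14, 10,-14,-14, -9, -7, -6,-15,-14,-13,-13, -8, -3, -8,-15, -4, -6,
   -4, -2, -3, -2,-14,  8,  1, -7,  1, -8, -5, -3, -4,-13, -3, -5, -5,-13,-12, -7,
   -2, -9, -2,  2,-14,  1,  8, -4, -5, -5, -9, -4, -7,-14, -5, -4, -6,-17, -8, -6,
   -2, -9, -3, -3, -9, -7, -4,  6, -9,-11,-10, -7, -8, -9, -6, -2, -6,-15,-14, -5,
   -7, -2,  0, -4, -7,  1, -5, -9,  9, -9, -6, -6,-10, -6, -4, -6, -7, -7, -3, -6,
   -5, -5, -5, -7, -6, -8, -5,-11, -9,  8, -1, -6, -1, -2, -8, -7, -2,-14, -6,  2,
   -6, -8, -7,-12,-15, -5, -9,-10, -6, -1,  7, -8,  1, -3, -7, -8, -7, -6, -7, -2,
   -7,  0, -1, -4,-14, -3, -4, -7, -6, -6, -8,  7, -2,-14, -6, -4, -3,-12, -9, -9,
   -5, -4, -9,-11,-13, -4, -7, -8,-10, -1,  1, -2, 11, -4, -8, -5, -4,-13,-11, -1,
   -8, -9, -9,-15,-13,-13,-14, -9, -6, -2, -3,-14, -4,  9,-10, -6, -9, -4,  2, -8,
   -2, -4, -6, -8, -8, -3, -5, -6, -4, -8, -7, -6, -8,-10,  8, -2, -4,-14,-13, -6,
    0, -3,  0, -4, -3, -5, -4, -2, -6, -7, -8, -4, -5, -6, -2,  6,  0, -5, -7, -6,
   -1, -6, -2, -5, -8, -5, -6, -6, -7, -2, -7, -3, -4, -9, -4,  0,  7,-13, -6, -3,
  -13, -2, -8,-15,-15,-13,-17,-15, -7,-14, -6,-12,-13, -4,-14, -5,-13, 13, -5,-15,
   -8,-10, -4,-11, -4,-12, -8,-14, -3, -6, -7, -9,-11,  2,-13, -7, -6, -5, 10, -7,
   -2, -8, -8, -8, -6, -7, -6, -5, -6,  2, -2, -9, -1, -8, -6, -6, -3,-15, -7,  7)

#' PAM30 substitution matrix
#'
#' Standard PAM30 values plus an `X` row/column scored -1, the score scale
#' short degenerate peptide queries are searched with.
#'
#' @return Integer matrix with dimnames over the 20 residues plus `X`.
#' @export
pam30 <- function() {
  m <- matrix(.PAM30_VALUES, 20, 20, byrow = TRUE,
              dimnames = list(.AA20, .AA20))
  m <- rbind(cbind(m, X = -1L), X = -1L)
  rownames(m)[21] <- "X"
  storage.mode(m) <- "integer"
  m
}

#' Mass-ambiguity tolerant homology-search matrix
#'
#' PAM30 modified for de novo peptide queries where isobaric calls cannot
#' be distinguished, following the PAM30MS idea: I/L pairs score like an
#' identity (`score(I,L) = score(I,I)`) and K/Q pairs score one below the
#' best of their self-scores, since K and Q differ by less than the
#' fragment tolerance. PAM30 is the appropriate scale for short,
#' low-divergence peptide queries, and the fixed HSSP confidence cutoff of
#' 62 presupposes it.
#'
#' @return Integer matrix like [pam30()].
#' @export
msblast_matrix <- function() {
  m <- pam30()
  m["I", "L"] <- m["L", "I"] <- m["I", "I"]
  kq <- max(m["K", "K"], m["Q", "Q"]) - 1L
  m["K", "Q"] <- m["Q", "K"] <- kq
  m
}

#' Robinson-Robinson amino-acid background frequencies
#'
#' @return Named numeric vector over the 20 residues, summing to 1.
#' @export
robinson_frequencies <- function() {
  f <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
         Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
         L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
         S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
  f / sum(f)
}

# convolve two integer-score distributions given as (offset, probs)
.conv_dist <- function(a, b) {
  probs <- outer(a$p, b$p)
  idx <- outer(seq_along(a$p) - 1L, seq_along(b$p) - 1L, "+")
  p <- as.vector(rowsum(as.vector(probs), as.vector(idx)))
  list(min = a$min + b$min, p = p)
}

#' Ungapped Karlin-Altschul parameters
#'
#' Estimates lambda, K and the relative entropy H for a substitution matrix
#' under independent background frequencies, by the standard moment method
#' for lattice score distributions: lambda is the positive root of
#' `sum p_s exp(lambda s) = 1`, and K follows from the lattice-case series
#' formula using iterated convolutions of the score distribution.
#'
#' @param matrix Substitution matrix (20x20 core used).
#' @param freqs Background frequencies (default [robinson_frequencies()]).
#' @param max_terms Terms in the K series (default 40).
#' @return List with `lambda`, `K`, `H`.
#' @export
karlin_params <- function(matrix = blosum62(), freqs = robinson_frequencies(),
                          max_terms = 40L) {
  aa <- intersect(rownames(matrix), names(freqs))
  m <- matrix[aa, aa]
  f <- freqs[aa] / sum(freqs[aa])
  pij <- outer(f, f)
  if (sum(pij * m) >= 0)
    stop("expected score must be negative for Karlin-Altschul statistics")
  smin <- min(m); smax <- max(m)
  p_s <- vapply(smin:smax, function(s) sum(pij[m == s]), 0)
  d <- {
    nz <- which(p_s > 0) - 1L          # offsets from smin with support
    offs <- nz + smin
    g <- 0L
    for (o in diff(sort(offs))) g <- if (g == 0L) o else .gcd(g, o)
    max(g, 1L)
  }
  sc <- smin:smax
  fn <- function(l) sum(p_s * exp(l * sc)) - 1
  lambda <- stats::uniroot(fn, c(1e-4, 20), tol = 1e-12)$root
  H <- lambda * sum(sc * p_s * exp(lambda * sc))
  # sigma = sum_j (1/j) [ P(S_j >= 0) + E(e^{lambda S_j}; S_j < 0) ]
  base <- list(min = smin, p = p_s)
  dist <- base
  sigma <- 0
  for (j in seq_len(max_terms)) {
    if (j > 1L) dist <- .conv_dist(dist, base)
    s_vals <- dist$min + seq_along(dist$p) - 1L
    neg <- s_vals < 0
    term <- sum(dist$p[!neg]) + sum(dist$p[neg] * exp(lambda * s_vals[neg]))
    sigma <- sigma + term / j
    if (term / j < 1e-10) break
  }
  K <- d * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * d)))
  list(lambda = lambda, K = K, H = H)
}

.gcd <- function(a, b) if (b == 0L) a else .gcd(b, a %% b)
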