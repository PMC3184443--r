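# Shared fixture builders. Everything is generated in code; no data files.

# exact theoretical spectrum of a peptide: the requested ion series at unit
# (or given) intensities, no noise, no jitter
ladder_spectrum <- function(seq, series = c("b", "y"), intensity = 100,
                            mods = NULL) {
  pep <- if (is.null(mods)) layerid::peptide(seq) else
    layerid::peptide(seq, mods = mods)
  ions <- layerid::fragment_ions(pep, series = series)
  mz <- sort(unique(ions$mz))
  list(precursor = layerid::peptide_mh(pep),
       peaks = layerid::peak_list(mz, rep(intensity, length(mz))))
}

# random tryptic-looking peptide: interior letters avoid K/R/P edge cases,
# terminal residue K or R
random_tryptic_peptide <- function(len) {
  interior <- sample(c("A", "D", "E", "F", "G", "H", "L", "N", "S", "T",
                       "V", "Y"), len - 1L, replace = TRUE)
  paste(c(interior, sample(c("K", "R"), 1L)), collapse = "")
}

# small random protein database
tiny_db <- function(n, len = 120L, prefix = "PROT") {
  stats::setNames(vapply(seq_len(n), function(i) layerid::random_protein(len), ""),
                  sprintf("%s%03d", prefix, seq_len(n)))
}

# independent brute-force tryptic digestion: scan-based cut-site finder plus
# concatenation of adjacent runs (independent of digest_protein internals)
brute_digest <- function(seq, max_missed) {
  aa <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(aa)
  cuts <- integer(0)
  for (i in seq_len(max(0L, n - 1L)))
    if (aa[i] %in% c("K", "R") && aa[i + 1L] != "P") cuts <- c(cuts, i)
  bounds <- c(0L, cuts, n)
  base <- character(0)
  for (b in seq_len(length(bounds) - 1L))
    base <- c(base, paste(aa[(bounds[b] + 1L):bounds[b + 1L]], collapse = ""))
  out <- character(0)
  for (i in seq_along(base))
    for (w in 0:max_missed)
      if (i + w <= length(base))
        out <- c(out, paste(base[i:(i + w)], collapse = ""))
  sort(unique(out))
}

# exhaustive gapless segment-pair enumeration (oracle for align_gapless):
# scores every (query offset, subject offset, length) triple and extracts
# the recursive maximal-segment decomposition from the enumerated scores
brute_hssps <- function(query, subject, matrix, min_score) {
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  t <- strsplit(subject, "", fixed = TRUE)[[1]]
  n <- length(q); m <- length(t)
  res <- list()
  for (d in (-(m - 1L)):(n - 1L)) {
    i0 <- max(1L, d + 1L); i1 <- min(n, m + d)
    if (i1 < i0) next
    vals <- vapply(i0:i1, function(i) {
      a <- q[i]; b <- t[i - d]
      if (!(a %in% rownames(matrix)) || !(b %in% colnames(matrix))) -Inf
      else matrix[a, b]
    }, 0)
    # exhaustive best-segment search with recursive splitting
    rec <- function(lo, hi) {
      if (hi < lo) return()
      best <- -Inf; bs <- NA; be <- NA
      for (s in lo:hi) for (e in s:hi) {
        sc <- sum(vals[s:e])
        if (is.finite(sc) && sc > best) { best <- sc; bs <- s; be <- e }
      }
      if (!is.finite(best) || best < min_score) return()
      res[[length(res) + 1L]] <<- c(score = best,
                                    query_start = i0 + bs - 1L,
                                    query_end = i0 + be - 1L,
                                    subject_start = i0 + bs - 1L - d,
                                    subject_end = i0 + be - 1L - d)
      rec(lo, bs - 2L)
      rec(be + 1L, hi)
    }
    rec(1L, length(vals))
  }
  if (!length(res))
    return(data.frame(score = numeric(), query_start = integer(),
                      query_end = integer(), subject_start = integer(),
                      subject_end = integer()))
  df <- as.data.frame(do.call(rbind, res))
  df[order(df$query_start, df$subject_start), ]
}

# binomial tail by complete outcome enumeration over all 2^N match patterns
enum_binom_tail <- function(k, N, q) {
  if (k <= 0) return(1)
  total <- 0
  for (pattern in 0:(2^N - 1)) {
    bits <- sum(bitwAnd(pattern, 2^(0:(N - 1))) > 0)
    if (bits >= k) total <- total + q^bits * (1 - q)^(N - bits)
  }
  total
}
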