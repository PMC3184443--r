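test_that("spectrum-graph nodes equal brute-force peak interpretation", {
  set.seed(71)
  cfg <- denovo_config()
  for (trial in 1:5) {
    s <- random_tryptic_peptide(9L)
    sp <- ladder_spectrum(s)
    # drop some ions, add noise
    keep <- sample(nrow(sp$peaks), ceiling(0.7 * nrow(sp$peaks)))
    peaks <- sp$peaks[sort(keep), ]
    g <- build_spectrum_graph(peaks, sp$precursor, cfg)
    # oracle: both interpretations of every peak, merged within tolerance
    sinkm <- sp$precursor - 1.007276 - 18.010565
    raw <- sort(c(peaks$mz - 1.007276, sp$precursor - peaks$mz))
    raw <- raw[raw > cfg$fragment_tol & raw < sinkm - cfg$fragment_tol]
    expected_n <- sum(diff(raw) > cfg$fragment_tol) + 1L
    expect_equal(nrow(g$nodes), expected_n)
    # every node is within tolerance of a raw interpretation
    for (m in g$nodes$mass)
      expect_true(min(abs(raw - m)) <= cfg$fragment_tol)
  }
})

test_that("a complete ladder spectrum yields the true sequence as a path", {
  sp <- ladder_spectrum("PEPTLDER")
  g <- build_spectrum_graph(sp$peaks, sp$precursor)
  cand <- generate_candidates(g)
  expect_true("PEPTLDER" %in% cand$sequence)
})

test_that("empty spectrum constrains candidates to mass-consistent sequences", {
  prec <- peptide_mh("GG")
  g <- build_spectrum_graph(peak_list(numeric(0) + 1, numeric(0))[0, ], prec)
  cand <- generate_candidates(g)
  # exhaustive scan: single residues and dipeptides within parent tolerance
  alpha <- amino_acid_masses()[setdiff(names(amino_acid_masses()), "I")]
  alpha["C"] <- alpha["C"] + 57.021464
  target <- prec - 1.007276 - 18.010565
  ok1 <- names(alpha)[abs(alpha - target) <= 0.08]
  pairs <- expand.grid(a = names(alpha), b = names(alpha))
  ok2 <- paste0(pairs$a, pairs$b)[abs(alpha[pairs$a] + alpha[pairs$b] - target)
                                  <= 0.08]
  expect_setequal(cand$sequence, union(ok1, ok2))
  expect_true(all(c("GG", "N") %in% cand$sequence))
})

test_that("beam search recovers top paths of exhaustive enumeration", {
  # peptides over a 5-letter alphabet, <= 4 residues: enumerate all paths
  set.seed(72)
  cfg <- denovo_config(beam_width = 500L)
  letters5 <- c("G", "A", "S", "V", "F")
  for (trial in 1:3) {
    s <- paste(sample(letters5, 4, replace = TRUE), collapse = "")
    sp <- ladder_spectrum(s)
    keep <- sort(sample(nrow(sp$peaks), 4))
    peaks <- sp$peaks[keep, ]
    g <- build_spectrum_graph(peaks, sp$precursor, cfg)
    cand <- generate_candidates(g, cfg)
    # oracle: score every mass-consistent sequence over the full alphabet
    alpha <- amino_acid_masses()[setdiff(names(amino_acid_masses()), "I")]
    alpha["C"] <- alpha["C"] + 57.021464
    target <- sp$precursor - 1.007276 - 18.010565
    seqs <- unlist(lapply(2:4, function(L) {
      gr <- do.call(expand.grid, rep(list(names(alpha)), L))
      apply(gr, 1, paste, collapse = "")
    }))
    masses <- vapply(strsplit(seqs, ""), function(x) sum(alpha[x]), 0)
    valid <- seqs[abs(masses - target) <= cfg$parent_tol]
    path_score <- function(sq) {
      pre <- cumsum(alpha[strsplit(sq, "")[[1]]])
      pre <- pre[-length(pre)]
      sc <- 0
      for (p in pre) {
        d <- if (nrow(g$nodes)) min(abs(g$nodes$mass - p)) else Inf
        sc <- sc + if (d <= cfg$fragment_tol)
          g$nodes$score[which.min(abs(g$nodes$mass - p))] else cfg$penalty
      }
      sc
    }
    oracle <- vapply(valid, path_score, 0)
    top5 <- names(sort(oracle, decreasing = TRUE))[seq_len(min(5, length(oracle)))]
    expect_true(all(top5 %in% cand$sequence))
  }
})

test_that("rescoring is the explained fraction of total ion abundance", {
  s <- "LGEYGFK"
  sp <- ladder_spectrum(s)
  expect_equal(rescore_candidate(s, sp$peaks), 100)
  # half the total intensity in unmatched noise -> 50
  tot <- sum(sp$peaks$intensity)
  noisy <- rbind(sp$peaks, data.frame(mz = c(3101.17, 3333.33),
                                      intensity = c(tot / 2, tot / 2)))
  noisy <- noisy[order(noisy$mz), ]
  expect_equal(rescore_candidate(s, noisy), 50)
  # candidate matching nothing -> 0
  far <- peak_list(c(3000, 3100), c(5, 5))
  expect_equal(rescore_candidate(s, far), 0)
  # empty spectrum -> 0
  expect_equal(rescore_candidate(s, sp$peaks[0, ]), 0)
})

test_that("score is bounded and unmatched noise strictly lowers it", {
  set.seed(73)
  for (i in 1:5) {
    s <- random_tryptic_peptide(8L)
    sp <- ladder_spectrum(s)
    sc0 <- rescore_candidate(s, sp$peaks)
    expect_gte(sc0, 0); expect_lte(sc0, 100)
    noisy <- rbind(sp$peaks, data.frame(mz = 3222.22, intensity = 50))
    expect_lt(rescore_candidate(s, noisy), sc0)
  }
})

test_that("finalisation reports ten candidates and filters strictly above 50", {
  cand <- data.frame(sequence = replicate(25, random_tryptic_peptide(7L)),
                     score = seq(99, 3, length.out = 25))
  out <- finalize_candidates(cand)
  expect_equal(nrow(out), 10L)
  expect_equal(out$rank, 1:10)
  expect_true(all(diff(out$score) <= 0))
  edge <- finalize_candidates(data.frame(sequence = c("AAK", "GGK"),
                                         score = c(50, 50.1)))
  expect_equal(edge$passes_filter, c(TRUE, FALSE))  # 50.1 passes, 50 does not
  none <- finalize_candidates(data.frame(sequence = character(),
                                         score = numeric()))
  expect_equal(nrow(none), 0L)
})

test_that("rank-1 recovery on noiseless ladders (module-level check)", {
  set.seed(74)
  ok <- 0L; n <- 25L
  for (i in seq_len(n)) {
    s <- random_tryptic_peptide(sample(7:15, 1))
    sp <- ladder_spectrum(s)
    dn <- denovo_spectrum(sp)
    if (nrow(dn) && canonical_sequence(dn$sequence[1]) ==
        canonical_sequence(s)) ok <- ok + 1L
  }
  expect_gte(ok / n, 0.95)
})

test_that("candidates respect the parent-mass constraint", {
  set.seed(75)
  s <- random_tryptic_peptide(9L)
  sp <- ladder_spectrum(s)
  dn <- denovo_spectrum(sp)
  expect_true(all(abs(dn$mh - sp$precursor) <= 0.08 + 1e-9))
  expect_true(all(dn$score >= 0 & dn$score <= 100))
})

test_that("candidate TSV export carries the supplement columns", {
  set.seed(77)
  s <- random_tryptic_peptide(8L)
  spx <- spot("tsv1", peak_list(1000, 5, sn = 60),
              list(ladder_spectrum(s)))
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- write_denovo_candidates(spx, path)
  back <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  expect_identical(names(back),
                   c("spot", "spectrum", "precursor", "rank", "sequence",
                     "mods", "score", "passes_filter"))
  expect_lte(nrow(back), 10L)
  expect_true(canonical_sequence(s) %in% canonical_sequence(back$sequence))
})

test_that("true peptide survives ion dropout and noise within the top ten", {
  # 20% of ladder ions deleted, 10 noise peaks added (regression floor)
  set.seed(76)
  ok <- 0L; n <- 200L
  for (i in seq_len(n)) {
    s <- random_tryptic_peptide(sample(7:15, 1))
    sp <- ladder_spectrum(s)
    keep <- sort(sample(nrow(sp$peaks), ceiling(0.8 * nrow(sp$peaks))))
    peaks <- sp$peaks[keep, ]
    noise <- data.frame(mz = runif(10, 100, sp$precursor - 30),
                        intensity = runif(10, 10, 60))
    peaks <- rbind(peaks, noise)
    peaks <- peaks[order(peaks$mz), ]
    dn <- denovo_spectrum(list(precursor = sp$precursor, peaks = peaks))
    if (nrow(dn) && canonical_sequence(s) %in%
        canonical_sequence(dn$sequence)) ok <- ok + 1L
  }
  expect_gte(ok / n, 0.70)
})
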