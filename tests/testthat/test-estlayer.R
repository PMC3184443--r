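test_that("six-frame translation follows the standard code and splits at stops", {
  f <- six_frame_translate(c(e = "ATGAAA"))
  expect_equal(f$sequence[f$frame == "+1"], "MK")
  g <- six_frame_translate(c(e = "TTTCAT"))
  expect_equal(g$sequence[g$frame == "-1"], "MK")
  h <- six_frame_translate(c(e = "ATGTAAAAA"))
  expect_setequal(h$sequence[h$frame == "+1"], c("M", "K"))
  # ambiguous codon translates to X
  x <- six_frame_translate(c(e = "ATGNNN"))
  expect_equal(x$sequence[x$frame == "+1"], "MX")
  # too short for frame +3
  s <- six_frame_translate(c(e = "ATGA"))
  expect_false("+3" %in% s$frame)
})

test_that("reverse frames translate the reverse complement", {
  set.seed(61)
  for (i in 1:8) {
    nt <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
    fw <- six_frame_translate(c(a = rc))
    rv <- six_frame_translate(c(a = nt))
    for (k in 1:3) {
      expect_identical(
        paste(fw$sequence[fw$frame == paste0("+", k)], collapse = "*"),
        paste(rv$sequence[rv$frame == paste0("-", k)], collapse = "*"))
    }
  }
})

test_that("segment coordinates map back onto the EST", {
  set.seed(62)
  prot <- random_protein(40L)
  rt <- reverse_translate(prot)
  fr <- six_frame_translate(c(x = rt$dna))
  hit <- fr[grepl(prot, fr$sequence, fixed = TRUE), ][1, ]
  expect_false(is.na(hit$est))
  # re-extract the segment's nucleotides and translate them back
  L <- nchar(rt$dna)
  if (startsWith(hit$frame, "+")) {
    sub <- substring(rt$dna, hit$nt_start, hit$nt_end)
  } else {
    sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      substring(rt$dna, hit$nt_end, hit$nt_start))))
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(sub)))
  expect_identical(aa, hit$sequence)
})

test_that("Karlin-Altschul parameters reproduce published BLOSUM62 values", {
  kp <- karlin_params(blosum62(), robinson_frequencies())
  expect_equal(kp$lambda, 0.3176, tolerance = 0.01)
  expect_equal(kp$K, 0.134, tolerance = 0.05)
  expect_equal(kp$H, 0.40, tolerance = 0.05)
})

test_that("embedded BLOSUM62 matches the independent reference copy", {
  ref <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  m <- blosum62()
  aa <- rownames(m)[rownames(m) != "X"]
  expect_identical(unname(m[aa, aa]), unname(ref[aa, aa]))
})

test_that("an exact-match EST annotates far below the e-20 bar", {
  set.seed(63)
  db <- tiny_db(100L, len = 200L, prefix = "ANN")
  target <- db[[7]]
  rt <- reverse_translate(target)
  ann <- annotate_blastx(c(est1 = rt$dna), db)
  expect_equal(ann$accession, "ANN007")
  expect_lt(ann$evalue, 1e-20)
  # identity alignment score equals the sum of diagonal matrix values
  m <- blosum62()
  expect_gte(ann$score, sum(diag(m[strsplit(target, "")[[1]],
                                   strsplit(target, "")[[1]]])) * 0.9)
})

test_that("random short ESTs are not significant", {
  set.seed(64)
  db <- tiny_db(20L, len = 150L)
  insig <- 0L
  n <- 30L
  kp <- karlin_params()
  for (i in seq_len(n)) {
    nt <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
    ann <- annotate_blastx(stats::setNames(nt, "r"), db, params = kp)
    if (is.null(ann) || ann$evalue > 0.01) insig <- insig + 1L
  }
  expect_gte(insig / n, 0.95)
})

test_that("E-value decreases strictly as the alignment score increases", {
  kp <- karlin_params()
  scores <- seq(20, 200, by = 20)
  ev <- kp$K * 1e3 * 1e5 * exp(-kp$lambda * scores)
  expect_true(all(diff(ev) < 0))
})

test_that("a spot simulated from an EST-encoded protein finds that EST", {
  set.seed(65)
  prot <- random_protein(250L)
  rt <- reverse_translate(prot)
  ests <- c(stats::setNames(rt$dna, "ESTX"),
            stats::setNames(reverse_translate(random_protein(250L))$dna, "ESTY"))
  frames <- six_frame_translate(ests)
  idx <- build_est_index(frames)
  sim <- simulate_spot(prot, "s", noiseless_spec(simulation_spec(seed = 65)))
  hits <- search_est(sim$spot, idx)
  expect_match(hits$accession[1], "^ESTX\\|")
  expect_gte(hits$total_ion_ci[1], 95)
  # an EST database with no usable ORF yields nothing
  tiny <- six_frame_translate(c(z = "ATGTAATAGTGA"))
  expect_null(build_est_index(tiny))
})

test_that("layer-2 classification needs both the C.I. and the E-value bar", {
  hit_hi <- data.frame(total_ion_ci = 99)
  hit_lo <- data.frame(total_ion_ci = 80)
  ann <- function(e) list(evalue = e)
  expect_equal(classify_layer2(hit_hi, ann(1e-30))$category, "confident")
  expect_equal(classify_layer2(hit_hi, ann(1e-5))$category, "nonconfident")
  expect_equal(classify_layer2(hit_lo, ann(1e-30))$category, "nonconfident")
  expect_equal(classify_layer2(NULL, NULL)$category, "nonconfident")
})
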