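test_that("query assembly joins candidates with minus and keeps an invertible map", {
  cands <- data.frame(spectrum = c(1L, 2L), rank = c(1L, 1L),
                      sequence = c("PEPTIDE", "LVK"))
  mq <- assemble_query(cands)
  expect_equal(mq$query, "PEPTIDE-LVK")
  p9 <- query_position(mq, 9L)
  expect_equal(p9$spectrum, 2L)
  expect_equal(p9$offset, 1L)
  expect_error(query_position(mq, 8L))      # separator
  one <- assemble_query(cands[1, ])
  expect_equal(one$query, "PEPTIDE")
  expect_null(assemble_query(cands[0, ]))
})

test_that("gapless alignment finds the self-match and never crosses a separator", {
  set.seed(81)
  subj <- random_protein(60L)
  q <- substring(subj, 20, 39)
  h <- align_gapless(q, c(S1 = subj), min_score = 30)
  m <- msblast_matrix()
  self <- sum(diag(m[strsplit(q, "")[[1]], strsplit(q, "")[[1]]]))
  expect_equal(max(h$score), self)
  best <- h[which.max(h$score), ]
  expect_equal(best$subject_start, 20L)
  expect_equal(best$subject_end, 39L)
  # separator is a hard break
  h2 <- align_gapless("AAA-AAA", c(S = "AAAAAA"), min_score = 1)
  expect_true(all(h2$query_end - h2$query_start + 1L <= 3L))
})

test_that("HSSP set equals exhaustive segment-pair enumeration", {
  set.seed(82)
  m <- msblast_matrix()
  for (trial in 1:6) {
    q <- paste0(random_protein(12L), "-", random_protein(10L))
    subj <- random_protein(28L)
    got <- align_gapless(q, c(S = subj), min_score = 10)
    want <- brute_hssps(q, subj, m, 10)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      got <- got[order(got$query_start, got$subject_start), ]
      expect_equal(got$score, want$score)
      expect_equal(got$query_start, as.integer(want$query_start))
      expect_equal(got$subject_end, as.integer(want$subject_end))
    }
  }
})

test_that("embedded PAM30 matches the independent reference copy", {
  ref <- local({
    e <- new.env()
    utils::data("PAM30", package = "Biostrings", envir = e)
    e$PAM30
  })
  m <- pam30()
  aa <- rownames(m)[rownames(m) != "X"]
  expect_identical(unname(m[aa, aa]), unname(ref[aa, aa]))
  # the homology matrix differs from PAM30 exactly at the I/L and K/Q pairs
  h <- msblast_matrix()
  expect_equal(h["I", "L"], h["I", "I"])
  expect_equal(h["K", "Q"], max(h["K", "K"], h["Q", "Q"]) - 1L)
  diffs <- which(h != m, arr.ind = TRUE)
  expect_setequal(paste(rownames(h)[diffs[, 1]], colnames(h)[diffs[, 2]]),
                  c("I L", "L I", "K Q", "Q K"))
})

test_that("HSSP score is symmetric in query and subject", {
  set.seed(83)
  a <- random_protein(25L); b <- random_protein(25L)
  ha <- align_gapless(a, c(S = b), min_score = 5)
  hb <- align_gapless(b, c(S = a), min_score = 5)
  expect_equal(sort(ha$score), sort(hb$score))
})

test_that("per-candidate best HSSPs bound the merged-query best", {
  set.seed(84)
  subj <- c(S = random_protein(80L))
  cands <- data.frame(spectrum = 1:3, rank = 1L,
                      sequence = replicate(3, random_protein(10L)))
  mq <- assemble_query(cands)
  merged <- align_gapless(mq, subj, min_score = 5)
  singles <- vapply(cands$sequence, function(s) {
    h <- align_gapless(s, subj, min_score = 5)
    if (nrow(h)) max(h$score) else 0
  }, 0)
  if (nrow(merged)) expect_gte(sum(singles), max(merged$score))
})

test_that("homology classification counts distinct-spectrum HSSPs at the 62 bar", {
  mk <- function(acc, score, spec) data.frame(
    accession = acc, score = score, query_start = 1L, query_end = 5L,
    subject_start = 1L, subject_end = 5L, spectrum = spec, rank = 1L)
  two <- rbind(mk("P1", 70, "1"), mk("P1", 65, "2"))
  expect_equal(classify_homology(two)$category, "confident")
  one62 <- mk("P1", 62, "1")
  expect_equal(classify_homology(one62)$category, "borderline")  # inclusive
  below <- rbind(mk("P1", 61.9, "1"), mk("P1", 45, "2"))
  expect_equal(classify_homology(below)$category, "none")
  # same-spectrum duplicates count once
  dup <- rbind(mk("P1", 70, "1"), mk("P1", 68, "1"))
  expect_equal(classify_homology(dup)$category, "borderline")
  # taxon priority breaks ties
  tie <- rbind(mk("A", 70, "1"), mk("A", 70, "2"),
               mk("B", 70, "1"), mk("B", 70, "2"))
  pri <- data.frame(accession = "B", priority = 1)
  expect_equal(classify_homology(tie, taxon_priority = pri)$accession, "B")
})

test_that("planted homolog is recovered through denovo + homology search", {
  set.seed(85)
  ok <- 0L; n <- 10L
  for (i in seq_len(n)) {
    target <- random_protein(300L)
    hom <- mutate_protein(target, 0.8)
    db <- c(stats::setNames(hom, "HOM"), tiny_db(10L, len = 300L, prefix = "BG"))
    sim <- simulate_spot(target, "x", simulation_spec(seed = 85 + i))
    if (is.null(sim)) next
    cands <- do.call(rbind, lapply(seq_along(sim$spot$msms), function(si) {
      dn <- denovo_spectrum(sim$spot$msms[[si]])
      dn <- dn[dn$passes_filter, , drop = FALSE]
      if (!nrow(dn)) return(NULL)
      data.frame(spectrum = si, rank = dn$rank, sequence = dn$sequence)
    }))
    mq <- assemble_query(cands)
    if (is.null(mq)) next
    dec <- classify_homology(align_gapless(mq, db, min_score = 62))
    if (identical(dec$accession, "HOM")) ok <- ok + 1L
  }
  expect_gte(ok / n, 0.7)
})
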