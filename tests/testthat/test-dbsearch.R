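test_that("peptide index holds every tryptic peptide and supports mass lookup", {
  idx <- build_peptide_index(c(p1 = "MAKR"))
  expect_setequal(unique(idx$peptides$sequence), c("MAK", "R", "MAKR"))
  # oxidised forms of the methionine peptides are indexed too
  expect_true(any(idx$peptides$mod_string == "1:Oxidation"))
  m <- peptide_mass("MAK")
  hit <- index_lookup(idx, m, 50)
  expect_true("MAK" %in% hit$sequence)
  expect_equal(nrow(index_lookup(idx, 3999, 50)), 0L)
  expect_error(build_peptide_index(character(0)))
})

test_that("PSM binomial tail equals complete outcome enumeration", {
  # spectra with <= 12 peaks: enumerate all 2^N match patterns
  set.seed(51)
  for (trial in 1:8) {
    N <- sample(4:12, 1)
    k <- sample(0:N, 1)
    q <- runif(1, 0.01, 0.4)
    expect_equal(pbinom(k - 1, N, q, lower.tail = FALSE),
                 enum_binom_tail(k, N, q), tolerance = 1e-9)
  }
})

test_that("a clean ladder scores high, a zero-match spectrum scores zero", {
  set.seed(52)
  db <- tiny_db(100L)
  cfg <- search_config()
  seqs <- random_tryptic_peptide(12L)
  sp <- ladder_spectrum(seqs)
  psm <- score_psm(sp, peptide(seqs), cfg, n_candidates = 100L)
  expect_gt(psm$ci, 99)
  expect_equal(psm$k, sum(!duplicated(round(sp$peaks$mz, 4))))
  # unrelated flat spectrum: no matches forced at all -> score 0 when k = 0
  far <- list(precursor = peptide_mh(seqs),
              peaks = peak_list(c(3000, 3100, 3200), c(1, 1, 1)))
  psm0 <- score_psm(far, peptide(seqs), cfg, 1L)
  expect_equal(psm0$ions_score, 0)
  expect_equal(psm0$ci, 0)
  # precursor outside tolerance -> no candidate result
  off <- list(precursor = peptide_mh(seqs) + 1, peaks = sp$peaks)
  expect_null(score_psm(off, peptide(seqs), cfg))
})

test_that("random spectra rarely reach the 95% confidence bar", {
  set.seed(53)
  cfg <- search_config()
  hits <- 0L
  n_trials <- 200L
  for (i in seq_len(n_trials)) {
    s <- random_tryptic_peptide(11L)
    prec <- peptide_mh(s)
    peaks <- peak_list(sort(runif(40, 100, prec - 20)), runif(40, 1, 100))
    psm <- score_psm(list(precursor = prec, peaks = peaks), peptide(s), cfg, 1L)
    if (psm$ci >= 95) hits <- hits + 1L
  }
  expect_lte(hits / n_trials, 0.05)
})

test_that("adding a matched fragment peak never decreases the ions score", {
  set.seed(54)
  cfg <- search_config()
  for (i in 1:10) {
    s <- random_tryptic_peptide(10L)
    pep <- peptide(s)
    ions <- fragment_ions(pep, series = c("b", "y"))
    base_mz <- sort(ions$mz[seq(1, nrow(ions), by = 2)])
    sp <- list(precursor = peptide_mh(pep),
               peaks = peak_list(base_mz, rep(10, length(base_mz))))
    s1 <- score_psm(sp, pep, cfg, 1L)$ions_score
    extra <- setdiff(round(ions$mz, 4), round(base_mz, 4))[1]
    sp2 <- list(precursor = sp$precursor,
                peaks = peak_list(c(base_mz, extra),
                                  rep(10, length(base_mz) + 1L)))
    s2 <- score_psm(sp2, pep, cfg, 1L)$ions_score
    expect_gte(s2, s1)
  }
})

test_that("a planted protein ranks first against a decoy database", {
  set.seed(55)
  db <- tiny_db(30L, len = 200L)
  target <- db[[1]]
  spec <- noiseless_spec(simulation_spec(seed = 55))
  sim <- simulate_spot(target, "t1", spec)
  idx <- build_peptide_index(db)
  hits <- search_spot(sim$spot, idx)
  expect_equal(hits$accession[1], "PROT001")
  expect_gte(hits$n_sig_peptides[1], 2L)
  expect_gte(hits$protein_ci[1], 95)
  # duplicated database entry gets identical scores
  db2 <- c(db, stats::setNames(db[1], "COPY001"))
  hits2 <- search_spot(sim$spot, build_peptide_index(db2))
  two <- hits2[hits2$accession %in% c("PROT001", "COPY001"), ]
  expect_equal(nrow(two), 2L)
  expect_equal(two$protein_score[1], two$protein_score[2], tolerance = 1e-9)
})

test_that("an empty spot yields an empty hit list", {
  idx <- build_peptide_index(tiny_db(3L))
  empty_spot <- spot("e", peak_list(5000, 1), list())
  expect_equal(nrow(search_spot(empty_spot, idx)), 0L)
})

test_that("layer-1 classification follows the two-peptide / 95% C.I. rule", {
  mk <- function(nsig, npep, ci)
    data.frame(accession = "a", n_sig_peptides = nsig, n_peptides = npep,
               protein_ci = ci)
  expect_equal(classify_layer1(mk(2L, 2L, 99))$category, "confident")
  expect_equal(classify_layer1(mk(1L, 1L, 99))$category, "borderline")
  expect_equal(classify_layer1(mk(2L, 2L, 80))$category, "borderline")
  expect_equal(classify_layer1(mk(0L, 1L, 50))$category, "borderline")
  expect_equal(classify_layer1(mk(0L, 0L, 0))$category, "nonconfident")
  expect_equal(classify_layer1(NULL)$category, "nonconfident")
})
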