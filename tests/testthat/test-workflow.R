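# Small end-to-end fixtures; the full-size study conditions run in
# test-acceptance.R.

small_study <- function(seed = 3L) {
  simulate_study(simulation_spec(
    seed = seed, n_spots = c(db = 2L, est = 2L, homolog = 2L, junk = 1L),
    n_background = 10L))
}

test_that("spots route to their planted layers on a small study", {
  s <- small_study()
  cfg <- pipeline_config(protein_db = s$protein_db, est_db = s$est_db,
                         annotation_db = s$annotation_db, seed = 3L)
  rep <- run_pipeline(s$spots, cfg)
  merged <- merge(rep, s$truth, by = "spot")
  # planted layer recovered for the clear classes
  db_rows <- merged[merged$class == "db", ]
  expect_true(all(db_rows$layer.x == "1" & db_rows$category == "confident"))
  expect_true(all(db_rows$accession == db_rows$expected_accession))
  est_rows <- merged[merged$class == "est", ]
  expect_true(all(est_rows$layer.x == "2"))
  expect_true(all(startsWith(est_rows$accession,
                             paste0(est_rows$expected_accession, "|"))))
  junk_rows <- merged[merged$class == "junk", ]
  expect_true(all(junk_rows$category == "unknown"))
})

test_that("every spot lands in exactly one category and counts partition", {
  s <- small_study(4L)
  cfg <- pipeline_config(protein_db = s$protein_db, est_db = s$est_db,
                         annotation_db = s$annotation_db)
  rep <- run_pipeline(s$spots, cfg)
  expect_equal(nrow(rep), length(s$spots))
  expect_equal(anyDuplicated(rep$spot), 0L)
  cats <- c("confident", "EST-confident", "tentative-homology", "borderline",
            "unknown")
  expect_true(all(rep$category %in% cats))
  expect_equal(sum(table(factor(rep$category, cats))), length(s$spots))
  # unknown iff no layer retained a hit
  expect_identical(rep$category == "unknown", rep$layer == "none")
})

test_that("identical inputs and seed give byte-identical reports", {
  s1 <- small_study(5L)
  s2 <- small_study(5L)
  cfg1 <- pipeline_config(protein_db = s1$protein_db, est_db = s1$est_db,
                          annotation_db = s1$annotation_db, seed = 5L)
  cfg2 <- pipeline_config(protein_db = s2$protein_db, est_db = s2$est_db,
                          annotation_db = s2$annotation_db, seed = 5L)
  r1 <- run_pipeline(s1$spots, cfg1)
  r2 <- run_pipeline(s2$spots, cfg2)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_spot_reports(r1, p1)
  write_spot_reports(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("taxonomic summary percentages are exact per layer", {
  rep <- data.frame(
    spot = sprintf("s%d", 1:6), layer = c("1", "1", "1", "1", "2", "none"),
    category = c(rep("confident", 4), "EST-confident", "unknown"),
    accession = c("A1", "A2", "B1", "C1", "E1|+1", NA))
  tm <- data.frame(accession = c("A1", "A2", "B1", "E1"),
                   group = c("dinoflagellates", "dinoflagellates",
                             "nondinoflagellate-algae", "dinoflagellates"))
  tt <- summarize_taxa(rep, tm)
  l1 <- tt[tt$layer == "1", ]
  expect_equal(l1$pct[l1$group == "dinoflagellates"], 50)        # 2 of 4
  expect_equal(l1$pct[l1$group == "nondinoflagellate-algae"], 25)
  expect_equal(l1$pct[l1$group == "other"], 25)                  # unmapped C1
  expect_equal(sum(l1$pct), 100, tolerance = 0.1)
  # EST accession maps through its id prefix
  l2 <- tt[tt$layer == "2", ]
  expect_equal(l2$pct[l2$group == "dinoflagellates"], 100)
  # all-one-group degenerate case
  one <- summarize_taxa(rep[1:2, ], tm)
  expect_equal(one$pct[one$group == "dinoflagellates"], 100)
  # independent tally oracle
  counts <- table(c("dinoflagellates", "dinoflagellates",
                    "nondinoflagellate-algae", "other"))
  expect_equal(l1$n[match(names(counts), l1$group)], as.integer(counts))
})

test_that("functional summary counts unique proteins once", {
  rep <- data.frame(
    spot = sprintf("s%d", 1:5), layer = c("1", "1", "1", "1", "1"),
    category = "confident",
    accession = c("A1", "A1", "A2", "A3", "A4"))   # A1 has two isoform spots
  fm <- data.frame(accession = c("A1", "A2"),
                   category = c("photosynthesis", "glycolysis"))
  ft <- summarize_functions(rep, fm)
  expect_equal(sum(ft$n), 4L)                       # unique accessions
  expect_equal(ft$pct[ft$category == "photosynthesis"], 25)
  expect_equal(ft$n[ft$category == "unknown function"], 2L)
  expect_equal(sum(ft$pct), 100, tolerance = 0.1)
})
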