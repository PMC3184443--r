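# Synthetic-data generator: protein / homolog / EST databases and MALDI
# spot spectra with known ground truth, so every layer of the pipeline is
# testable without external downloads. The model emulates singly charged
# tryptic MALDI spots: b/y/a ladders with water and ammonia losses and
# immonium ions, lognormal intensity variation, probabilistic fragment
# detection, uniform noise peaks and Gaussian calibration error.

.CODON_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  codons <- paste0(rep(bases, each = 16L), rep(rep(bases, each = 4L), 4L),
                   rep(bases, 16L))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  split(codons, aa)
})

#' Simulation specification
#'
#' Defaults are the study conditions used throughout the test suites: a
#' 60-spot study (20 protein-database spots, 20 EST-only spots, 15
#' homolog-only spots, 5 junk spots), homologs at 80 percent identity,
#' 90 percent fragment detection, lognormal intensities, 8 noise peaks per
#' MS/MS spectrum and 0.02 Da calibration error.
#'
#' @param seed Integer seed; every random draw derives from it.
#' @param n_background Background proteins in the search database.
#' @param protein_length Length range of generated proteins (residues).
#' @param n_spots Named counts per routing class: `db`, `est`, `homolog`,
#'   `junk`.
#' @param homolog_identity Target residue identity of planted homologs.
#' @param detection_prob Detection probability of b/y ladder ions.
#' @param secondary_prob Detection probability of a-ions, neutral losses
#'   and immonium ions.
#' @param intensity_meanlog,intensity_sdlog Lognormal intensity model.
#' @param n_noise_ms,n_noise_msms Noise peaks per MS list / MS/MS spectrum.
#' @param calibration_sd Gaussian m/z error s.d. in Da.
#' @param oxidation_incidence Per-methionine probability of oxidation.
#' @param spectra_per_spot MS/MS spectra simulated per spot (at most 20).
#' @param peptide_length Length range of peptides chosen for MS/MS.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(seed = 1L, n_background = 60L,
                            protein_length = c(250L, 400L),
                            n_spots = c(db = 20L, est = 20L, homolog = 15L,
                                        junk = 5L),
                            homolog_identity = 0.8, detection_prob = 0.9,
                            secondary_prob = 0.4,
                            intensity_meanlog = log(500),
                            intensity_sdlog = 0.6, n_noise_ms = 10L,
                            n_noise_msms = 8L, calibration_sd = 0.02,
                            oxidation_incidence = 0.1,
                            spectra_per_spot = 5L,
                            peptide_length = c(8L, 25L)) {
  stopifnot(homolog_identity > 0, homolog_identity <= 1,
            detection_prob >= 0, detection_prob <= 1,
            secondary_prob >= 0, secondary_prob <= 1,
            spectra_per_spot <= 20L)
  structure(as.list(environment()), class = "simulation_spec")
}

#' Noiseless variant of a simulation specification
#'
#' All detection probabilities 1, no noise peaks, no calibration error, no
#' variable modifications: spectra are exact theoretical ladders.
#'
#' @param spec A [simulation_spec()].
#' @return Modified `simulation_spec`.
#' @export
noiseless_spec <- function(spec = simulation_spec()) {
  spec$detection_prob <- 1; spec$secondary_prob <- 1
  spec$n_noise_ms <- 0L; spec$n_noise_msms <- 0L
  spec$calibration_sd <- 0; spec$oxidation_incidence <- 0
  spec
}

#' Generate a random protein sequence
#'
#' Residues drawn from the Robinson-Robinson background.
#'
#' @param length Number of residues.
#' @return Amino-acid string.
#' @export
random_protein <- function(length) {
  f <- robinson_frequencies()
  paste(sample(names(f), length, replace = TRUE, prob = f), collapse = "")
}

#' Mutate a protein to a target identity
#'
#' Substitutes the required number of positions with different residues.
#'
#' @param sequence Source protein.
#' @param identity Target identity fraction in (0, 1].
#' @return Mutated sequence.
#' @export
mutate_protein <- function(sequence, identity) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  k <- round((1 - identity) * length(aa))
  if (k == 0L) return(sequence)
  pos <- sample(length(aa), k)
  f <- robinson_frequencies()
  for (p in pos) {
    choices <- setdiff(names(f), aa[p])
    aa[p] <- sample(choices, 1L, prob = f[choices])
  }
  paste(aa, collapse = "")
}

#' Reverse-translate a protein into a synthetic EST
#'
#' Uniform codon choice per residue, random untranslated padding on both
#' sides, and random strand orientation.
#'
#' @param sequence Protein string.
#' @param utr_range Length range of each untranslated end.
#' @return List with `dna` (string), `strand` (`+`/`-`).
#' @export
reverse_translate <- function(sequence, utr_range = c(30L, 90L)) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  codons <- vapply(aa, function(a) {
    opts <- .CODON_TABLE[[a]]
    opts[sample.int(length(opts), 1L)]
  }, "", USE.NAMES = FALSE)
  utr <- function() paste(sample(c("A", "C", "G", "T"),
                                 sample(utr_range[1]:utr_range[2], 1L),
                                 replace = TRUE), collapse = "")
  dna <- paste0(utr(), paste(codons, collapse = ""), "TAA", utr())
  strand <- sample(c("+", "-"), 1L)
  if (strand == "-")
    dna <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  list(dna = dna, strand = strand)
}

#' Generate the study databases
#'
#' Builds the protein search database (in-database sources, planted
#' homologs and background), the EST database (reverse-translated EST-only
#' sources plus background ESTs) and the annotation database (protein
#' database plus the EST source proteins), together with the ground-truth
#' table. Deterministic under `spec$seed`.
#'
#' @param spec [simulation_spec()].
#' @return List with `protein_db`, `est_db`, `annotation_db` (named
#'   character vectors), `sources` (named list of source proteins per
#'   spot class) and `truth` (data.frame `class`, `source_id`,
#'   `expected_accession`).
#' @export
make_databases <- function(spec = simulation_spec()) {
  set.seed(spec$seed)
  rlen <- function() sample(spec$protein_length[1]:spec$protein_length[2], 1L)
  gen <- function(n, prefix) {
    s <- vapply(seq_len(n), function(i) random_protein(rlen()), "")
    stats::setNames(s, sprintf("%s%03d", prefix, seq_len(n)))
  }
  db_src <- gen(spec$n_spots[["db"]], "P")
  est_src <- gen(spec$n_spots[["est"]], "Q")       # EST-only source proteins
  hom_src <- gen(spec$n_spots[["homolog"]], "S")   # homolog-only sources
  homologs <- stats::setNames(
    vapply(hom_src, mutate_protein, "", identity = spec$homolog_identity),
    sub("^S", "H", names(hom_src)))
  background <- gen(spec$n_background, "B")
  protein_db <- c(db_src, homologs, background)
  ests <- lapply(est_src, reverse_translate)
  est_db <- stats::setNames(vapply(ests, `[[`, "", "dna"),
                            sub("^Q", "EST", names(est_src)))
  bg_est <- lapply(gen(10L, "Z"), reverse_translate)
  est_db <- c(est_db, stats::setNames(vapply(bg_est, `[[`, "", "dna"),
                                      sprintf("BGEST%03d", seq_along(bg_est))))
  annotation_db <- c(protein_db,
                     stats::setNames(unname(est_src),
                                     sub("^Q", "ANN", names(est_src))))
  tr <- function(cls, ids, acc) {
    if (!length(ids)) return(NULL)
    data.frame(class = cls, source_id = ids, expected_accession = acc)
  }
  truth <- rbind(
    tr("db", names(db_src), names(db_src)),
    tr("est", names(est_src), sub("^Q", "EST", names(est_src))),
    tr("homolog", names(hom_src), sub("^S", "H", names(hom_src))))
  list(protein_db = protein_db, est_db = est_db,
       annotation_db = annotation_db,
       sources = list(db = db_src, est = est_src, homolog = hom_src),
       truth = truth)
}

.jitter <- function(mz, sd) if (sd > 0) mz + stats::rnorm(length(mz), 0, sd) else mz

#' Simulate one MALDI spot from a protein
#'
#' Digests the protein, picks up to `spectra_per_spot` tryptic peptides in
#' the instrument's 850-4000 Da window, and builds the MS peak list (all
#' eligible peptide masses plus noise) and one MS/MS spectrum per chosen
#' peptide (ion ladders sampled at the configured detection probabilities,
#' lognormal intensities, Gaussian m/z jitter, uniform noise peaks).
#' Sampling uses the current RNG state; seed upstream for determinism.
#'
#' @param protein_sequence Source protein.
#' @param id Spot id.
#' @param spec [simulation_spec()].
#' @return List with `spot` (a [spot()]) and `peptides` (data.frame
#'   `spectrum`, `sequence`, `mods`, `mh`), or NULL when no tryptic
#'   peptide falls in the window.
#' @export
simulate_spot <- function(protein_sequence, id, spec = simulation_spec()) {
  dig <- digest_protein(protein_sequence, max_missed = 0L)
  dig$mh <- vapply(dig$sequence, function(s) {
    nC <- sum(strsplit(s, "")[[1]] == "C")
    peptide_mh(s) + nC * 57.021464
  }, 0, USE.NAMES = FALSE)
  elig <- dig[dig$mh >= 850 & dig$mh <= 4000 &
              nchar(dig$sequence) >= spec$peptide_length[1] &
              nchar(dig$sequence) <= spec$peptide_length[2], , drop = FALSE]
  if (!nrow(elig)) return(NULL)
  sel <- elig[sample.int(nrow(elig), min(spec$spectra_per_spot, nrow(elig))), ,
              drop = FALSE]
  # MS list: all eligible peptide masses + noise
  ms_mz <- .jitter(elig$mh, spec$calibration_sd)
  ms_int <- stats::rlnorm(length(ms_mz), spec$intensity_meanlog,
                          spec$intensity_sdlog)
  ms_sn <- stats::runif(length(ms_mz), 55, 150)
  if (spec$n_noise_ms > 0L) {
    ms_mz <- c(ms_mz, stats::runif(spec$n_noise_ms, 850, 4000))
    ms_int <- c(ms_int, stats::qlnorm(stats::runif(spec$n_noise_ms, 0, 0.25),
                                      spec$intensity_meanlog,
                                      spec$intensity_sdlog))
    ms_sn <- c(ms_sn, stats::runif(spec$n_noise_ms, 3, 30))
  }
  msms <- list()
  pep_truth <- list()
  for (k in seq_len(nrow(sel))) {
    s <- sel$sequence[k]
    letters <- strsplit(s, "", fixed = TRUE)[[1]]
    mods <- data.frame(pos = integer(), name = character(), delta = numeric())
    cpos <- which(letters == "C")
    if (length(cpos))
      mods <- rbind(mods, data.frame(pos = cpos, name = "Carbamidomethyl",
                                     delta = 57.021464))
    mpos <- which(letters == "M")
    ox <- mpos[stats::runif(length(mpos)) < spec$oxidation_incidence]
    ox <- utils::head(ox, 2L)
    if (length(ox))
      mods <- rbind(mods, data.frame(pos = ox, name = "Oxidation",
                                     delta = 15.994915))
    pep <- peptide(s, mods = mods)
    mh <- peptide_mh(pep)
    primary <- fragment_ions(pep, series = c("b", "y"))
    secondary <- fragment_ions(pep, series = c("a", "b-H2O", "b-NH3",
                                               "y-H2O", "y-NH3", "immonium"))
    keep1 <- stats::runif(nrow(primary)) < spec$detection_prob
    keep2 <- stats::runif(nrow(secondary)) < spec$secondary_prob
    mz <- c(primary$mz[keep1], secondary$mz[keep2])
    int <- c(stats::rlnorm(sum(keep1), spec$intensity_meanlog,
                           spec$intensity_sdlog),
             stats::rlnorm(sum(keep2), spec$intensity_meanlog + log(0.3),
                           spec$intensity_sdlog))
    if (spec$n_noise_msms > 0L) {
      mz <- c(mz, stats::runif(spec$n_noise_msms, 100, mh - 50))
      int <- c(int, stats::qlnorm(stats::runif(spec$n_noise_msms, 0, 0.25),
                                  spec$intensity_meanlog,
                                  spec$intensity_sdlog))
    }
    keep <- mz > 0
    mz <- .jitter(mz[keep], spec$calibration_sd); int <- int[keep]
    if (!length(mz)) next
    msms[[length(msms) + 1L]] <- list(precursor = .jitter(mh, spec$calibration_sd),
                                      peaks = peak_list(mz, int))
    pep_truth[[length(pep_truth) + 1L]] <- data.frame(
      spectrum = length(msms), sequence = s,
      mods = if (nrow(mods)) paste(paste0(mods$pos, ":", mods$name),
                                   collapse = ";") else "",
      mh = mh)
  }
  if (!length(msms)) return(NULL)
  list(spot = spot(id, peak_list(ms_mz, ms_int, sn = ms_sn), msms),
       peptides = do.call(rbind, pep_truth))
}

.simulate_junk_spot <- function(id, spec) {
  n_ms <- 30L
  ms <- peak_list(stats::runif(n_ms, 850, 4000),
                  stats::rlnorm(n_ms, spec$intensity_meanlog,
                                spec$intensity_sdlog),
                  sn = stats::runif(n_ms, 40, 120))
  msms <- lapply(seq_len(min(3L, spec$spectra_per_spot)), function(k) {
    prec <- stats::runif(1, 900, 2200)
    n <- 40L
    list(precursor = prec,
         peaks = peak_list(stats::runif(n, 100, prec - 20),
                           stats::rlnorm(n, spec$intensity_meanlog,
                                         spec$intensity_sdlog)))
  })
  spot(id, ms, msms)
}

#' Simulate a full study with ground truth
#'
#' Generates the databases and one spot per planted routing class entry,
#' plus junk spots with no source. Deterministic for a given seed;
#' optionally writes the MGF, the three FASTA files and the ground-truth
#' TSV to a directory.
#'
#' @param spec [simulation_spec()].
#' @param out_dir Optional output directory.
#' @return List with `spots`, `protein_db`, `est_db`, `annotation_db`,
#'   `truth` (spot-level data.frame: `spot`, `class`, `layer`,
#'   `expected_accession`), `peptides` (per-spectrum truth).
#' @export
simulate_study <- function(spec = simulation_spec(), out_dir = NULL) {
  dbs <- make_databases(spec)          # seeds the RNG stream
  spots <- list(); truth <- list(); peptides <- list()
  classes <- data.frame(
    class = rep(c("db", "est", "homolog"),
                times = c(spec$n_spots[["db"]], spec$n_spots[["est"]],
                          spec$n_spots[["homolog"]])),
    source_id = c(names(dbs$sources$db), names(dbs$sources$est),
                  names(dbs$sources$homolog)))
  planted_layer <- c(db = "1", est = "2", homolog = "3")
  for (i in seq_len(nrow(classes))) {
    cls <- classes$class[i]; src <- classes$source_id[i]
    sid <- sprintf("spot%03d", i)
    sim <- simulate_spot(dbs$sources[[cls]][[src]], sid, spec)
    if (is.null(sim)) next
    spots[[length(spots) + 1L]] <- sim$spot
    truth[[length(truth) + 1L]] <- data.frame(
      spot = sid, class = cls, layer = planted_layer[[cls]],
      source_id = src,
      expected_accession = dbs$truth$expected_accession[
        dbs$truth$source_id == src])
    pt <- sim$peptides; pt$spot <- sid
    peptides[[length(peptides) + 1L]] <- pt
  }
  for (j in seq_len(spec$n_spots[["junk"]])) {
    sid <- sprintf("spot%03d", nrow(classes) + j)
    spots[[length(spots) + 1L]] <- .simulate_junk_spot(sid, spec)
    truth[[length(truth) + 1L]] <- data.frame(
      spot = sid, class = "junk", layer = "none", source_id = NA_character_,
      expected_accession = NA_character_)
  }
  res <- list(spots = spots, protein_db = dbs$protein_db,
              est_db = dbs$est_db, annotation_db = dbs$annotation_db,
              truth = do.call(rbind, truth),
              peptides = do.call(rbind, peptides))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_mgf(res$spots, file.path(out_dir, "spots.mgf"))
    wfa <- function(x, f) {
      con <- file(file.path(out_dir, f), "w")
      on.exit(close(con), add = TRUE)
      for (nm in names(x)) writeLines(c(paste0(">", nm), x[[nm]]), con)
    }
    wfa(res$protein_db, "proteins.fasta")
    wfa(res$est_db, "ests.fasta")
    wfa(res$annotation_db, "annotation.fasta")
    utils::write.table(res$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
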