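# Layer 1: combined PMF + MS/MS probability-scored search against a protein
# FASTA. The score model is a transparent binomial shared-peak-count model:
# each retained spectrum peak matches a theoretical ion by chance with
# probability q = (n_ions * 2 * tol) / span, the observed match count k has a
# binomial tail probability p, the ions score is -10*log10(p), and E-values
# multiply p by the number of trials (candidate peptides, database proteins).

#' Layer-1 search configuration
#'
#' @param peptide_tol_ppm Precursor/peptide mass tolerance in ppm (default 50).
#' @param fragment_tol Fragment tolerance in Da (default 0.25).
#' @param max_missed Maximum missed cleavages (default 1).
#' @param mods Modification list, see [default_modifications()].
#' @param max_variable Cap on simultaneous variable-mod sites (default 2).
#' @param alpha Significance level for peptide matches (default 0.05).
#' @return A `search_config` list.
#' @export
search_config <- function(peptide_tol_ppm = 50, fragment_tol = 0.25,
                          max_missed = 1L, mods = default_modifications(),
                          max_variable = 2L, alpha = 0.05) {
  stopifnot(peptide_tol_ppm > 0, fragment_tol > 0, alpha > 0, alpha < 1)
  structure(list(peptide_tol_ppm = peptide_tol_ppm, fragment_tol = fragment_tol,
                 max_missed = as.integer(max_missed), mods = mods,
                 max_variable = as.integer(max_variable), alpha = alpha),
            class = "search_config")
}

#' Build a mass-keyed tryptic peptide index
#'
#' Digests every database protein, enumerates modified forms, and stores the
#' peptides sorted by neutral mass for tolerance-window lookup.
#'
#' @param proteins Named character vector or `AAStringSet` (see
#'   [read_protein_fasta()]); an empty database is an error.
#' @param config [search_config()].
#' @return A `peptide_index` with the peptide table, source accessions and
#'   database size.
#' @export
build_peptide_index <- function(proteins, config = search_config()) {
  if (methods::is(proteins, "XStringSet")) {
    desc <- attr(proteins, "descriptions")
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  } else desc <- NULL
  if (!length(proteins)) stop("empty protein database")
  if (is.null(names(proteins))) stop("database sequences must be named")
  tabs <- vector("list", length(proteins))
  for (i in seq_along(proteins)) {
    seqi <- gsub("[^A-Z]", "", toupper(proteins[[i]]))
    seqi <- gsub("[BJOUXZ]", "", seqi)   # drop non-standard letters
    if (!nchar(seqi)) next
    pep <- digest_protein(seqi, max_missed = config$max_missed,
                          accession = names(proteins)[i])
    if (nrow(pep)) tabs[[i]] <- pep
  }
  tab0 <- do.call(rbind, tabs[!vapply(tabs, is.null, TRUE)])
  if (is.null(tab0) || !nrow(tab0)) stop("database produced no peptides")
  # fixed modifications apply implicitly (mod_string records variable only)
  fixed_delta <- rep(0, nrow(tab0))
  var_specs <- list()
  for (m in config$mods) {
    if (m$mode == "fixed") {
      cnt <- nchar(tab0$sequence) -
        nchar(gsub(m$target, "", tab0$sequence, fixed = TRUE))
      fixed_delta <- fixed_delta + cnt * m$delta
    } else var_specs[[length(var_specs) + 1L]] <- m
  }
  base_rows <- data.frame(row = seq_len(nrow(tab0)), mod_string = "",
                          delta = fixed_delta, n_variable = 0L)
  extra <- list(base_rows)
  for (m in var_specs) {
    has <- grepl(m$target, tab0$sequence, fixed = TRUE)
    if (!any(has)) next
    sites <- gregexpr(m$target, tab0$sequence[has], fixed = TRUE)
    widx <- which(has)
    for (j in seq_along(widx)) {
      pos <- as.integer(sites[[j]])
      nv <- length(pos)
      combos <- unlist(lapply(seq_len(min(config$max_variable, nv)),
                              function(k) utils::combn(pos, k, simplify = FALSE)),
                       recursive = FALSE)
      for (cmb in combos) {
        extra[[length(extra) + 1L]] <- data.frame(
          row = widx[j],
          mod_string = paste(paste0(cmb, ":", m$name), collapse = ";"),
          delta = fixed_delta[widx[j]] + length(cmb) * m$delta,
          n_variable = length(cmb))
      }
    }
  }
  forms <- do.call(rbind, extra)
  tab <- tab0[forms$row, , drop = FALSE]
  tab$mod_string <- forms$mod_string
  tab$delta <- forms$delta
  tab$n_variable <- forms$n_variable
  useq <- unique(tab$sequence)
  lookup <- numeric(128)
  lookup[utf8ToInt(paste(names(.RESIDUE_MASSES), collapse = ""))] <-
    unname(.RESIDUE_MASSES)
  umass <- vapply(useq, function(s) sum(lookup[utf8ToInt(s)]), 0,
                  USE.NAMES = FALSE)
  tab$mass <- umass[match(tab$sequence, useq)] + tab$delta + .MASS_WATER
  tab <- tab[order(tab$mass), , drop = FALSE]
  rownames(tab) <- NULL
  # duplicated names are allowed (multi-segment entries share an accession)
  structure(list(peptides = tab, accessions = unique(names(proteins)),
                 descriptions = desc, n_proteins = length(unique(names(proteins))),
                 masses_by_acc = split(tab$mass, tab$accession)),
            class = "peptide_index")
}

#' Look up index candidates by neutral mass
#'
#' @param index [build_peptide_index()] result.
#' @param mass Neutral peptide mass (Da).
#' @param ppm Tolerance in ppm.
#' @return Rows of the peptide table within tolerance.
#' @export
index_lookup <- function(index, mass, ppm = 50) {
  tol <- mass * ppm * 1e-6
  m <- index$peptides$mass
  lo <- findInterval(mass - tol, m) + 1L
  hi <- findInterval(mass + tol, m)
  if (hi < lo) return(index$peptides[0, , drop = FALSE])
  index$peptides[lo:hi, , drop = FALSE]
}

.peptide_from_row <- function(row, mods = default_modifications()) {
  md <- data.frame(pos = integer(), name = character(), delta = numeric())
  by_name <- stats::setNames(mods, vapply(mods, `[[`, "", "name"))
  for (m in mods) {
    if (m$mode != "fixed") next
    pos <- which(strsplit(row$sequence, "", fixed = TRUE)[[1]] == m$target)
    if (length(pos))
      md <- rbind(md, data.frame(pos = pos, name = m$name, delta = m$delta))
  }
  if (nzchar(row$mod_string)) {
    parts <- strsplit(row$mod_string, ";", fixed = TRUE)[[1]]
    pos <- as.integer(sub(":.*", "", parts))
    name <- sub(".*:", "", parts)
    delta <- vapply(name, function(nm)
      if (!is.null(by_name[[nm]])) by_name[[nm]]$delta else NA_real_, 0)
    md <- rbind(md, data.frame(pos = pos, name = name, delta = unname(delta)))
  }
  peptide(row$sequence, mods = md, missed = row$missed,
          protein = row$accession, start = row$start, end = row$end)
}

# count spectrum peaks (each at most once) lying within tol of any value in
# the sorted vector `targets`
.count_matched <- function(peak_mz, targets, tol) {
  if (!length(peak_mz) || !length(targets)) return(logical(length(peak_mz)))
  targets <- sort(targets)
  idx <- findInterval(peak_mz, targets)
  lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(targets))
  d <- pmin(abs(peak_mz - targets[lo]), abs(peak_mz - targets[hi]))
  d <= tol
}

# scoring ion ladder (b, y, a, water/ammonia losses) from a modified
# residue-mass vector
.ladder_ion_mz <- function(res) {
  n <- length(res)
  if (n < 2L) return(numeric(0))
  pre <- cumsum(res[-n])
  b <- pre + .MASS_PROTON
  y <- sum(res) - pre + .MASS_WATER + .MASS_PROTON
  c(b, y, b - .MASS_CO, b - .MASS_WATER, b - .MASS_AMMONIA,
    y - .MASS_WATER, y - .MASS_AMMONIA)
}

# deterministic composition-preserving shuffles used as per-PSM decoys;
# the C-terminal residue stays fixed so decoys share the tryptic anchor
# (and hence the y1 / low-mass coincidences) of real candidates
.decoy_perms <- function(n) {
  k <- n - 1L          # interior positions to permute
  perms <- list()
  for (m in c(3L, 5L, 7L, 11L, 13L)) {
    if (k > 1L && gcd_helper(m, k) == 1L) {
      p <- c(((seq_len(k) - 1L) * m) %% k + 1L, n)
      if (!identical(p, seq_len(n))) perms[[length(perms) + 1L]] <- p
    }
    if (length(perms) == 3L) break
  }
  perms
}

gcd_helper <- function(a, b) if (b == 0L) a else gcd_helper(b, a %% b)

#' Score one peptide-spectrum match
#'
#' Matches the spectrum against the theoretical b/y/a and neutral-loss ions
#' of the candidate peptide and converts the shared-peak count k into an
#' ions score via a binomial null: each of the N retained peaks matches by
#' chance with probability q. Because peptide fragment masses cluster on
#' the ~1 Da mass-defect lattice, the uniform-span estimate
#' `q0 = (ion count * 2 * tol) / span` is calibrated against deterministic
#' composition-preserving decoys (residue-shuffled versions of the
#' candidate): q is the larger of q0 and the decoys' observed match rate.
#' Ions score = -10*log10(p); E multiplies p by the candidate count.
#'
#' @param spectrum List with `precursor` and `peaks`.
#' @param pep A [peptide()].
#' @param config [search_config()].
#' @param n_candidates Number of candidate peptides tried for this spectrum
#'   (multiplies p into the expectation E).
#' @return List with `peptide`, `k` (matched peaks), `n` (retained peaks),
#'   `ions_score`, `p`, `expect`, `ci` (C.I.%), or `NULL` when the precursor
#'   is outside the peptide tolerance.
#' @export
score_psm <- function(spectrum, pep, config = search_config(), n_candidates = 1L) {
  mh <- peptide_mh(pep)
  if (abs(spectrum$precursor - mh) > mh * config$peptide_tol_ppm * 1e-6)
    return(NULL)
  letters <- strsplit(pep$sequence, "", fixed = TRUE)[[1]]
  res <- .RESIDUE_MASSES[letters]
  if (nrow(pep$mods))
    for (r in seq_len(nrow(pep$mods)))
      res[pep$mods$pos[r]] <- res[pep$mods$pos[r]] + pep$mods$delta[r]
  ions <- .ladder_ion_mz(res)
  mz <- spectrum$peaks$mz
  n <- length(mz)
  if (!n || !length(ions)) return(NULL)
  matched <- .count_matched(mz, ions, config$fragment_tol)
  k <- sum(matched)
  span <- max(mz) - min(mz)
  if (span <= 0) span <- 2 * config$fragment_tol * length(ions)
  q0 <- min(1, length(ions) * 2 * config$fragment_tol / span)
  # decoy chance-match rate over all retained peaks: isobaric interior
  # shuffles with the tryptic C-terminus kept share the lattice clustering
  # and low-mass coincidences of real candidates
  k_dec <- 0L; n_dec <- 0L
  for (perm in .decoy_perms(length(res))) {
    k_dec <- k_dec + sum(.count_matched(mz, .ladder_ion_mz(res[perm]),
                                        config$fragment_tol))
    n_dec <- n_dec + n
  }
  q <- if (n_dec > 0L) max(q0, k_dec / n_dec) else q0
  q <- min(q, 0.9999)
  p <- stats::pbinom(k - 1L, n, q, lower.tail = FALSE)
  p <- max(p, 1e-300)
  score <- if (k == 0L) 0 else -10 * log10(p)
  expect <- p * n_candidates
  list(peptide = pep, k = k, n = n, ions_score = score, p = p, q = q,
       expect = expect, ci = 100 * (1 - min(1, expect)), matched = matched)
}

#' Search one spot against a peptide index
#'
#' For every MS/MS spectrum the index is queried at the precursor mass and
#' every candidate is scored; per protein, the best PSM per spectrum
#' contributes its ions score. A PMF component (binomial tail on the count
#' of MS-peak / peptide-mass matches) is added to form the protein score.
#' Protein and total-ion C.I.% use expectations multiplied by the database
#' protein count.
#'
#' @param spt A [spot()].
#' @param index [build_peptide_index()] result.
#' @param config [search_config()].
#' @return data.frame of protein hits ranked by protein score, with the
#'   per-hit PSM lists in `attr(,"psms")`.
#' @export
search_spot <- function(spt, index, config = search_config()) {
  empty <- data.frame(accession = character(), description = character(),
                      protein_score = numeric(), protein_ci = numeric(),
                      total_ion_score = numeric(), total_ion_ci = numeric(),
                      n_peptides = integer(), n_sig_peptides = integer())
  acc_psms <- list()   # accession -> list of per-spectrum best PSMs
  for (si in seq_along(spt$msms)) {
    sp <- spt$msms[[si]]
    if (!nrow(sp$peaks)) next
    neutral <- sp$precursor - .MASS_PROTON
    cand <- index_lookup(index, neutral, config$peptide_tol_ppm)
    if (!nrow(cand)) next
    ncand <- nrow(cand)
    # score unique (sequence, mod) forms once, reuse across accessions
    key <- paste(cand$sequence, cand$mod_string)
    ukey <- !duplicated(key)
    scores <- stats::setNames(vector("list", sum(ukey)), key[ukey])
    for (r in which(ukey)) {
      psm <- score_psm(sp, .peptide_from_row(cand[r, ], config$mods),
                       config, ncand)
      scores[[key[r]]] <- psm
    }
    # per accession keep best PSM for this spectrum
    for (acc in unique(cand$accession)) {
      rows <- which(cand$accession == acc)
      best <- NULL
      for (r in rows) {
        psm <- scores[[key[r]]]
        if (is.null(psm)) next
        if (is.null(best) || psm$ions_score > best$ions_score) best <- psm
      }
      if (is.null(best)) next
      best$spectrum_index <- si
      acc_psms[[acc]] <- c(acc_psms[[acc]], list(best))
    }
  }
  # PMF component over the filtered MS list
  pmf_score <- stats::setNames(numeric(length(index$accessions)), index$accessions)
  ms <- spt$ms
  if (nrow(ms) >= 1L) {
    mzv <- ms$mz
    span <- max(mzv) - min(mzv)
    tol_abs <- mean(mzv) * config$peptide_tol_ppm * 1e-6
    for (acc in names(index$masses_by_acc)) {
      masses <- index$masses_by_acc[[acc]] + .MASS_PROTON
      if (!length(masses)) next
      k <- sum(.count_matched(mzv, masses, tol_abs))
      if (k == 0L) next
      q <- min(1, length(unique(round(masses, 3))) * 2 * tol_abs /
                 max(span, 2 * tol_abs))
      p <- max(stats::pbinom(k - 1L, length(mzv), q, lower.tail = FALSE), 1e-300)
      pmf_score[acc] <- -10 * log10(p)
    }
  }
  accs <- union(names(acc_psms), names(pmf_score[pmf_score > 0]))
  if (!length(accs)) return(empty)
  rows <- lapply(accs, function(acc) {
    psms <- acc_psms[[acc]]
    total_ion <- sum(vapply(psms, function(p) p$ions_score, 0))
    nsig <- 0L; npep <- 0L
    if (length(psms)) {
      seqs <- vapply(psms, function(p) p$peptide$sequence, "")
      sig <- vapply(psms, function(p) p$expect <= config$alpha, TRUE)
      npep <- length(unique(seqs))
      nsig <- length(unique(seqs[sig]))
    }
    prot_score <- total_ion + pmf_score[acc]
    e_prot <- min(1, 10^(-prot_score / 10) * index$n_proteins)
    e_ion <- min(1, 10^(-total_ion / 10) * index$n_proteins)
    data.frame(accession = acc,
               description = if (!is.null(index$descriptions))
                 unname(index$descriptions[acc]) else NA_character_,
               protein_score = unname(prot_score),
               protein_ci = 100 * (1 - e_prot),
               total_ion_score = total_ion,
               total_ion_ci = 100 * (1 - e_ion),
               n_peptides = npep, n_sig_peptides = nsig)
  })
  hits <- do.call(rbind, rows)
  ord <- order(-hits$protein_score, hits$accession)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "psms") <- acc_psms[hits$accession]
  hits
}

#' Classify the best layer-1 hit
#'
#' At least two significant MS/MS peptides with a protein-score C.I. of 95%
#' or better make a confident identification; a single significant peptide,
#' or matched peptides with a sub-95% C.I., is borderline; anything else is
#' nonconfident.
#'
#' @param best_hit One row of a [search_spot()] result (or NULL/empty).
#' @param ci_threshold Minimum protein-score C.I.% (default 95).
#' @return List with `category` (`confident`/`borderline`/`nonconfident`),
#'   `layer` and `justification`.
#' @export
classify_layer1 <- function(best_hit, ci_threshold = 95) {
  decision <- function(cat, why) list(category = cat, layer = "1", justification = why)
  if (is.null(best_hit) || !nrow(best_hit) ||
      is.na(best_hit$n_sig_peptides[1]))
    return(decision("nonconfident", "no database hit"))
  nsig <- best_hit$n_sig_peptides[1]
  ci <- best_hit$protein_ci[1]
  if (nsig >= 2L && ci >= ci_threshold)
    return(decision("confident",
                    sprintf("%d significant peptides, protein C.I. %.1f%%", nsig, ci)))
  if (nsig == 1L)
    return(decision("borderline", "single significant MS/MS peptide"))
  if (nsig >= 1L || (best_hit$n_peptides[1] >= 1L && ci < ci_threshold))
    return(decision("borderline",
                    sprintf("protein C.I. %.1f%% below %g%%", ci, ci_threshold)))
  decision("nonconfident", "no significant peptide")
}
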