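# Layer 3a: automated de novo sequencing. A spectrum graph is built over
# candidate prefix residue masses (every peak read both as a b ion and as a
# y ion), a beam search enumerates source-to-sink residue paths maximising
# summed node support with a penalty for peakless steps, and candidates are
# rescored by the fraction of total ion abundance their theoretical
# fragments explain (0-100).

#' De novo sequencing configuration
#'
#' @param fragment_tol,parent_tol Fragment / precursor mass tolerance in Da
#'   (default 0.08 each).
#' @param mods Modification list (default [default_modifications()]): fixed
#'   modifications shift their residue's edge mass, variable modifications
#'   add a lowercase edge letter.
#' @param n_report Candidates reported per spectrum (default 10).
#' @param threshold Reliability score filter, strict (default 50).
#' @param penalty Score added for a peakless (unsupported) step, in units of
#'   percent total intensity (default -1).
#' @param beam_width Beam width of the path search (default 200).
#' @param max_internal Internal-fragment length cap during rescoring
#'   (default 5).
#' @return A `denovo_config` list.
#' @export
denovo_config <- function(fragment_tol = 0.08, parent_tol = 0.08,
                          mods = default_modifications(), n_report = 10L,
                          threshold = 50, penalty = -1, beam_width = 200L,
                          max_internal = 5L) {
  stopifnot(fragment_tol > 0, parent_tol > 0, n_report >= 1L,
            threshold >= 0, threshold <= 100, beam_width >= 1L)
  structure(list(fragment_tol = fragment_tol, parent_tol = parent_tol,
                 mods = mods, n_report = as.integer(n_report),
                 threshold = threshold, penalty = penalty,
                 beam_width = as.integer(beam_width),
                 max_internal = as.integer(max_internal)),
            class = "denovo_config")
}

# residue alphabet for graph edges: I is dropped (reported as L), fixed mods
# shift their target, variable mods add a lowercase letter
.denovo_alphabet <- function(config) {
  masses <- .RESIDUE_MASSES[setdiff(names(.RESIDUE_MASSES), "I")]
  for (m in config$mods) {
    if (m$mode == "fixed" && m$target %in% names(masses)) {
      masses[m$target] <- masses[m$target] + m$delta
    } else if (m$mode == "variable" && m$target %in% names(masses)) {
      extra <- stats::setNames(masses[m$target] + m$delta, tolower(m$target))
      masses <- c(masses, extra)
    }
  }
  sort(masses)
}

# expand a (possibly lowercase-modified) candidate string into a peptide
.candidate_peptide <- function(seq, config) {
  letters <- strsplit(seq, "", fixed = TRUE)[[1]]
  mods <- data.frame(pos = integer(), name = character(), delta = numeric())
  for (m in config$mods) {
    if (m$mode == "fixed") {
      p <- which(toupper(letters) == m$target)
    } else {
      p <- which(letters == tolower(m$target))
    }
    if (length(p))
      mods <- rbind(mods, data.frame(pos = p, name = m$name, delta = m$delta))
  }
  peptide(toupper(seq), mods = mods)
}

#' Build a spectrum graph
#'
#' Every peak is interpreted both as a b ion (prefix mass `mz - proton`) and
#' as a y ion (prefix mass `precursor - mz`); interpretations agreeing
#' within the fragment tolerance are merged into one node whose score is the
#' summed relative intensity (percent of total) of its supporting peaks.
#' The source is prefix mass 0 and the sink the total residue mass
#' `precursor - proton - water`.
#'
#' @param msms Peak data.frame (deconvoluted, singly charged).
#' @param precursor Precursor m/z (singly protonated).
#' @param config [denovo_config()].
#' @return List with `nodes` (data.frame `mass`, `score`), `sink`,
#'   `precursor`.
#' @export
build_spectrum_graph <- function(msms, precursor, config = denovo_config()) {
  sink <- precursor - .MASS_PROTON - .MASS_WATER
  if (sink < min(.RESIDUE_MASSES) - config$parent_tol)
    return(list(nodes = data.frame(mass = numeric(), score = numeric()),
                sink = sink, precursor = precursor))
  total <- sum(msms$intensity)
  if (!nrow(msms) || total <= 0) {
    nodes <- data.frame(mass = numeric(), score = numeric())
    return(list(nodes = nodes, sink = sink, precursor = precursor))
  }
  rel <- 100 * msms$intensity / total
  cand <- data.frame(mass = c(msms$mz - .MASS_PROTON, precursor - msms$mz),
                     score = c(rel, rel))
  cand <- cand[cand$mass > config$fragment_tol &
               cand$mass < sink - config$fragment_tol, , drop = FALSE]
  if (!nrow(cand))
    return(list(nodes = data.frame(mass = numeric(), score = numeric()),
                sink = sink, precursor = precursor))
  cand <- cand[order(cand$mass), , drop = FALSE]
  grp <- cumsum(c(1L, diff(cand$mass) > config$fragment_tol))
  mass <- vapply(split(seq_len(nrow(cand)), grp), function(i)
    sum(cand$mass[i] * cand$score[i]) / sum(cand$score[i]), 0)
  score <- vapply(split(cand$score, grp), sum, 0)
  list(nodes = data.frame(mass = unname(mass), score = unname(score)),
       sink = sink, precursor = precursor)
}

#' Enumerate sequence candidates from a spectrum graph
#'
#' Beam search over residue-labelled source-to-sink paths maximising summed
#' node scores, with the configured penalty for steps landing on no node.
#' Emitted sequences satisfy the parent-mass constraint within the parent
#' tolerance.
#'
#' @param graph [build_spectrum_graph()] result.
#' @param config [denovo_config()].
#' @return data.frame with `sequence` (lowercase letters mark variable
#'   modifications) and `graph_score`, best first; empty when no path
#'   reaches the sink.
#' @export
generate_candidates <- function(graph, config = denovo_config()) {
  alpha <- .denovo_alphabet(config)
  S <- graph$sink
  empty <- data.frame(sequence = character(), graph_score = numeric())
  if (S < min(alpha) - config$parent_tol) return(empty)
  nm <- graph$nodes$mass; ns <- graph$nodes$score
  nr <- length(alpha)
  res_letters <- names(alpha); res_mass <- unname(alpha)
  beam_mass <- 0; beam_score <- 0; beam_seq <- ""
  done_seq <- character(); done_score <- numeric()
  max_depth <- ceiling(S / min(alpha)) + 1L
  for (depth in seq_len(max_depth)) {
    k <- length(beam_mass)
    if (!k) break
    new_mass <- rep(beam_mass, times = nr) + rep(res_mass, each = k)
    new_seq <- paste0(rep(beam_seq, times = nr), rep(res_letters, each = k))
    base <- rep(beam_score, times = nr)
    gain <- rep(config$penalty, length(new_mass))
    if (length(nm)) {
      idx <- findInterval(new_mass, nm)
      lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(nm))
      dlo <- abs(new_mass - nm[lo]); dhi <- abs(new_mass - nm[hi])
      nearest <- ifelse(dlo <= dhi, lo, hi)
      ok <- pmin(dlo, dhi) <= config$fragment_tol
      gain[ok] <- ns[nearest[ok]]
    }
    complete <- abs(new_mass - S) <= config$parent_tol
    if (any(complete)) {
      # completion lands on the sink: matched node support counts, but no
      # penalty for an unsupported final step
      cg <- gain[complete]; cg[cg < 0] <- 0
      done_seq <- c(done_seq, new_seq[complete])
      done_score <- c(done_score, base[complete] + cg)
    }
    new_score <- base + gain
    extend <- !complete & (new_mass <= S - min(alpha) + config$parent_tol)
    if (!any(extend)) break
    ordx <- order(-new_score[extend], new_mass[extend])
    keep <- which(extend)[ordx][seq_len(min(config$beam_width, sum(extend)))]
    beam_mass <- new_mass[keep]; beam_score <- new_score[keep]
    beam_seq <- new_seq[keep]
  }
  if (!length(done_seq)) return(empty)
  u <- !duplicated(done_seq)
  out <- data.frame(sequence = done_seq[u], graph_score = done_score[u])
  out <- out[order(-out$graph_score, out$sequence), , drop = FALSE]
  out <- utils::head(out, config$beam_width)
  rownames(out) <- NULL
  out
}

# fast theoretical ion list for rescoring (b, y, a, losses, immonium,
# internal b-type up to max_internal)
.rescore_ions <- function(res, max_internal) {
  n <- length(res)
  total <- sum(res)
  mz <- res - .MASS_CO + .MASS_PROTON           # immonium
  if (n >= 2L) {
    pre <- cumsum(res[-n])
    b <- pre + .MASS_PROTON
    y <- total - pre + .MASS_WATER + .MASS_PROTON
    mz <- c(mz, b, y, b - .MASS_CO, b - .MASS_WATER, b - .MASS_AMMONIA,
            y - .MASS_WATER, y - .MASS_AMMONIA)
  }
  if (n >= 3L) {
    cs <- c(0, cumsum(res))
    for (i in 2:(n - 1L)) {
      jmax <- min(n - 1L, i + max_internal - 1L)
      mz <- c(mz, cs[(i + 1L):(jmax + 1L)] - cs[i] + .MASS_PROTON)
    }
  }
  mz
}

#' Rescore a candidate against its spectrum
#'
#' Returns the percentage of total ion abundance explained by the
#' candidate's typical fragment ions (b, y, a, water/ammonia losses,
#' immonium, internal b-type), each peak counted once.
#'
#' @param sequence Candidate string (lowercase marks variable mods).
#' @param msms Peak data.frame.
#' @param config [denovo_config()].
#' @return Score in \[0, 100\].
#' @export
rescore_candidate <- function(sequence, msms, config = denovo_config()) {
  total <- sum(msms$intensity)
  if (!nrow(msms) || total <= 0) return(0)
  alpha <- .denovo_alphabet(config)
  res <- unname(alpha[strsplit(sequence, "", fixed = TRUE)[[1]]])
  ions <- .rescore_ions(res, config$max_internal)
  matched <- .count_matched(msms$mz, ions, config$fragment_tol)
  100 * sum(msms$intensity[matched]) / total
}

#' Rank, truncate and filter rescored candidates
#'
#' Sorts by score descending — ties broken by spectrum-graph support when
#' available (isobaric rearrangements can explain identical ion abundance,
#' but only the true path lands on supported graph nodes at every
#' boundary), then by shorter sequence, then lexicographically — truncates
#' to the reporting depth, and marks candidates passing the strict
#' reliability filter.
#'
#' @param candidates data.frame with `sequence`, `score` and optionally
#'   `graph_score`.
#' @param config [denovo_config()].
#' @return data.frame with `rank`, `sequence`, `score`, `passes_filter`.
#' @export
finalize_candidates <- function(candidates, config = denovo_config()) {
  if (!nrow(candidates))
    return(data.frame(rank = integer(), sequence = character(),
                      score = numeric(), passes_filter = logical()))
  gs <- if ("graph_score" %in% names(candidates)) candidates$graph_score
        else rep(0, nrow(candidates))
  ord <- order(-candidates$score, -gs, nchar(candidates$sequence),
               candidates$sequence)
  out <- candidates[ord, , drop = FALSE]
  out <- utils::head(out, config$n_report)
  data.frame(rank = seq_len(nrow(out)), sequence = out$sequence,
             score = out$score, passes_filter = out$score > config$threshold)
}

#' De novo sequence one MS/MS spectrum
#'
#' Deconvolutes the peak list, builds the spectrum graph, enumerates
#' candidates, rescores them by explained ion abundance, and applies the
#' reporting and reliability rules. I is never emitted (L stands for the
#' I/L pair) and K/Q calls are flagged ambiguous when the fragment
#' tolerance cannot separate them.
#'
#' @param spectrum List with `precursor` and `peaks`.
#' @param config [denovo_config()].
#' @return data.frame with `rank`, `sequence`, `mods`, `score`, `mh`,
#'   `passes_filter`, `il_ambiguous`, `kq_ambiguous`.
#' @export
denovo_spectrum <- function(spectrum, config = denovo_config()) {
  peaks <- deconvolute_to_singly_charged(spectrum$peaks)
  graph <- build_spectrum_graph(peaks, spectrum$precursor, config)
  cand <- generate_candidates(graph, config)
  empty <- data.frame(rank = integer(), sequence = character(),
                      mods = character(), score = numeric(), mh = numeric(),
                      passes_filter = logical(), il_ambiguous = logical(),
                      kq_ambiguous = logical())
  if (!nrow(cand)) return(empty)
  cand$score <- vapply(cand$sequence, rescore_candidate, 0,
                       msms = peaks, config = config, USE.NAMES = FALSE)
  out <- finalize_candidates(cand, config)
  if (!nrow(out)) return(empty)
  alpha <- .denovo_alphabet(config)
  out$mods <- vapply(out$sequence, function(s) {
    pep <- .candidate_peptide(s, config)
    if (!nrow(pep$mods)) "" else
      paste(paste0(pep$mods$pos, ":", pep$mods$name), collapse = ";")
  }, "", USE.NAMES = FALSE)
  out$mh <- vapply(out$sequence, function(s)
    sum(alpha[strsplit(s, "", fixed = TRUE)[[1]]]) + .MASS_WATER + .MASS_PROTON,
    0, USE.NAMES = FALSE)
  out$il_ambiguous <- grepl("L", out$sequence, fixed = TRUE)
  out$kq_ambiguous <- config$fragment_tol >= 0.0364 &
    grepl("[KQkq]", out$sequence)
  out$sequence <- out$sequence
  out[, c("rank", "sequence", "mods", "score", "mh", "passes_filter",
          "il_ambiguous", "kq_ambiguous")]
}

#' Write per-spectrum de novo candidates as TSV
#'
#' One row per candidate: spot, spectrum index, precursor, rank, sequence,
#' mods, score, passes_filter — the shape of a study-wide candidate
#' supplement.
#'
#' @param spt A [spot()].
#' @param path Output TSV path.
#' @param config [denovo_config()].
#' @return The candidate data.frame, invisibly.
#' @export
write_denovo_candidates <- function(spt, path, config = denovo_config()) {
  rows <- list()
  for (si in seq_along(spt$msms)) {
    dn <- denovo_spectrum(spt$msms[[si]], config)
    if (!nrow(dn)) next
    rows[[length(rows) + 1L]] <- data.frame(
      spot = spt$id, spectrum = si,
      precursor = sprintf("%.4f", spt$msms[[si]]$precursor),
      rank = dn$rank, sequence = toupper(dn$sequence), mods = dn$mods,
      score = sprintf("%.2f", dn$score), passes_filter = dn$passes_filter)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(spot = character(), spectrum = integer(),
               precursor = character(), rank = integer(),
               sequence = character(), mods = character(),
               score = character(), passes_filter = logical())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Canonicalise a peptide for mass-ambiguity comparison
#'
#' Maps I to L and, when `kq` is TRUE, Q to K, so that sequences equal up to
#' isobaric calls compare equal.
#'
#' @param seq Character vector of sequences.
#' @param kq Collapse K/Q (default TRUE, matching a 0.08 Da tolerance).
#' @return Canonicalised uppercase sequences.
#' @export
canonical_sequence <- function(seq, kq = TRUE) {
  s <- toupper(seq)
  s <- gsub("I", "L", s, fixed = TRUE)
  if (kq) s <- gsub("Q", "K", s, fixed = TRUE)
  s
}
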