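# Layer 2: six-frame translation of an EST database, spectrum search against
# the translated segments, and alignment-based annotation of matched ESTs
# against a protein database with Karlin-Altschul significance.

.FRAME_LABELS <- c("+1", "+2", "+3", "-1", "-2", "-3")

#' Six-frame translation of a nucleotide database
#'
#' Translates each EST in all six frames with the standard genetic code
#' (reverse frames translate the reverse complement), splits the products at
#' stop codons, and records 1-based strand-aware nucleotide coordinates of
#' each segment on the original sequence.
#'
#' @param ests `DNAStringSet`, named character vector, or path to a
#'   nucleotide FASTA. IUPAC ambiguity codes are allowed; codons that do not
#'   resolve translate to `X`.
#' @param min_length Minimum segment length in residues (default 1).
#' @return data.frame with columns `est`, `frame` (`+1`..`-3`), `segment`
#'   (index within frame), `sequence`, `nt_start`, `nt_end` (coordinates on
#'   the forward strand; for reverse frames `nt_start > nt_end`).
#' @export
six_frame_translate <- function(ests, min_length = 1L) {
  if (is.character(ests) && length(ests) == 1L && file.exists(ests))
    ests <- Biostrings::readDNAStringSet(ests)
  if (!methods::is(ests, "DNAStringSet"))
    ests <- Biostrings::DNAStringSet(ests)
  names(ests) <- sub("\\s.*$", "", names(ests))
  # batch all (est, frame) chunks into one translate() call
  L <- Biostrings::width(ests)
  rc <- Biostrings::reverseComplement(ests)
  chunk_src <- list(); chunk_est <- character(); chunk_frame <- character()
  for (lab in .FRAME_LABELS) {
    k <- as.integer(substring(lab, 2))
    len <- ((L - k + 1L) %/% 3L) * 3L
    ok <- which(len >= 3L)
    if (!length(ok)) next
    src <- if (startsWith(lab, "+")) ests[ok] else rc[ok]
    chunk_src[[lab]] <- Biostrings::subseq(src, start = k, width = len[ok])
    chunk_est <- c(chunk_est, names(ests)[ok])
    chunk_frame <- c(chunk_frame, rep(lab, length(ok)))
  }
  empty <- data.frame(est = character(), frame = character(),
                      segment = integer(), sequence = character(),
                      nt_start = integer(), nt_end = integer())
  if (!length(chunk_src)) return(empty)
  all_chunks <- do.call(c, unname(chunk_src))
  aa <- as.character(Biostrings::translate(all_chunks, if.fuzzy.codon = "X"))
  est_v <- character(); frame_v <- character(); seg_v <- integer()
  seq_v <- character(); ns_v <- integer(); ne_v <- integer()
  for (ci in seq_along(aa)) {
    lab <- chunk_frame[ci]
    k <- as.integer(substring(lab, 2))
    Lc <- L[match(chunk_est[ci], names(ests))]
    segs <- strsplit(aa[ci], "*", fixed = TRUE)[[1]]
    pos <- 1L   # residue position within the frame translation
    for (si in seq_along(segs)) {
      seg <- segs[si]
      if (nchar(seg) >= max(min_length, 1L)) {
        a <- pos; b <- pos + nchar(seg) - 1L
        nt_a <- k + 3L * (a - 1L); nt_b <- k + 3L * b - 1L  # on source strand
        if (startsWith(lab, "+")) { ns <- nt_a; ne <- nt_b }
        else { ns <- Lc - nt_a + 1L; ne <- Lc - nt_b + 1L }
        est_v <- c(est_v, chunk_est[ci]); frame_v <- c(frame_v, lab)
        seg_v <- c(seg_v, si); seq_v <- c(seq_v, seg)
        ns_v <- c(ns_v, ns); ne_v <- c(ne_v, ne)
      }
      pos <- pos + nchar(seg) + 1L
    }
  }
  if (!length(seq_v)) return(empty)
  data.frame(est = est_v, frame = frame_v, segment = seg_v,
             sequence = seq_v, nt_start = ns_v, nt_end = ne_v)
}

#' Build a peptide index over translated EST segments
#'
#' Each (EST, frame) pair becomes one searchable entry with accession
#' `estid|frame`; its tryptic peptides are drawn from all stop-free segments
#' of that frame.
#'
#' @param frames [six_frame_translate()] output.
#' @param config [search_config()].
#' @param min_orf Minimum segment length in residues to index (default 6).
#' @return A `peptide_index` over EST-frame accessions, or NULL when no
#'   segment reaches `min_orf`.
#' @export
build_est_index <- function(frames, config = search_config(), min_orf = 6L) {
  frames <- frames[nchar(frames$sequence) >= min_orf, , drop = FALSE]
  if (!nrow(frames)) return(NULL)
  acc <- paste0(frames$est, "|", frames$frame)
  # one entry per stop-free segment; segments of a frame share an accession
  build_peptide_index(stats::setNames(frames$sequence, acc), config)
}

#' Search a spot against translated EST frames
#'
#' Identical contract to [search_spot()], with accessions `estid|frame`.
#'
#' @param spt A [spot()].
#' @param est_index [build_est_index()] result (NULL gives an empty result).
#' @param config [search_config()].
#' @return Ranked hit data.frame as in [search_spot()].
#' @export
search_est <- function(spt, est_index, config = search_config()) {
  if (is.null(est_index))
    return(data.frame(accession = character(), description = character(),
                      protein_score = numeric(), protein_ci = numeric(),
                      total_ion_score = numeric(), total_ion_ci = numeric(),
                      n_peptides = integer(), n_sig_peptides = integer()))
  search_spot(spt, est_index, config)
}

#' Annotate an EST against a protein database
#'
#' Finds the best gapped local alignment (affine gaps, open 11 / extend 1)
#' between any translated stop-free segment of the EST and any database
#' protein, and converts the score to an E-value `K*m*n*exp(-lambda*S)`
#' with m the total translated length and n the database residue count,
#' using ungapped moment-method (lambda, K) for the matrix.
#'
#' @param est Single named nucleotide sequence (named character or
#'   `DNAStringSet` of length 1).
#' @param proteins Protein database (named character or `AAStringSet`).
#' @param matrix Substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend Affine gap costs (defaults 11, 1).
#' @param params Optional precomputed [karlin_params()].
#' @return List with `est`, `accession`, `score` (alignment score),
#'   `bits`, `evalue`, `frame`, plus aligned ranges `query_range` (residues
#'   in the translated frame) and `subject_range`; NULL when the EST has no
#'   translatable segment.
#' @export
annotate_blastx <- function(est, proteins, matrix = blosum62(),
                            gap_open = 11, gap_extend = 1, params = NULL) {
  if (methods::is(proteins, "XStringSet"))
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  if (!length(proteins)) stop("empty protein database")
  if (methods::is(est, "DNAStringSet"))
    est <- stats::setNames(as.character(est), names(est))
  frames <- six_frame_translate(est, min_length = 1L)
  frames <- frames[nchar(frames$sequence) >= 3L, , drop = FALSE]
  if (!nrow(frames)) return(NULL)
  if (is.null(params)) params <- karlin_params(matrix)
  m_len <- sum(nchar(frames$sequence))
  n_len <- sum(nchar(proteins))
  segs <- Biostrings::AAStringSet(frames$sequence)
  best <- NULL
  for (j in seq_along(proteins)) {
    subj <- gsub("[^A-Z]", "", toupper(proteins[[j]]))
    subj <- gsub("[BJOUZ]", "X", subj)
    al <- Biostrings::pairwiseAlignment(
      segs, Biostrings::AAString(subj), type = "local",
      substitutionMatrix = matrix, gapOpening = gap_open,
      gapExtension = gap_extend)
    sc <- Biostrings::score(al)
    b <- which.max(sc)
    if (is.null(best) || sc[b] > best$score) {
      pr <- al[b]
      best <- list(
        est = names(est)[1], accession = names(proteins)[j],
        score = sc[b], frame = frames$frame[b],
        query_range = c(Biostrings::start(Biostrings::pattern(pr)),
                        Biostrings::end(Biostrings::pattern(pr))),
        subject_range = c(Biostrings::start(Biostrings::subject(pr)),
                          Biostrings::end(Biostrings::subject(pr))))
    }
  }
  best$bits <- (params$lambda * best$score - log(params$K)) / log(2)
  best$evalue <- params$K * m_len * n_len * exp(-params$lambda * best$score)
  best
}

#' Classify a layer-2 (EST) identification
#'
#' Confident only when the total-ion C.I.% of the EST hit reaches the
#' threshold and the annotation E-value is at most `e_threshold`; otherwise
#' the spot passes on to layer 3.
#'
#' @param est_hit Best row of a [search_est()] result (or NULL/empty).
#' @param annotation [annotate_blastx()] result (or NULL).
#' @param ci_threshold Minimum total-ion C.I.% (default 95).
#' @param e_threshold Maximum E-value (default 1e-20).
#' @return List with `category` (`confident`/`nonconfident`), `layer`,
#'   `justification`.
#' @export
classify_layer2 <- function(est_hit, annotation, ci_threshold = 95,
                            e_threshold = 1e-20) {
  decision <- function(cat, why) list(category = cat, layer = "2", justification = why)
  if (is.null(est_hit) || !nrow(est_hit) || is.null(annotation))
    return(decision("nonconfident", "no EST hit or annotation"))
  ci <- est_hit$total_ion_ci[1]
  ev <- annotation$evalue
  if (ci >= ci_threshold && ev <= e_threshold)
    return(decision("confident",
                    sprintf("total-ion C.I. %.1f%%, annotation E = %.2e", ci, ev)))
  decision("nonconfident",
           sprintf("total-ion C.I. %.1f%% or annotation E = %.2e outside thresholds",
                   ci, ev))
}
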