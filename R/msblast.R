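# Layer 3b: homology search over merged de novo candidates. Filtered
# candidates of all spectra of a spot are joined into one minus-separated
# query string and aligned gaplessly against every database protein with a
# mass-ambiguity tolerant matrix; retained high-scoring segment pairs
# (HSSPs) drive a count-based confidence call.

#' Assemble the merged homology-search query
#'
#' Joins all reliability-filtered candidates of all spectra of a spot into
#' one string separated by the minus symbol, keeping an invertible map from
#' string positions back to (spectrum, candidate rank).
#'
#' @param spot_candidates data.frame with columns `spectrum`, `rank`,
#'   `sequence` (filtered candidates; lowercase mod letters allowed, they
#'   are uppercased for alignment).
#' @return A `merged_query` list with `query` and `map` (data.frame
#'   `start`, `end`, `spectrum`, `rank`, `sequence`), or NULL when there is
#'   no passing candidate (spot labelled unknown downstream).
#' @export
assemble_query <- function(spot_candidates) {
  if (is.null(spot_candidates) || !nrow(spot_candidates)) return(NULL)
  seqs <- toupper(spot_candidates$sequence)
  len <- nchar(seqs)
  start <- cumsum(c(1L, utils::head(len + 1L, -1L)))
  structure(list(
    query = paste(seqs, collapse = "-"),
    map = data.frame(start = start, end = start + len - 1L,
                     spectrum = spot_candidates$spectrum,
                     rank = spot_candidates$rank, sequence = seqs)),
    class = "merged_query")
}

#' Map a query position back to its candidate
#'
#' @param query A `merged_query`.
#' @param pos 1-based position in the query string.
#' @return List with `spectrum`, `rank`, `offset` (1-based within the
#'   candidate); errors on a separator position.
#' @export
query_position <- function(query, pos) {
  hit <- which(query$map$start <= pos & query$map$end >= pos)
  if (!length(hit)) stop("position ", pos, " falls on a separator")
  r <- query$map[hit[1], ]
  list(spectrum = r$spectrum, rank = r$rank, offset = pos - r$start + 1L)
}

# all maximal-scoring segments of a numeric vector with score >= min_score,
# by recursive best-segment splitting (vectorised Kadane per level)
.maximal_segments <- function(x, min_score) {
  out <- list()
  rec <- function(lo, hi) {
    if (hi < lo) return()
    v <- x[lo:hi]
    cs <- cumsum(v)
    pre <- c(0, cs[-length(cs)])
    cmin <- cummin(pre)
    gains <- cs - cmin
    t <- which.max(gains)
    if (gains[t] < min_score) return()
    s <- which(pre[seq_len(t)] == cmin[t])[1]
    out[[length(out) + 1L]] <<- c(lo + s - 1L, lo + t - 1L, gains[t])
    rec(lo, lo + s - 2L)
    rec(lo + t, hi)
  }
  rec(1L, length(x))
  out
}

#' Gapless local alignment of a merged query against a protein database
#'
#' Enumerates, per subject, all maximal-scoring gapless segment pairs with
#' score at or above `min_score`, never crossing a `-` separator. Scores
#' are sums of substitution-matrix values over the aligned pairs.
#'
#' @param query A `merged_query` (see [assemble_query()]) or plain string
#'   (separators allowed).
#' @param proteins Named character vector or `AAStringSet`.
#' @param matrix Substitution matrix (default [msblast_matrix()]).
#' @param min_score Retention threshold for reported segments (default 30;
#'   the confidence cutoff proper is applied in [classify_homology()]).
#' @return data.frame of HSSPs: `accession`, `score`, `query_start`,
#'   `query_end`, `subject_start`, `subject_end`, `spectrum`, `rank`.
#' @export
align_gapless <- function(query, proteins, matrix = msblast_matrix(),
                          min_score = 30) {
  if (is.character(query)) {
    map <- NULL; qstr <- query
  } else { map <- query$map; qstr <- query$query }
  if (methods::is(proteins, "XStringSet"))
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  empty <- data.frame(accession = character(), score = numeric(),
                      query_start = integer(), query_end = integer(),
                      subject_start = integer(), subject_end = integer(),
                      spectrum = character(), rank = integer())
  q <- strsplit(toupper(qstr), "", fixed = TRUE)[[1]]
  n <- length(q)
  if (!n) return(empty)
  aa <- rownames(matrix)
  qcode <- match(q, aa)                    # NA at separators / unknowns
  sep <- is.na(qcode) & q != "X"
  qcode[is.na(qcode)] <- match("X", aa)
  acc_v <- character(); num_v <- list()
  for (j in seq_along(proteins)) {
    subj <- gsub("[^A-Z]", "", toupper(proteins[[j]]))
    t <- strsplit(subj, "", fixed = TRUE)[[1]]
    m <- length(t)
    if (!m) next
    tcode <- match(t, aa)
    tcode[is.na(tcode)] <- match("X", aa)
    S <- matrix[cbind(rep(qcode, times = m), rep(tcode, each = n))]
    dim(S) <- c(n, m)
    S[sep, ] <- -Inf
    for (d in (-(m - 1L)):(n - 1L)) {       # d = qpos - tpos
      i0 <- max(1L, d + 1L); i1 <- min(n, m + d)
      if (i1 < i0) next
      iv <- i0:i1
      vals <- S[cbind(iv, iv - d)]
      # split at separators, scan each piece
      fin <- is.finite(vals)
      if (!any(fin)) next
      runs <- rle(fin)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (r in which(runs$values)) {
        piece <- vals[starts[r]:ends[r]]
        segs <- .maximal_segments(piece, min_score)
        for (sg in segs) {
          qs <- iv[1] + starts[r] - 1L + sg[1] - 1L
          qe <- iv[1] + starts[r] - 1L + sg[2] - 1L
          acc_v <- c(acc_v, names(proteins)[j])
          num_v[[length(num_v) + 1L]] <- c(sg[3], qs, qe, qs - d, qe - d)
        }
      }
    }
  }
  if (!length(num_v)) return(empty)
  nm <- do.call(rbind, num_v)
  out <- data.frame(accession = acc_v, score = nm[, 1],
                    query_start = as.integer(nm[, 2]),
                    query_end = as.integer(nm[, 3]),
                    subject_start = as.integer(nm[, 4]),
                    subject_end = as.integer(nm[, 5]),
                    spectrum = NA_character_, rank = NA_integer_)
  if (!is.null(map)) {
    idx <- vapply(out$query_start, function(p)
      which(map$start <= p & map$end >= p)[1], 0L)
    out$spectrum <- as.character(map$spectrum[idx])
    out$rank <- map$rank[idx]
  }
  out <- out[order(out$accession, -out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a homology-search result
#'
#' Discards HSSPs below the confidence threshold (62, inclusive), groups
#' the survivors by subject, and picks the best subject by the count of
#' retained HSSPs from distinct MS/MS spectra (ties by summed score, then
#' by an optional taxon-priority table, then alphabetically). Two or more
#' distinct-spectrum HSSPs make the call confident, exactly one borderline.
#'
#' @param hssps [align_gapless()] output.
#' @param threshold Retention score, inclusive (default 62).
#' @param taxon_priority Optional data.frame (`accession`, `priority`,
#'   smaller = phylogenetically closer) used as a tie-break.
#' @return List with `category` (`confident`/`borderline`/`none`),
#'   `accession`, `n_hssp` (distinct-spectrum count), `best_score`,
#'   `hssps` (retained rows for the best subject).
#' @export
classify_homology <- function(hssps, threshold = 62, taxon_priority = NULL) {
  none <- list(category = "none", accession = NA_character_, n_hssp = 0L,
               best_score = NA_real_, hssps = hssps[0, ])
  if (is.null(hssps) || !nrow(hssps)) return(none)
  keep <- hssps[hssps$score >= threshold, , drop = FALSE]
  if (!nrow(keep)) return(none)
  spl <- split(keep, keep$accession)
  stats_df <- do.call(rbind, lapply(spl, function(g) {
    spec <- g$spectrum
    # duplicate HSSPs from one spectrum count once; unmapped spectra are
    # conservatively collapsed to a single piece of evidence
    nsp <- if (all(is.na(spec))) 1L else length(unique(spec[!is.na(spec)]))
    data.frame(accession = g$accession[1], n = nsp, total = sum(g$score),
               best = max(g$score))
  }))
  if (!is.null(taxon_priority)) {
    pr <- taxon_priority$priority[match(stats_df$accession,
                                        taxon_priority$accession)]
    stats_df$prio <- ifelse(is.na(pr), Inf, pr)
  } else stats_df$prio <- Inf
  ord <- order(-stats_df$n, -stats_df$total, stats_df$prio,
               stats_df$accession)
  top <- stats_df[ord[1], ]
  list(category = if (top$n >= 2L) "confident" else "borderline",
       accession = top$accession, n_hssp = top$n, best_score = top$best,
       hssps = keep[keep$accession == top$accession, , drop = FALSE])
}

#' Write merged queries as FASTA
#'
#' @param queries Named list of `merged_query` objects (names become FASTA
#'   headers).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_query_fasta <- function(queries, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(queries)) {
    writeLines(paste0(">", nm), con)
    writeLines(queries[[nm]]$query, con)
  }
  invisible(path)
}
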