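# Peak-list data model and the software-side acquisition filters applied to
# centroided MALDI spot data before any search layer sees it.

#' Construct a peak list
#'
#' @param mz,intensity Numeric vectors; m/z must be positive, intensity
#'   non-negative.
#' @param sn Optional per-peak signal-to-noise estimates.
#' @param charge Optional integer charge annotations (MALDI default 1).
#' @return data.frame sorted ascending by m/z with columns `mz`, `intensity`
#'   and, when supplied, `sn` and `charge`.
#' @export
peak_list <- function(mz, intensity, sn = NULL, charge = NULL) {
  stopifnot(length(mz) == length(intensity), all(mz > 0), all(intensity >= 0))
  df <- data.frame(mz = mz, intensity = intensity)
  if (!is.null(sn)) df$sn <- sn
  if (!is.null(charge)) df$charge <- as.integer(charge)
  df[order(df$mz), , drop = FALSE]
}

#' Construct a spot
#'
#' A spot is the routing unit of the pipeline: one MS peak list (the PMF)
#' plus its associated MS/MS spectra.
#'
#' @param id Spot identifier.
#' @param ms MS [peak_list()].
#' @param msms List of MS/MS spectra, each a list with elements `precursor`
#'   (m/z) and `peaks` (a [peak_list()]).
#' @return A `spot` object.
#' @export
spot <- function(id, ms, msms = list()) {
  if (is.unsorted(ms$mz)) ms <- ms[order(ms$mz), , drop = FALSE]
  structure(list(id = as.character(id), ms = ms, msms = msms), class = "spot")
}

#' @export
print.spot <- function(x, ...) {
  cat(sprintf("<spot %s: %d MS peaks, %d MS/MS spectra>\n",
              x$id, nrow(x$ms), length(x$msms)))
  invisible(x)
}

# ---- MGF I/O ---------------------------------------------------------------

#' Read spots from a Mascot generic format file
#'
#' Each `BEGIN IONS` block must carry `TITLE` and `PEPMASS`. Titles follow
#' the convention written by [write_mgf()]: `spot=<id> kind=<ms|msms>` with
#' an `index=` field for MS/MS blocks. Peak lines are whitespace-separated
#' `m/z intensity [third]`, the third column being S/N for MS blocks and
#' charge for MS/MS blocks.
#'
#' @param path MGF file path.
#' @return List of [spot()] objects (empty file gives an empty list).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  spots <- list()
  i <- 1L; n <- length(lines)
  parse_fail <- function(ln, msg) stop(sprintf("%s:%d: %s", path, ln, msg), call. = FALSE)
  while (i <= n) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) { i <- i + 1L; next }
    if (line != "BEGIN IONS") parse_fail(i, "expected BEGIN IONS")
    begin_ln <- i
    title <- NA_character_; pepmass <- NA_real_
    mzv <- c(); intv <- c(); thirdv <- c()
    i <- i + 1L
    ended <- FALSE
    while (i <= n) {
      line <- trimws(lines[i])
      if (line == "END IONS") { ended <- TRUE; i <- i + 1L; break }
      if (grepl("^TITLE=", line)) {
        title <- sub("^TITLE=", "", line)
      } else if (grepl("^PEPMASS=", line)) {
        pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", line), "\\s+")[[1]][1])
      } else if (grepl("^[A-Z]+=", line)) {
        # other headers (CHARGE, SCANS, ...) tolerated
      } else if (line != "") {
        f <- suppressWarnings(as.numeric(strsplit(line, "\\s+")[[1]]))
        if (length(f) < 2L || anyNA(f[1:2])) parse_fail(i, "malformed peak line")
        mzv <- c(mzv, f[1]); intv <- c(intv, f[2])
        thirdv <- c(thirdv, if (length(f) >= 3L) f[3] else NA_real_)
      }
      i <- i + 1L
    }
    if (!ended) parse_fail(begin_ln, "BEGIN IONS without END IONS")
    if (is.na(title)) parse_fail(begin_ln, "block missing TITLE")
    if (is.na(pepmass)) parse_fail(begin_ln, "block missing PEPMASS")
    sid <- sub(".*spot=(\\S+).*", "\\1", title)
    kind <- if (grepl("kind=ms($|\\s)", title)) "ms" else "msms"
    if (is.null(spots[[sid]]))
      spots[[sid]] <- list(id = sid,
                           ms = data.frame(mz = numeric(0), intensity = numeric(0)),
                           msms = list())
    if (kind == "ms") {
      pl <- peak_list(mzv, intv, sn = if (all(is.na(thirdv))) NULL else thirdv)
      spots[[sid]]$ms <- pl
    } else {
      pl <- peak_list(mzv, intv,
                      charge = if (all(is.na(thirdv))) NULL else as.integer(thirdv))
      spots[[sid]]$msms[[length(spots[[sid]]$msms) + 1L]] <-
        list(precursor = pepmass, peaks = pl)
    }
  }
  lapply(unname(spots), function(s) spot(s$id, s$ms, s$msms))
}

#' Write spots to a Mascot generic format file
#'
#' @param spots List of [spot()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spots, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.5f", x)
  for (s in spots) {
    if (nrow(s$ms)) {
      writeLines(c("BEGIN IONS",
                   sprintf("TITLE=spot=%s kind=ms", s$id),
                   "PEPMASS=0.0"), con)
      third <- if ("sn" %in% names(s$ms)) fmt(s$ms$sn) else NULL
      lines <- paste(fmt(s$ms$mz), fmt(s$ms$intensity))
      if (!is.null(third)) lines <- paste(lines, third)
      writeLines(lines, con)
      writeLines("END IONS", con)
    }
    for (k in seq_along(s$msms)) {
      sp <- s$msms[[k]]
      writeLines(c("BEGIN IONS",
                   sprintf("TITLE=spot=%s kind=msms index=%d", s$id, k),
                   sprintf("PEPMASS=%s", fmt(sp$precursor)),
                   "CHARGE=1+"), con)
      third <- if ("charge" %in% names(sp$peaks)) as.character(sp$peaks$charge) else NULL
      lines <- paste(fmt(sp$peaks$mz), fmt(sp$peaks$intensity))
      if (!is.null(third)) lines <- paste(lines, third)
      writeLines(lines, con)
      writeLines("END IONS", con)
    }
  }
  invisible(path)
}

# ---- filters ---------------------------------------------------------------

#' Estimate signal-to-noise from local context
#'
#' Stand-in used when the instrument's S/N is absent: each peak's noise level
#' is the median intensity of the peaks inside a 200-Da window centred on it.
#'
#' @param peaks Peak data.frame.
#' @param window Window width in Da (default 200).
#' @return Numeric S/N vector.
#' @export
estimate_snr <- function(peaks, window = 200) {
  half <- window / 2
  vapply(seq_len(nrow(peaks)), function(i) {
    sel <- abs(peaks$mz - peaks$mz[i]) <= half
    noise <- stats::median(peaks$intensity[sel])
    if (noise <= 0) Inf else peaks$intensity[i] / noise
  }, 0)
}

#' Filter an MS peak list
#'
#' Applies, in order: the mass-range gate, the minimum S/N gate, a peak
#' density cap (at most `density_n` peaks inside any window of
#' `density_window` Da, keeping the most intense), and a global cap of
#' `max_peaks` most intense peaks. Output is re-sorted by m/z.
#'
#' @param peaks Peak data.frame sorted by m/z.
#' @param mass_range Length-2 numeric, default `c(850, 4000)` Da.
#' @param min_sn Minimum S/N, default 10. Peaks without S/N use
#'   [estimate_snr()].
#' @param density_n,density_window Density cap: default 50 peaks per 200 Da.
#' @param max_peaks Global cap, default 65.
#' @return Filtered peak data.frame.
#' @export
filter_ms_peaks <- function(peaks, mass_range = c(850, 4000), min_sn = 10,
                            density_n = 50, density_window = 200,
                            max_peaks = 65) {
  keep <- peaks$mz >= mass_range[1] & peaks$mz <= mass_range[2]
  peaks <- peaks[keep, , drop = FALSE]
  if (!nrow(peaks)) return(peaks)
  sn <- if ("sn" %in% names(peaks) && !all(is.na(peaks$sn))) peaks$sn
        else estimate_snr(peaks)
  peaks <- peaks[!is.na(sn) & sn >= min_sn, , drop = FALSE]
  if (!nrow(peaks)) return(peaks)
  # density cap: greedy acceptance in decreasing intensity; a peak is
  # rejected if some 200-Da window containing it already holds density_n
  ord <- order(-peaks$intensity, peaks$mz)
  accepted <- numeric(0)
  acc_idx <- integer(0)
  for (i in ord) {
    p <- peaks$mz[i]
    near <- sort(accepted[abs(accepted - p) <= density_window])
    ok <- TRUE
    if (length(near) >= density_n) {
      for (j in seq_len(length(near) - density_n + 1L)) {
        lo <- min(near[j], p); hi <- max(near[j + density_n - 1L], p)
        if (hi - lo <= density_window) { ok <- FALSE; break }
      }
    }
    if (ok) { accepted <- c(accepted, p); acc_idx <- c(acc_idx, i) }
  }
  peaks <- peaks[sort(acc_idx), , drop = FALSE]
  if (nrow(peaks) > max_peaks) {
    ord <- order(-peaks$intensity, peaks$mz)[seq_len(max_peaks)]
    peaks <- peaks[sort(ord), , drop = FALSE]
  }
  peaks[order(peaks$mz), , drop = FALSE]
}

#' Built-in contaminant exclusion list
#'
#' Canonical singly protonated m/z values of human keratin tryptic peptides,
#' trypsin autolysis products, and CHCA matrix clusters, each at a 0.1 Da
#' tolerance. Fully user-overridable via [read_exclusion_list()].
#'
#' @return data.frame with columns `mz`, `tol`, `label`.
#' @export
default_exclusion_list <- function() {
  data.frame(
    mz = c(842.5100, 1045.5642, 2211.1046, 2225.1190,          # trypsin
           1066.4300, 1179.6010, 1300.5302, 1475.7850,          # keratin
           1716.8517, 1993.9772, 2383.9520,
           946.2200, 1135.2600),                                # CHCA clusters
    tol = 0.1,
    label = c(rep("trypsin-autolysis", 4), rep("keratin", 7), rep("matrix", 2))
  )
}

#' Read an exclusion list from a text table
#'
#' Two or three whitespace-separated columns (`m/z`, `tolerance`, optional
#' `label`), `#` comments allowed.
#'
#' @param path File path.
#' @return data.frame with columns `mz`, `tol`, `label`.
#' @export
read_exclusion_list <- function(path) {
  df <- utils::read.table(path, comment.char = "#", header = FALSE,
                          col.names = c("mz", "tol", "label")[1:3],
                          fill = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L || all(is.na(df[[3]]))) df$label <- "user"
  stopifnot(all(df$tol > 0))
  df[, c("mz", "tol", "label")]
}

#' Select MS/MS precursors from an MS peak list
#'
#' Removes exclusion-list contaminants, requires a minimum S/N (peaks with
#' no S/N annotation pass), and returns the `top_n` most intense survivors
#' in descending intensity order.
#'
#' @param ms_peaks MS peak data.frame.
#' @param exclusion Exclusion data.frame (see [default_exclusion_list()]).
#' @param top_n Maximum precursors, default 20.
#' @param min_sn Minimum S/N, default 50.
#' @return Numeric vector of precursor m/z values.
#' @export
select_precursors <- function(ms_peaks, exclusion = default_exclusion_list(),
                              top_n = 20, min_sn = 50) {
  if (!nrow(ms_peaks)) return(numeric(0))
  excluded <- rep(FALSE, nrow(ms_peaks))
  for (r in seq_len(nrow(exclusion)))
    excluded <- excluded | abs(ms_peaks$mz - exclusion$mz[r]) <= exclusion$tol[r]
  ok <- !excluded
  if ("sn" %in% names(ms_peaks)) ok <- ok & (is.na(ms_peaks$sn) | ms_peaks$sn >= min_sn)
  cand <- ms_peaks[ok, , drop = FALSE]
  cand <- cand[order(-cand$intensity, cand$mz), , drop = FALSE]
  utils::head(cand$mz, top_n)
}

#' Deconvolute a peak list to singly charged species
#'
#' MALDI spectra are assumed singly charged, so unannotated peaks pass
#' unchanged; peaks annotated with charge z > 1 are transformed to the mass
#' of the singly protonated species, `z*mz - (z-1)*proton`.
#'
#' @param peaks Peak data.frame, optionally with a `charge` column.
#' @return Peak data.frame, all charges 1, re-sorted by m/z.
#' @export
deconvolute_to_singly_charged <- function(peaks) {
  if (!"charge" %in% names(peaks)) {
    peaks$charge <- 1L
    return(peaks[order(peaks$mz), , drop = FALSE])
  }
  z <- ifelse(is.na(peaks$charge) | peaks$charge < 1L, 1L, peaks$charge)
  peaks$mz <- z * peaks$mz - (z - 1L) * .MASS_PROTON
  peaks$charge <- 1L
  peaks[order(peaks$mz), , drop = FALSE]
}
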