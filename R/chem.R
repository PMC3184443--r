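# Monoisotopic masses of the 20 standard residues and the small-molecule
# constants everything downstream is built from. All values in Da.

.MASS_WATER   <- 18.010565
.MASS_PROTON  <- 1.007276
.MASS_AMMONIA <- 17.026549
.MASS_CO      <- 27.994915

.RESIDUE_MASSES <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Monoisotopic residue masses
#'
#' Named vector of monoisotopic residue (not free amino acid) masses for the
#' 20 standard amino acids. Isoleucine and leucine share a mass; lysine and
#' glutamine differ by 0.03638 Da, less than the 0.08 Da fragment tolerance
#' used throughout, which is what makes K/Q calls ambiguous in de novo
#' interpretation.
#'
#' @return Named numeric vector, residue letter to mass in Da.
#' @export
amino_acid_masses <- function() .RESIDUE_MASSES

#' Mass constants
#'
#' @return Named numeric vector with elements `water`, `proton`, `ammonia`
#'   and `co` (all monoisotopic, Da).
#' @export
mass_constants <- function() {
  c(water = .MASS_WATER, proton = .MASS_PROTON,
    ammonia = .MASS_AMMONIA, co = .MASS_CO)
}

#' Modification specifications
#'
#' A modification is a named mass delta targeting one residue, applied either
#' unconditionally (`fixed`) or enumerated combinatorially (`variable`).
#'
#' @param name Modification name.
#' @param target Single residue letter.
#' @param delta Mass delta in Da.
#' @param mode `"fixed"` or `"variable"`.
#' @return A `modification_spec` list.
#' @export
modification_spec <- function(name, target, delta, mode = c("fixed", "variable")) {
  mode <- match.arg(mode)
  stopifnot(nchar(target) == 1L, is.numeric(delta))
  structure(list(name = name, target = target, delta = delta, mode = mode),
            class = "modification_spec")
}

#' Default modification set
#'
#' Carbamidomethylation of cysteine as the fixed modification (iodoacetamide
#' alkylation during gel processing) and methionine oxidation as the variable
#' modification.
#'
#' @return List of [modification_spec()] objects.
#' @export
default_modifications <- function() {
  list(
    modification_spec("Carbamidomethyl", "C", 57.021464, "fixed"),
    modification_spec("Oxidation", "M", 15.994915, "variable")
  )
}

.check_modlist <- function(mods) {
  if (length(mods) == 0L) return(invisible(mods))
  key <- vapply(mods, function(m) paste(m$target, m$name), "")
  fixed <- vapply(mods, function(m) m$mode == "fixed", TRUE)
  if (anyDuplicated(key[fixed]) || any(key[fixed] %in% key[!fixed]))
    stop("fixed and variable modifications must target disjoint (residue, name) pairs")
  invisible(mods)
}

#' Construct a peptide
#'
#' @param sequence Residue letters (uppercase).
#' @param mods Optional data.frame with columns `pos` (1-based), `name`,
#'   `delta` giving site-localised modifications.
#' @param missed Missed-cleavage count.
#' @param protein,start,end Optional provenance: source accession and 1-based
#'   inclusive coordinates.
#' @return A `peptide` list.
#' @export
peptide <- function(sequence, mods = NULL, missed = 0L,
                    protein = NA_character_, start = NA_integer_, end = NA_integer_) {
  if (!nzchar(sequence)) stop("empty peptide sequence")
  letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(letters %in% names(.RESIDUE_MASSES)))
    stop("unknown residue letter in sequence: ",
         paste(setdiff(letters, names(.RESIDUE_MASSES)), collapse = ","))
  if (is.null(mods))
    mods <- data.frame(pos = integer(), name = character(), delta = numeric())
  if (nrow(mods) && (any(mods$pos < 1L) || any(mods$pos > length(letters))))
    stop("modification position outside sequence")
  structure(list(sequence = sequence, mods = mods, missed = as.integer(missed),
                 protein = protein, start = start, end = end),
            class = "peptide")
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus modification deltas plus one water.
#'
#' @param pep A [peptide()] or plain character sequence.
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(pep) {
  if (is.character(pep)) pep <- peptide(pep)
  letters <- strsplit(pep$sequence, "", fixed = TRUE)[[1]]
  sum(.RESIDUE_MASSES[letters]) + sum(pep$mods$delta) + .MASS_WATER
}

#' Singly protonated peptide mass (M+H)+
#' @param pep A [peptide()] or character sequence.
#' @return m/z of the singly protonated peptide.
#' @export
peptide_mh <- function(pep) peptide_mass(pep) + .MASS_PROTON

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P, and emits
#' every peptide with at most `max_missed` internal (uncut) cleavage sites.
#' Coordinates are 1-based inclusive on the protein.
#'
#' @param protein_sequence Amino-acid string; empty input gives an empty set.
#' @param max_missed Maximum internal missed cleavages (>= 0).
#' @param accession Optional accession recorded on each peptide.
#' @return data.frame with columns `sequence`, `start`, `end`, `missed`.
#' @export
digest_protein <- function(protein_sequence, max_missed = 1L, accession = NA_character_) {
  stopifnot(max_missed >= 0L)
  n <- nchar(protein_sequence)
  empty <- data.frame(sequence = character(), start = integer(),
                      end = integer(), missed = integer(),
                      accession = character())
  if (n == 0L) return(empty)
  aa <- strsplit(protein_sequence, "", fixed = TRUE)[[1]]
  # cut after position i when aa[i] is K/R and aa[i+1] is not P
  cuts <- which(aa[-n] %in% c("K", "R") & aa[-1L] != "P")
  bounds <- c(0L, cuts, n)               # segment boundaries
  ns <- length(bounds) - 1L
  out <- vector("list", 0L)
  for (i in seq_len(ns)) {
    for (j in i:min(ns, i + max_missed)) {
      s <- bounds[i] + 1L; e <- bounds[j + 1L]
      out[[length(out) + 1L]] <- c(s, e, j - i)
    }
  }
  m <- do.call(rbind, out)
  data.frame(
    sequence = substring(protein_sequence, m[, 1], m[, 2]),
    start = m[, 1], end = m[, 2], missed = m[, 3],
    accession = accession
  )
}

#' Enumerate modified forms of a peptide
#'
#' Applies fixed modifications unconditionally and enumerates variable
#' modifications combinatorially up to `max_variable` sites per peptide.
#'
#' @param sequence Peptide sequence.
#' @param mods List of [modification_spec()]s.
#' @param max_variable Cap on simultaneous variable sites (default 2).
#' @return data.frame with columns `sequence`, `mod_string` (e.g.
#'   `"3:Oxidation"`, `""` if none beyond fixed), `delta` (total mod delta)
#'   and `n_variable`.
#' @export
enumerate_modifications <- function(sequence, mods = default_modifications(),
                                    max_variable = 2L) {
  .check_modlist(mods)
  letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  fixed_delta <- 0
  fixed_str <- character()
  var_sites <- list()
  for (m in mods) {
    pos <- which(letters == m$target)
    if (!length(pos)) next
    if (m$mode == "fixed") {
      fixed_delta <- fixed_delta + length(pos) * m$delta
      fixed_str <- c(fixed_str, paste0(pos, ":", m$name))
    } else {
      for (p in pos) var_sites[[length(var_sites) + 1L]] <- list(pos = p, m = m)
    }
  }
  combos <- list(integer(0))
  nv <- length(var_sites)
  if (nv) {
    for (k in seq_len(min(max_variable, nv)))
      combos <- c(combos, utils::combn(nv, k, simplify = FALSE))
  }
  res <- lapply(combos, function(idx) {
    vd <- sum(vapply(var_sites[idx], function(v) v$m$delta, 0))
    vs <- vapply(var_sites[idx], function(v) paste0(v$pos, ":", v$m$name), "")
    data.frame(sequence = sequence,
               mod_string = paste(c(fixed_str, vs), collapse = ";"),
               delta = fixed_delta + vd,
               n_variable = length(idx))
  })
  do.call(rbind, res)
}

.SERIES_ALL <- c("b", "y", "a", "b-H2O", "b-NH3", "y-H2O", "y-NH3",
                 "immonium", "internal")

#' Theoretical fragment ions
#'
#' Generates singly protonated m/z values for the requested ion series of a
#' peptide: the b/y ladders, a-ions (b minus CO), water and ammonia neutral
#' losses of b and y, immonium ions (residue minus CO plus proton, one per
#' distinct residue), and internal b-type fragments (contiguous interior
#' subsequences, length capped to bound cost).
#'
#' @param pep A [peptide()] or character sequence.
#' @param series Character vector drawn from
#'   `c("b","y","a","b-H2O","b-NH3","y-H2O","y-NH3","immonium","internal")`.
#' @param max_internal Maximum internal-fragment length (default 5).
#' @return data.frame with columns `series`, `ordinal`, `mz`.
#' @export
fragment_ions <- function(pep, series = c("b", "y", "a", "b-H2O", "b-NH3",
                                          "y-H2O", "y-NH3", "immonium"),
                          max_internal = 5L) {
  if (is.character(pep)) pep <- peptide(pep)
  bad <- setdiff(series, .SERIES_ALL)
  if (length(bad)) stop("unknown ion series: ", paste(bad, collapse = ","))
  letters <- strsplit(pep$sequence, "", fixed = TRUE)[[1]]
  n <- length(letters)
  if (n == 0L) stop("empty peptide")
  res <- .RESIDUE_MASSES[letters]
  if (nrow(pep$mods)) {
    for (r in seq_len(nrow(pep$mods)))
      res[pep$mods$pos[r]] <- res[pep$mods$pos[r]] + pep$mods$delta[r]
  }
  pre <- cumsum(res)                     # prefix residue-mass sums
  total <- pre[n]
  out <- list()
  add <- function(s, ord, mz) out[[length(out) + 1L]] <<-
      data.frame(series = s, ordinal = ord, mz = unname(mz))
  if (n >= 2L) {
    bi <- pre[-n] + .MASS_PROTON
    yi <- (total - pre[-n])[(n - 1L):1L] + .MASS_WATER + .MASS_PROTON
    ord <- seq_len(n - 1L)
    if ("b" %in% series) add("b", ord, bi)
    if ("y" %in% series) add("y", ord, yi)
    if ("a" %in% series) add("a", ord, bi - .MASS_CO)
    if ("b-H2O" %in% series) add("b-H2O", ord, bi - .MASS_WATER)
    if ("b-NH3" %in% series) add("b-NH3", ord, bi - .MASS_AMMONIA)
    if ("y-H2O" %in% series) add("y-H2O", ord, yi - .MASS_WATER)
    if ("y-NH3" %in% series) add("y-NH3", ord, yi - .MASS_AMMONIA)
  }
  if ("immonium" %in% series) {
    u <- !duplicated(letters)
    add("immonium", match(letters[u], letters), res[u] - .MASS_CO + .MASS_PROTON)
  }
  if ("internal" %in% series && n >= 3L) {
    for (i in 2:(n - 1L)) {
      jmax <- min(n - 1L, i + max_internal - 1L)
      for (j in i:jmax) {
        mz <- sum(res[i:j]) + .MASS_PROTON
        add("internal", i, mz)
      }
    }
  }
  if (!length(out))
    return(data.frame(series = character(), ordinal = integer(), mz = numeric()))
  do.call(rbind, out)
}

#' Read a protein FASTA with accession parsing
#'
#' @param path FASTA path.
#' @return Named `AAStringSet`; names are the first whitespace-delimited
#'   token of each description line, full descriptions kept in
#'   `attr(,"descriptions")` (named by accession).
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  full <- names(x)
  acc <- sub("\\s.*$", "", full)
  desc <- sub("^\\S+\\s*", "", full)
  names(x) <- acc
  attr(x, "descriptions") <- stats::setNames(desc, acc)
  x
}
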