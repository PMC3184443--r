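# Orchestration of the three identification layers, per-spot reporting and
# study-level summaries. Layer precedence is strict: the first layer that
# produces a confident call wins and later layers are not consulted, except
# that layer 3 evidence can corroborate ("validate") a layer-1 borderline
# hit on the same subject.

#' Pipeline configuration
#'
#' @param protein_db Protein FASTA path or `AAStringSet` (layer 1 and the
#'   homology-search database of layer 3).
#' @param est_db Nucleotide FASTA path or `DNAStringSet` (layer 2), may be
#'   NULL.
#' @param annotation_db Protein FASTA path or `AAStringSet` used to
#'   annotate matched ESTs (defaults to `protein_db`).
#' @param taxon_map,function_map Optional two-column data.frames
#'   (`accession`, `group` / `category`) or TSV paths.
#' @param search [search_config()].
#' @param denovo [denovo_config()].
#' @param hssp_threshold HSSP confidence cutoff, inclusive (default 62).
#' @param ci_threshold Confidence-interval bar in percent (default 95).
#' @param e_threshold Layer-2 annotation E-value bar (default 1e-20).
#' @param taxon_priority Optional tie-break table for [classify_homology()].
#' @param seed Seed recorded in report headers.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(protein_db, est_db = NULL, annotation_db = NULL,
                            taxon_map = NULL, function_map = NULL,
                            search = search_config(), denovo = denovo_config(),
                            hssp_threshold = 62, ci_threshold = 95,
                            e_threshold = 1e-20, taxon_priority = NULL,
                            seed = NA_integer_) {
  load_aa <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1L && file.exists(x))
      read_protein_fasta(x)
    else x
  }
  load_nt <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      y <- Biostrings::readDNAStringSet(x)
      names(y) <- sub("\\s.*$", "", names(y))
      y
    } else x
  }
  load_map <- function(x, col) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      df <- utils::read.table(x, sep = "\t", header = FALSE,
                              col.names = c("accession", col),
                              stringsAsFactors = FALSE, comment.char = "#",
                              quote = "")
      df
    } else x
  }
  protein_db <- load_aa(protein_db)
  if (is.null(protein_db) || !length(protein_db)) stop("protein database required")
  structure(list(
    protein_db = protein_db, est_db = load_nt(est_db),
    annotation_db = if (is.null(annotation_db)) protein_db else load_aa(annotation_db),
    taxon_map = load_map(taxon_map, "group"),
    function_map = load_map(function_map, "category"),
    search = search, denovo = denovo, hssp_threshold = hssp_threshold,
    ci_threshold = ci_threshold, e_threshold = e_threshold,
    taxon_priority = taxon_priority, seed = seed), class = "pipeline_config")
}

.empty_report_row <- function(id) {
  data.frame(spot = id, layer = "none", category = "unknown",
             validated = FALSE, accession = NA_character_,
             description = NA_character_, protein_score = NA_real_,
             protein_ci = NA_real_, total_ion_score = NA_real_,
             total_ion_ci = NA_real_, n_peptides = NA_integer_,
             n_sig_peptides = NA_integer_, n_hssp = NA_integer_,
             best_hssp = NA_real_, justification = "no layer produced a hit")
}

#' Run the layered identification pipeline
#'
#' Each spot is routed layer 1 (protein database) to layer 2 (translated
#' ESTs plus annotation) to layer 3 (de novo plus gapless homology search);
#' the first confident layer wins. Layer-1 borderline hits corroborated by
#' layer-3 HSSPs on the same subject are flagged validated. Spots failing
#' every layer are reported unknown.
#'
#' @param spots List of [spot()] objects (or an MGF path).
#' @param config [pipeline_config()].
#' @param verbose Emit one log line per spot (default FALSE).
#' @return data.frame of per-spot reports (one row per spot), with the
#'   per-spot evidence lists in `attr(,"evidence")`.
#' @export
run_pipeline <- function(spots, config, verbose = FALSE) {
  if (is.character(spots) && length(spots) == 1L) spots <- read_mgf(spots)
  prot_index <- build_peptide_index(config$protein_db, config$search)
  est_index <- NULL
  est_seqs <- NULL
  if (!is.null(config$est_db) && length(config$est_db)) {
    frames <- six_frame_translate(config$est_db)
    est_index <- build_est_index(frames, config$search)
    est_seqs <- stats::setNames(as.character(config$est_db),
                                names(config$est_db))
  }
  kparams <- karlin_params(blosum62())
  ann_cache <- new.env(parent = emptyenv())
  rows <- vector("list", length(spots))
  evidence <- vector("list", length(spots))
  for (i in seq_along(spots)) {
    spt <- spots[[i]]
    spt$ms <- filter_ms_peaks(spt$ms)
    log_steps <- character()
    # ---- layer 1
    hits1 <- search_spot(spt, prot_index, config$search)
    dec1 <- classify_layer1(hits1[1, , drop = FALSE], config$ci_threshold)
    log_steps <- c(log_steps, paste("layer1:", dec1$category))
    row <- NULL
    if (dec1$category == "confident") {
      h <- hits1[1, ]
      row <- data.frame(spot = spt$id, layer = "1", category = "confident",
                        validated = FALSE, accession = h$accession,
                        description = h$description,
                        protein_score = h$protein_score, protein_ci = h$protein_ci,
                        total_ion_score = h$total_ion_score,
                        total_ion_ci = h$total_ion_ci,
                        n_peptides = h$n_peptides,
                        n_sig_peptides = h$n_sig_peptides,
                        n_hssp = NA_integer_, best_hssp = NA_real_,
                        justification = dec1$justification)
    }
    # ---- layer 2
    if (is.null(row) && !is.null(est_index)) {
      hits2 <- search_est(spt, est_index, config$search)
      if (nrow(hits2) && hits2$total_ion_ci[1] >= config$ci_threshold) {
        h <- hits2[1, ]
        est_id <- sub("\\|[^|]*$", "", h$accession)
        ann <- get0(est_id, envir = ann_cache, inherits = FALSE)
        if (is.null(ann)) {
          ann <- annotate_blastx(stats::setNames(est_seqs[est_id], est_id),
                                 config$annotation_db, params = kparams)
          assign(est_id, ann, envir = ann_cache)
        }
        dec2 <- classify_layer2(h, ann, config$ci_threshold, config$e_threshold)
        log_steps <- c(log_steps, paste("layer2:", dec2$category))
        if (dec2$category == "confident") {
          row <- data.frame(spot = spt$id, layer = "2", category = "EST-confident",
                            validated = FALSE, accession = h$accession,
                            description = sprintf("EST similar to %s (E=%.2e)",
                                                  ann$accession, ann$evalue),
                            protein_score = h$protein_score,
                            protein_ci = h$protein_ci,
                            total_ion_score = h$total_ion_score,
                            total_ion_ci = h$total_ion_ci,
                            n_peptides = h$n_peptides,
                            n_sig_peptides = h$n_sig_peptides,
                            n_hssp = NA_integer_, best_hssp = NA_real_,
                            justification = dec2$justification)
        }
      } else log_steps <- c(log_steps, "layer2: nonconfident")
    }
    # ---- layer 3
    if (is.null(row)) {
      cand_rows <- list()
      for (si in seq_along(spt$msms)) {
        dn <- denovo_spectrum(spt$msms[[si]], config$denovo)
        dn <- dn[dn$passes_filter, , drop = FALSE]
        if (nrow(dn))
          cand_rows[[length(cand_rows) + 1L]] <-
            data.frame(spectrum = si, rank = dn$rank, sequence = dn$sequence)
      }
      cands <- if (length(cand_rows)) do.call(rbind, cand_rows) else NULL
      mq <- assemble_query(cands)
      hdec <- if (is.null(mq)) classify_homology(NULL) else
        classify_homology(align_gapless(mq, config$protein_db,
                                        min_score = config$hssp_threshold),
                          config$hssp_threshold, config$taxon_priority)
      log_steps <- c(log_steps, paste("layer3:", hdec$category))
      l1_borderline <- dec1$category == "borderline" && nrow(hits1)
      corroborates <- l1_borderline && !is.na(hdec$accession) &&
        identical(hdec$accession, hits1$accession[1])
      if (hdec$category %in% c("confident", "borderline")) {
        cat3 <- if (hdec$category == "confident" || corroborates)
          "tentative-homology" else "borderline"
        desc <- if (!is.null(attr(config$protein_db, "descriptions")))
          unname(attr(config$protein_db, "descriptions")[hdec$accession])
        else NA_character_
        row <- data.frame(spot = spt$id, layer = "3", category = cat3,
                          validated = corroborates,
                          accession = hdec$accession, description = desc,
                          protein_score = NA_real_, protein_ci = NA_real_,
                          total_ion_score = NA_real_, total_ion_ci = NA_real_,
                          n_peptides = NA_integer_, n_sig_peptides = NA_integer_,
                          n_hssp = hdec$n_hssp, best_hssp = hdec$best_score,
                          justification = sprintf(
                            "%d distinct-spectrum HSSP(s) >= threshold%s",
                            hdec$n_hssp,
                            if (corroborates) "; corroborates layer-1 borderline hit"
                            else ""))
        evidence[[i]] <- hdec$hssps
      } else if (l1_borderline) {
        h <- hits1[1, ]
        row <- data.frame(spot = spt$id, layer = "1", category = "borderline",
                          validated = FALSE, accession = h$accession,
                          description = h$description,
                          protein_score = h$protein_score, protein_ci = h$protein_ci,
                          total_ion_score = h$total_ion_score,
                          total_ion_ci = h$total_ion_ci,
                          n_peptides = h$n_peptides,
                          n_sig_peptides = h$n_sig_peptides,
                          n_hssp = 0L, best_hssp = NA_real_,
                          justification = dec1$justification)
      }
    }
    if (is.null(row)) row <- .empty_report_row(spt$id)
    rows[[i]] <- row
    if (verbose)
      message(sprintf("spot %s: %s -> layer %s (%s)", spt$id,
                      paste(log_steps, collapse = "; "), row$layer, row$category))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "evidence") <- evidence
  attr(out, "seed") <- config$seed
  out
}

#' Write per-spot reports as TSV
#'
#' @param reports [run_pipeline()] output.
#' @param path Output TSV path.
#' @param seed Seed recorded in the header (defaults to the one carried on
#'   `reports`).
#' @return `path`, invisibly.
#' @export
write_spot_reports <- function(reports, path, seed = attr(reports, "seed")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# layerid spot report\tseed=%s",
                     if (is.null(seed) || is.na(seed)) "NA" else seed), con)
  df <- reports
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  for (cn in names(df)[num]) df[[cn]] <- ifelse(
    is.na(df[[cn]]), "NA", sprintf("%.4f", df[[cn]]))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.TAXON_GROUPS <- c("dinoflagellates", "nondinoflagellate-algae", "other")

#' Taxonomic summary per layer
#'
#' Percentages of identified spots per taxonomic group
#' (dinoflagellates / non-dinoflagellate algae / other) within each layer.
#' Accessions missing from the map fall into "other".
#'
#' @param reports [run_pipeline()] output.
#' @param taxon_map data.frame (`accession`, `group`).
#' @return data.frame with `layer`, `group`, `n`, `pct` (per-layer
#'   percentages summing to 100).
#' @export
summarize_taxa <- function(reports, taxon_map) {
  idd <- reports[reports$layer != "none", , drop = FALSE]
  if (!nrow(idd))
    return(data.frame(layer = character(), group = character(),
                      n = integer(), pct = numeric()))
  lookup <- function(acc) {
    g <- taxon_map$group[match(acc, taxon_map$accession)]
    miss <- is.na(g)
    g[miss] <- taxon_map$group[match(sub("\\|[^|]*$", "", acc[miss]),
                                     taxon_map$accession)]
    g[is.na(g) | !(g %in% .TAXON_GROUPS)] <- "other"
    g
  }
  idd$group <- lookup(idd$accession)
  out <- list()
  for (ly in sort(unique(idd$layer))) {
    sub <- idd[idd$layer == ly, ]
    n <- vapply(.TAXON_GROUPS, function(g) sum(sub$group == g), 0L)
    out[[ly]] <- data.frame(layer = ly, group = .TAXON_GROUPS, n = unname(n),
                            pct = unname(100 * n / sum(n)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Functional summary over unique proteins
#'
#' Collapses spot-level reports to unique accessions (isoform spots of one
#' accession count once) and tabulates functional-category percentages;
#' unmapped accessions fall into "unknown function".
#'
#' @param reports [run_pipeline()] output.
#' @param function_map data.frame (`accession`, `category`).
#' @return data.frame with `category`, `n`, `pct` (summing to 100).
#' @export
summarize_functions <- function(reports, function_map) {
  idd <- reports[reports$layer != "none" & !is.na(reports$accession), ,
                 drop = FALSE]
  accs <- unique(idd$accession)
  if (!length(accs))
    return(data.frame(category = character(), n = integer(), pct = numeric()))
  cat <- function_map$category[match(accs, function_map$accession)]
  miss <- is.na(cat)
  cat[miss] <- function_map$category[match(sub("\\|[^|]*$", "", accs[miss]),
                                           function_map$accession)]
  cat[is.na(cat)] <- "unknown function"
  tab <- table(cat)
  out <- data.frame(category = names(tab), n = as.integer(tab),
                    pct = 100 * as.integer(tab) / length(accs))
  out <- out[order(-out$n, out$category), ]
  rownames(out) <- NULL
  out
}
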