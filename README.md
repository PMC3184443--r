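# layerid

Multilayered protein identification for organisms without a sequenced
genome, built for gel-based MALDI-TOF/TOF studies (the motivating case is
dinoflagellate proteomics, where only a few thousand proteins are
annotated and identification must lean on cross-species and EST
evidence).

Each 2-DE spot — one MS peak list plus up to 20 MS/MS spectra — is routed
through three layers, and the first confident layer wins:

1. **Protein-database search.** A combined PMF + MS/MS search. Each
   peptide-spectrum match is scored with a binomial shared-peak-count
   model: with *k* of *N* peaks matching the candidate's b/y/a and
   neutral-loss ions within tolerance, the ions score is
   `-10·log10 P(X ≥ k)`, `X ~ Binom(N, q)`, where `q` is the larger of the
   uniform estimate `(ion count · 2 · tol)/span` and a per-match decoy
   rate from composition-preserving shuffles of the candidate.
   Expectations are `E = p · (candidates tried)` and
   `C.I.% = 100·(1 − min(1, E))`. A spot is **confident** with ≥ 2
   significant peptides and protein-score C.I. ≥ 95%; one significant
   peptide (or sub-95% C.I.) is **borderline**.
2. **EST search.** Six-frame translations of an EST database, split at
   stop codons, are indexed and searched identically; a matched EST is
   annotated by gapped local alignment (BLOSUM62, affine gaps 11/1)
   against a protein database, with Karlin–Altschul significance
   `E = K·m·n·e^(−λS)`. **EST-confident** requires total-ion C.I. ≥ 95%
   and annotation E ≤ 1e−20.
3. **De novo + homology search.** Spectra are interpreted on a spectrum
   graph (each peak read as b and as y; beam search over residue paths;
   candidates rescored by the percentage of total ion abundance their
   fragments explain). Up to ten candidates per spectrum are reported and
   those scoring > 50 are merged into one minus-separated query, searched
   gaplessly against the protein database with a PAM30-based
   mass-ambiguity-tolerant matrix (I/L and K/Q collapsed). Subjects with
   ≥ 2 HSSPs of score ≥ 62 from distinct spectra are
   **tentative-homology** identifications; exactly one is **borderline**,
   and layer-3 evidence on a layer-1 borderline subject flags it
   **validated**.

Spots failing all layers are **unknown**. A seeded synthetic-data module
(`simulate_study()`) generates protein/EST/homolog databases and MALDI
spots with known ground truth, so the whole pipeline is testable offline.

## Worked example

```r
library(layerid)
study <- simulate_study(simulation_spec(
  seed = 7, n_spots = c(db = 2, est = 1, homolog = 1, junk = 1),
  n_background = 10))
cfg <- pipeline_config(protein_db = study$protein_db,
                       est_db = study$est_db,
                       annotation_db = study$annotation_db, seed = 7)
reports <- run_pipeline(study$spots, cfg)
reports[, c("spot", "layer", "category", "accession",
            "n_sig_peptides", "protein_ci", "n_hssp")]
```

```
     spot layer      category accession n_sig_peptides protein_ci n_hssp
1 spot001     1     confident      P001              5        100     NA
2 spot002     1     confident      P002              5        100     NA
3 spot003     2 EST-confident EST001|-1              5        100     NA
4 spot004     3    borderline      H001             NA         NA      1
5 spot005  none       unknown      <NA>             NA         NA     NA
```

The two spots simulated from database proteins are confident layer-1
hits (five significant peptides each, protein C.I. 100%); the spot whose
protein exists only as an EST is recovered from translation frame −1 of
`EST001`; the spot whose nearest database entry is an 80%-identity
homolog reaches it through de novo sequencing plus homology search (one
retained HSSP, hence borderline); the noise spot stays unknown.
`write_spot_reports()` writes the table as TSV with the seed in the
header; `summarize_taxa()` and `summarize_functions()` produce the
study-level percentage tables.

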