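---
title: "Layered protein identification for unsequenced genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layered protein identification for unsequenced genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Dinoflagellates and many other ecologically important organisms have no
sequenced genome, so the standard proteomics route — match MS/MS spectra of
tryptic peptides against the organism's protein database — cannot work
directly. `layerid` implements a three-layer fallback strategy for
gel-based MALDI-TOF/TOF studies of such organisms:

1. **Layer 1** — a combined peptide-mass-fingerprint (PMF) and MS/MS
   probability-scored search against a cross-species protein database.
   Spots matching at least two significant MS/MS peptides with a protein
   score confidence of 95% or better are *confident*; a single significant
   peptide, or sub-95% confidence, is *borderline*.
2. **Layer 2** — the remaining spots are searched against six-frame
   translations of a taxon-specific EST (expressed sequence tag) database;
   a matched EST is then annotated by gapped local alignment against a
   protein database. The identification is accepted when the total-ion
   confidence is at least 95% *and* the annotation E-value is at most
   1e-20.
3. **Layer 3** — spots still unexplained are sequenced *de novo* from
   their spectra via a spectrum graph; candidates passing a reliability
   filter (score strictly above 50, at most ten per spectrum) are merged
   into a single minus-separated query and searched gaplessly against the
   protein database with a mass-ambiguity-tolerant matrix. Subjects with
   two or more retained high-scoring segment pairs (HSSPs, score ≥ 62)
   from distinct spectra are *tentative homology* identifications; exactly
   one retained HSSP is *borderline*. Layer-3 evidence that lands on the
   same subject as a layer-1 borderline hit upgrades it and flags it
   *validated*.

Spots failing all three layers are reported *unknown*. Layer precedence is
strict: the first confident layer wins and later layers are not consulted.

## Layer-1 scoring model

The commercial engines used in MALDI workflows publish scores of the form
`-10*log10(p)` but keep `p` proprietary. `layerid` uses a transparent
binomial shared-peak-count model. For a candidate peptide whose precursor
matches within the peptide tolerance (default 50 ppm), the theoretical
b/y/a and water/ammonia-loss ions are matched against the spectrum at the
fragment tolerance (default 0.25 Da); with `k` of `N` retained peaks
matched, `p` is the binomial tail `P(X >= k)` with per-peak chance-match
probability `q`, the ions score is `-10*log10(p)`, the expectation is
`E = p * (number of candidates tried)`, and `C.I.% = 100 * (1 - min(1, E))`.

The chance probability `q` needs care. The naive uniform estimate
`q0 = (ion count * 2 * tol) / span` underestimates reality by roughly a
factor of five, because peptide fragment masses cluster on the ~1 Da
mass-defect lattice and real candidate peptides share the precursor mass
and the tryptic C-terminus with the true peptide, so their fragment
positions collide far more often than uniform placement predicts. Left
uncalibrated this produces ions scores of 40–120 for entirely unrelated
peptides. `score_psm()` therefore calibrates `q` per match: the candidate's
residue-mass vector is permuted by three fixed interior shuffles (the
C-terminal residue stays put, preserving the tryptic anchor, composition,
total mass and lattice alignment), the decoy ladders are matched against
the same spectrum, and `q = max(q0, observed decoy match rate)`. The
shuffles are deterministic functions of the peptide length, so scoring is
reproducible without any random state.

Protein scores add a PMF component: the count of MS-list peaks matching
the protein's peptide masses is converted through the analogous binomial
tail. Protein-level and total-ion expectations multiply by the database
protein count.

## Layer 2: translation and annotation

Six-frame translation uses the standard genetic code (ambiguous codons
give `X`) and splits products at stop codons; each stop-free segment of a
frame is digested and indexed exactly like a protein, under the accession
`estid|frame`. Spectrum search against this index reuses the layer-1
machinery unchanged.

Annotation aligns every translated segment of the matched EST against the
annotation database with `Biostrings::pairwiseAlignment` (local, BLOSUM62,
affine gaps open 11 / extend 1) and converts the best score `S` to
`E = K * m * n * exp(-lambda * S)` with `m` the total translated length
and `n` the database residue count. `(lambda, K)` come from the standard
ungapped moment method for lattice score distributions — `lambda` as the
positive root of `sum(p_s * exp(lambda*s)) = 1`, `K` from the
Karlin–Altschul series formula via iterated convolution — computed for
BLOSUM62 under Robinson–Robinson backgrounds; the unit tests check the
implementation against the published ungapped values
(`lambda = 0.3176`, `K = 0.134`). Pairing gapped scores with ungapped
parameters makes the E-values conservative approximations; with the e-20
acceptance bar this is inconsequential (exact-match annotations land many
orders of magnitude below it, random ones many above). "e-20" is read as
1e-20, the standard BLAST notation.

## Layer 3a: spectrum-graph de novo sequencing

Every deconvoluted peak is interpreted both as a b ion (prefix residue
mass `mz - proton`) and as a y ion (prefix mass `precursor - mz`);
interpretations agreeing within the fragment tolerance (default 0.08 Da)
merge into one graph node scored by the summed relative intensity of its
supporting peaks (percent of total, so node scores and the peakless-step
penalty share a scale). Note the y interpretation is `precursor - mz`, the
unique value consistent with b/y ladder complementarity
(`b_i + y_(n-i) = M + 2*proton`).

A beam search (default width 200) walks residue-labelled paths from prefix
mass 0 to the sink `precursor - proton - water`, adding the node score for
a supported step and the penalty (default −1) for an unsupported one. The
edge alphabet drops I (reported as L with an ambiguity flag), fixes
carbamidomethyl-C, and adds a lowercase `m` for oxidised methionine.
Completed paths become candidates and are rescored as the percentage of
total ion abundance explained by their b, y, a, loss, immonium and
internal (length ≤ 5) fragments, each peak counted once.

Ranking sorts by rescore, then by *graph score*, then by length and
lexicographic order. The graph-score tiebreak matters: isobaric
multi-residue rearrangements (e.g. `GTGT` vs `AGTS`) can explain identical
ion abundance because the peaks their mismatched boundaries fail to match
are picked up by coincidental loss or internal ions, while only the true
path lands on supported graph nodes at every boundary. The top ten
candidates are reported; those scoring strictly above 50 pass the
reliability filter. K/Q calls are flagged ambiguous whenever the fragment
tolerance exceeds their 0.0364 Da mass difference.

## Layer 3b: merged-query homology search

All filtered candidates of a spot are joined with `-` into one query
string with an invertible position map. Gapless local alignment against
each database protein enumerates, per diagonal, the recursive
maximal-segment decomposition (the best-scoring segment is extracted and
the flanks are decomposed recursively), with separator positions scored
`-Inf` so no segment crosses a candidate boundary; the unit suite checks
the segment set against exhaustive enumeration of all gapless segment
pairs.

The substitution matrix is PAM30 with two mass-ambiguity modifications:
`score(I, L) = score(I, I)` and `score(K, Q) = max(self scores) - 1`. PAM30
is the appropriate scale for short low-divergence peptide queries, and the
fixed HSSP confidence cutoff of 62 presupposes PAM30-scale scores — with
BLOSUM62-scale scores a fully correct tryptic peptide aligned to an
80%-identity homolog rarely reaches 62 and the search cannot work as
described. Classification counts retained HSSPs from distinct spectra per
subject (same-spectrum duplicates count once); ties break by summed score,
then by an optional taxon-priority table (phylogenetic closeness), then
alphabetically.

## The synthetic-data generator

No public raw spectra exist for this kind of study, so the generator is
first-class, tested code that emulates what the instrument produces:
singly charged tryptic precursors in 850–4000 Da, b/y ladders detected
with probability 0.9 (secondary a/loss/immonium ions at 0.4), lognormal
intensities (meanlog log 500, sdlog 0.6; secondary ions attenuated 0.3x),
Gaussian calibration error of 0.02 Da, 8 uniform noise peaks per MS/MS
spectrum and 10 per MS list, and 10% methionine-oxidation incidence. The
default study is 60 spots: 20 from proteins present in the search
database, 20 only encoded in the EST database (reverse-translated with
uniform codon usage, untranslated padding and random strand), 15 whose
nearest database relative is a planted homolog at 80% residue identity,
and 5 junk spots of pure noise; 5 MS/MS spectra per spot, peptides of
8–25 residues. These sizes keep the full suite tractable on one CPU while
leaving every routing decision represented.

What the generator does *not* emulate: isotope envelopes, detector
saturation, co-eluting chimeric precursors, real intensity structure along
the ladder (position- and residue-dependent cleavage propensities), and
realistic protein sequence composition beyond Robinson–Robinson residue
frequencies. Passing the synthetic suites therefore demonstrates that the
algorithms are implemented and calibrated as specified, not that the
pipeline reaches any particular identification rate on real gels.

## Numerical and design choices

- Masses are monoisotopic throughout; water 18.010565, proton 1.007276,
  ammonia 17.026549, CO 27.994915 Da. I/L share a mass; K/Q differ by
  0.0364 Da, below the 0.08 Da de novo tolerance.
- Trypsin cleaves after K/R except before P (standard specificity; the
  no-P exception is a package choice), with one missed cleavage by
  default; N-terminal methionine removal is not applied.
- Fixed modifications shift their residue mass unconditionally; variable
  modifications are enumerated up to 2 sites per peptide to bound the
  index.
- The fragment tolerance default for layer-1/2 searches is 0.25 Da and the
  de novo tolerance 0.08 Da; both are configurable (the instrument
  software's printed settings include both a 0.25 Da and a 0.1 Da MS/MS
  figure, and which governed a given search cannot be recovered, so the
  looser value is the default).
- The MS peak filter retains 850–4000 Da, S/N ≥ 10 (instrument S/N when
  present, otherwise intensity over the median intensity within a 200 Da
  window), at most 50 peaks per 200 Da window and at most 65 overall,
  keeping the most intense; precursor selection takes the top 20 by
  intensity at S/N ≥ 50 after removing keratin / trypsin-autolysis /
  CHCA-matrix exclusion-list masses (±0.1 Da, user-overridable).
- MS/MS peak lists are not range-filtered: the low-mass 60–200 Da region
  is retained because the de novo rescoring uses immonium ions that live
  there.
- Degenerate inputs: empty proteins digest to nothing; empty spectra score
  zero; a precursor below the smallest residue leaves the spectrum graph
  sinkless and the spot routes onward; spots failing every layer are
  reported unknown rather than dropped.
- Determinism: the pipeline itself draws no random numbers; all
  stochasticity lives in the seeded generator, so identical inputs and
  seed reproduce reports byte for byte.

## Known limitations

The layer-1 score is a calibrated stand-in, not a reimplementation of any
commercial engine, so absolute score values are not comparable to
published ones — only the decision thresholds are. E-values for gapped
annotation reuse ungapped Karlin–Altschul parameters. The homology layer
is gapless by design (gapped sensitivity is layer 2's job). Internal
fragments are capped at length 5 during rescoring for cost. The published
study-scale identification counts depend on 2010 database snapshots and
undeposited spectra and are out of reach of any reimplementation; the
acceptance machinery instead measures recovery rates and calibration on
the synthetic study described above.
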