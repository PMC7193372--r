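---
title: "Methods: ClpB-like gene function, alpha-MSH mimicry and host phenotype"
author: "clpbmimic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ClpB-like gene function, alpha-MSH mimicry and host phenotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clpbmimic)
```

## The scientific problem

Gut bacteria of several families carry a ClpB-like chaperone (KEGG ortholog
K03695) whose sequence contains a region resembling α-MSH, an anorexigenic
host peptide. Quantifying that resemblance, measuring how abundant the
ClpB-like gene function is per subject, and relating it to adiposity and to
metabolite profiles requires three bespoke computations that sit between
standard tools: an annotation-counting pipeline over predicted ORFs, a motif
mimicry screen over protein sequences, and an O-PLS association analysis
with permutation validation. This vignette documents how each is defined
here, which knobs matter, and what the synthetic data used for validation
does and does not emulate.

## Functional profiling

The pipeline consumes three tables: homology hits (`orf_id`, `ko`,
`evalue`, `bitscore`), ORF locations (1-based inclusive coordinates on
contigs; strand is carried but ignored for counting, since mapped reads are
strand-agnostic), and read alignments.

* **Best annotation per ORF.** Minimal e-value; ties broken by maximal
  bitscore, then by the lexicographically smallest KO. The third key makes
  the result a pure function of the inputs — important because downstream
  contingency tables must be byte-reproducible.
* **Read-to-ORF assignment.** "A read inside an ORF" is operationalized as
  an overlap of at least 50 % of the read's aligned length; among
  qualifying ORFs the smaller start coordinate wins (then the smaller
  `orf_id`). The threshold is the natural majority rule and behaves
  sensibly at boundaries: a 10-bp read overlapping an ORF by exactly 5 bp
  is assigned.
* **Contingency table.** Counts are summed per sample and KO; category
  roll-ups add a KO's count to *every* category it belongs to, so category
  totals may exceed annotation totals by design. Relative abundance divides
  by the per-sample annotated-read total by default; the denominator is
  configurable (`total_reads`) because "arbitrary units" can also be
  defined against all mapped reads, and published tables rarely state
  which.
* **Taxon filter.** A taxon survives only with strictly more than 10 reads
  in at least two samples. "More than" is read as a strict inequality; a
  taxon at exactly 10 reads everywhere is dropped.

## The mimicry screen

The reference protein is scanned for the hexapeptide motif (RWGKPV by
default); the first exact occurrence is used, with a warning if the motif
recurs. Each ORF is then aligned to the reference epitope region — the
motif plus 30 residues of flank on each side — and evaluated on two
identity figures.

**Alignment.** Semi-global (overlap) alignment: terminal gaps on either
sequence are free, so a fragment can sit anywhere inside the window and a
longer ORF can overhang it; internal gaps cost `open + L * extend`
(defaults 11 + L, the BLAST convention) against BLOSUM62 scores (taken from
Biostrings' shipped matrix, not retyped). The dynamic program is a
three-state Gotoh kernel in C++ with fully specified tie-breaking —
diagonal preferred over up (query residue against a gap) over left — and
the end cell chosen by a fixed scan order, so alignments are deterministic.
The alignment always contains at least one aligned residue pair; a
"skip-everything" zero-column alignment is not considered a valid
placement. The suite verifies the kernel against an exhaustive
dynamic-programming oracle (free-end decomposition around a fully penalized
global core) on hundreds of random short pairs.

**Identity.** `100 × matches / reference-residue columns`, with gaps in
either sequence counting as mismatches and reference-gap columns excluded
from the denominator. This makes identity(s, s) = 100, bounds it in
[0, 100], and is symmetric for gap-free alignments. Two figures are
reported per ORF because they answer different questions: *motif identity*
over the six motif columns (does this ORF carry the epitope verbatim?) and
*window identity* over the trimmed ± 30-residue window (how conserved is
the neighbourhood?). Family summaries count perfect-motif sequences and
average window identity; both are first-class outputs.

**Epitope coverage.** "Covers the epitope" requires query residues in all
six motif columns by default (`min_motif_cols` relaxes this to, say, 4 for
fragmentary reads). ORFs failing coverage are logged with a reason rather
than silently dropped.

## Metabolome association

* **PQN.** Reference spectrum = feature-wise median; per-sample dilution
  factor = median quotient against the reference over features positive in
  both; the sample row is divided by its factor. On a dilution series
  (rows that are scalar multiples of one spectrum) PQN collapses all rows
  to a single spectrum and a second application is the identity — both
  properties are asserted in the tests. Samples with no positive
  quotient-eligible feature are an error, not a silent pass-through.
* **Scaling.** Unit-variance scaling (mean 0, SD 1, denominator n − 1).
  Zero-variance features are an error: imputation and filtering are the
  caller's responsibility by design.
* **O-PLS.** `w ∝ X'y` normalized; per orthogonal component
  `w_o ∝ p − (w'p)w` normalized, `t_o = X w_o`, deflate
  `X ← X − t_o p_o'`; predictive score `t = X w` on the deflated matrix and
  inner regression `b = t'y/t't`. The construction guarantees `‖w‖ = 1`,
  `w'w_o = 0` and pairwise-orthogonal `T_o` columns, asserted across random
  datasets. With zero orthogonal components the model coincides with
  single-component PLS1 (checked against the closed form). The default is
  **one** orthogonal component — the common choice for a single-response
  model where one systematic orthogonal source is expected — and is
  configurable.
* **Q²Y.** Seven-fold cross-validation; folds are a seeded shuffle
  (recorded), scaling and centering re-estimated inside each training fold
  only; Q²Y = 1 − PRESS/TSS on the centered response, hence invariant to
  positive rescaling of y.
* **Permutation validation.** The statistic is Q²Y itself (not the training
  R²Y, which is optimistic under overfitting); the add-one estimator keeps
  p > 0, with minimum 1/(n_perm + 1). The reference depth is 1000
  permutations; calibration experiments in the tests use 99–199 per
  replicate, which fixes p-granularity at 1/100–1/200 and keeps 200-replicate
  null studies affordable.
* **Feature correlations.** Pearson r of each feature against the model's
  predictive scores by default (the response is available as an explicit
  alternative), p from the t-distribution, q by Benjamini-Hochberg.

## Cohort statistics

Group dispatch mirrors clinical-table conventions: χ² (no continuity
correction by default) for categorical variables; for continuous variables
Shapiro-Wilk per group at α = 0.05, then median-centered Levene choosing
Student versus Welch, otherwise Mann-Whitney U. The dispatch is a pure
function of the data and thresholds; its type-I error on planted normal and
skewed nulls is required to stay in [0.03, 0.07] at α = 0.05. Summaries
follow mean (SD) for normal and median [IQR] for non-normal variables.

"Adjusting for" covariates is implemented as rank-residual partial
correlation: rank-transform everything, residualize ranked x and y on the
ranked covariates, correlate residuals, p on n − 2 − k degrees of freedom.
With zero covariates the code path returns the plain Spearman result
bit-for-bit. Rank-based adjustment was chosen over Pearson-on-residuals to
stay consistent with the nonparametric headline correlations; both answer
slightly different questions and the choice is documented rather than
hidden. Multiple regression is ordinary least squares with optional
standardized β (z-scored response and numeric predictors). BH adjustment
delegates to the standard step-up implementation and is verified against a
brute-force oracle.

## The synthetic-data module

The generators define the study conditions for every test:

* **Reference and ORFs.** A 600-residue random protein with RWGKPV planted
  at position 300; ORFs copy the ± 30-residue epitope window with an exact
  number of motif substitutions (positions without replacement) and
  per-residue flank retention probability. Substitutions always change the
  residue, so planted identity is analytic: motif identity is exactly
  (6 − m)/6 and expected flank identity equals the retention probability.
  Recovery tests use families of 40/30/10 ORFs with 0/1/3 motif mismatches
  at flank identity 0.9 — large enough for 3-standard-error window-identity
  bands to be tight, small enough to screen in seconds.
* **Metagenome.** Each ORF sits on its own contig (span 300 nt), reads of
  100 nt fall wholly inside spans, decoy ORFs get reads but no hits, and
  30 % of annotated ORFs get a strictly inferior second hit so best-hit
  selection is exercised; ties are never planted (tie rules are tested with
  hand-built fixtures instead). Per-sample per-KO truth counts are recorded
  for conservation checks.
* **Metabolome.** `X = t p' + Σ t_o p_o' + E`, with y = t + noise and each
  orthogonal score orthogonalized against t by projection. The recovery
  condition (n = 60 samples, 40 features, one orthogonal component, noise
  SD 0.1) mirrors a modest untargeted panel on a cohort-scale sample count.
* **Cohort.** Function abundance and BMI from a bivariate normal with the
  planted correlation (−0.4 at the study's n = 131 in the drivers; the
  obesity label applies the clinical BMI ≥ 30 threshold, which also makes
  within-group BMI truncated-normal and exercises the nonparametric
  dispatch branch). Intakes and demographics are plausible covariates.

All randomness flows from one integer seed through `withr::with_seed`, so
every artifact is byte-reproducible and no global RNG state leaks.

What the synthetic data does **not** emulate: nucleotide-level sequencing
error, fragmentary ORFs (indels relative to the reference window),
compositionality of real count data, correlated metabolite blocks, missing
values, or batch structure. Passing tests therefore demonstrate
correctness of the computations and calibration of the inference under
clean planted conditions — not robustness to every artefact of real
metagenomes.

## Numerical choices and degenerate inputs

Alignment scores are exact integer arithmetic in double precision;
identity comparisons for "perfect motif" use a 1e-9 band. Orthogonality
invariants are asserted at 1e-8. Homology bins are half-open with a closed
last bin so percentages of exactly 100 are counted once. Empty hit tables,
empty FASTA sets, constant features, zero-variance responses, rank-deficient
designs and collinear covariates all raise explicit errors naming the
offender; reads on hitless contigs and ORFs without annotation are counted
and reported, never silently lost.

## Problem sizes

The shipped tests and drivers run at deliberately modest scale — hundreds
of ORFs, 60 × 40 metabolite matrices, 200-replicate calibration studies
with 99–199 permutations each, 2000-replicate dispatcher nulls — sizes a
desk machine handles in minutes while keeping every statistical band
(3 SE, type-I error in [0.03, 0.07], null rejection in [0.01, 0.10])
meaningful.

## Known limitations

* The aligner is pairwise; the original multiple-alignment formulation of
  the screen is replaced by per-ORF alignment to the reference window,
  which is deterministic and testable but can differ from an MSA around
  heavily gapped regions.
* Published per-family identity figures from real cohorts are not
  reproducible without the underlying reads; validation is therefore
  planted-recovery, not numeric replication.
* O-PLS here fits a single predictive component (the single-response
  case); multi-response extensions are out of scope.
* PQN assumes mostly positive intensities; matrices on a signed latent
  scale must be shifted or left unnormalized, as the drivers illustrate.
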