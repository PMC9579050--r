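---
title: "Quantifying concerted evolution of plant immune-receptor repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying concerted evolution of plant immune-receptor repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(receptoire)
```

## The scientific question

Plants defend themselves with two functionally interdependent receptor
layers: cell-surface pattern-recognition receptors (PRRs — receptor-like
kinases and receptor-like proteins) that detect extracellular pathogen
molecules, and intracellular NLRs (diagnosed by their NB-ARC
nucleotide-binding domain) that detect secreted effectors. If the two layers
mutually potentiate each other, their gene repertoires might expand and
contract together across species. `receptoire` implements the comparative
pipeline needed to ask that question from annotated proteomes: identify the
receptor families by explicit domain-architecture rules, normalize counts to
proteome percentages, and test for concerted evolution with Pearson
correlations, Mantel and partial Mantel tests against a species phylogeny,
and a resampling test for genomic co-clustering.

## Identification rules

Classification consumes precomputed per-domain hit tables (HMMER
`--domtblout` or a plain TSV dialect) and transmembrane summaries, not raw
sequences, so any upstream search tool can be used. Each primary-transcript
protein is tested against four independent rules:

| family | rule |
|---|---|
| LRR-RLK | length ≥ 250 AA, kinase domain (PF00069) at E ≤ 1e-10, ≥1 LRR domain at E ≤ 1e-2 |
| LRR-RLP | length ≥ 150 AA, ≥1 LRR domain, **no** kinase hit at E ≤ 1e-10, C3F juxtamembrane domain at E ≤ 1e-10 with alignment ≥ 140 AA, ≥1 TM helix |
| NB-ARC  | length ≥ 150 AA, NB-ARC domain (PF00931) at E ≤ 1e-10 |
| LysM-RLK / RLP | length ≥ 150 AA, LysM domain (PF01476) at a permissive E ≤ 1000, ≥1 TM helix; split by kinase presence/absence |

Numerical conventions worth stating explicitly, because they decide edge
cases:

* **All thresholds are inclusive on the passing side** — a hit at exactly
  E = 1e-10 passes, a 250-AA protein passes the LRR-RLK floor, a 140-residue
  C3F alignment passes. The synthetic generator always emits fixtures on
  both sides of every boundary so the tests pin these comparisons.
* **E-values are full-sequence E-values**, matching the semantics of an
  `-E` reporting threshold in a sequence search; the C3F length filter uses
  alignment (not envelope) coordinates.
* The LRR threshold is 1e-2, reading the conventional `10e-3` notation
  literally rather than as 1e-3.
* **Pfam accessions are matched before the version dot** (PF00069.26 and
  PF00069.28 are the same domain), so hit tables from any Pfam release work.
* A protein matching several family rules is counted in **every** family it
  matches (no exclusion hierarchy is defined for, say, an NB-ARC protein
  that also carries kinase + LRR domains); such proteins are reported
  separately. LRR-RLK and LRR-RLP remain disjoint by construction.
* The **primary transcript** is the longest isoform per gene, ties broken by
  the lexicographically smallest protein id. Source databases flag primary
  models inconsistently; longest-isoform is the standard reproducible proxy
  and is logged when gene ids must be inferred.

LRR-RLK candidates are assigned to one of the 20 kinase-domain subgroups
(I–XV, with VI, VII, VIII and X split; subgroup XII holds the classical
pathogen sensors FLS2, EFR, Xa21) by extracting the highest-scoring kinase
envelope and aligning it to a reference panel with Smith–Waterman local
alignment (BLOSUM62, gap open 11, extend 1). The call is best-hit with a
deterministic tie-break (score, then panel order) and a bit-score floor of
50: E-value calibration is aligner-specific, so a conservative score floor
replaces an E-value cutoff; candidates below it are "unclassified". Panel
entries are themselves re-filtered through the kinase/LRR rules at load
time rather than pruned by a hard-coded list. Best-hit assignment was chosen
over per-subgroup tree placement: it is deterministic, fast, and exactly
reproducible from the scorer, whereas tree placement depends on alignment
and inference heuristics outside this package's scope.

## Percentages and correlation

Counts are normalized per species as
\[ \%f = \frac{\text{genes identified in family } f}{\text{genes searched}} \times 100, \]
with the searched-gene denominator equal to the number of primary-transcript
proteins. This makes percentages invariant under whole-genome duplication
(both numerator and denominator double), which is the point of normalizing.
Two derived groups are computed as count sums *before* normalization:
LRR-RLK excluding subgroup XII, and LRR-RLP plus subgroup XII.

`pearson_correlation()` reports the sample product-moment r with a
two-sided p from the t distribution on n − 2 degrees of freedom;
`correlation_suite()` correlates every family column against %NB-ARC and
applies Bonferroni correction across the executed tests (k = the number of
tests actually run, configurable). Species with zero ("null") percentages
can either be kept (default) or dropped per pair via `drop_null = TRUE`;
both modes are supported because published analyses are often ambiguous on
this point. p-values below machine precision are stored as 0 and rendered
as "< 1e-300" in text.

## Phylogeny-aware tests

Percentage vectors are converted to distance matrices with
\(d(i,j) = |x_i - x_j|\) — the Euclidean metric on the line; no richer
metric is warranted for a scalar trait. Patristic distances come from the
species tree (sums of branch lengths along paths). `mantel()` correlates
the vectorized upper triangles of two matrices and assesses significance by
simultaneously permuting rows and columns of one matrix;
`partial_mantel()` uses the first-order partial correlation
\[ r_{AB\cdot C} = \frac{r_{AB} - r_{AC} r_{BC}}
   {\sqrt{(1 - r_{AC}^2)(1 - r_{BC}^2)}} \]
and permutes A. Choices:

* One-sided ("greater") alternative by default, the conventional Mantel
  alternative; two-sided available.
* The empirical p uses the add-one estimator \((1 + \#\{r^* \ge r\})/(N+1)\),
  so p is never 0 and its support starts at \(1/(N+1)\). The default is
  10,000 permutations; the test suite uses 99–999 for speed.
* Pearson correlation on the distance entries by default (Spearman
  available as an option).
* When the tree covers only part of the species table, labels are
  intersected and the dropped set is reported — partially overlapping
  genome panels and published trees are the rule, not the exception.
* Benjamini–Hochberg FDR correction is applied across each block of tests
  in `mantel_suite()`.

Calibration of all permutation machinery is tested: under a true null the
rejection rate at α = 0.05 stays within 2 binomial standard errors of α
over 1,000 replicates, and sampled p-values agree with exhaustive
enumeration (all 24 permutations of a 4-label matrix; all 15 two-gene
subsets of a toy universe).

## Genomic co-clustering test

Are subgroup-XII genes physically closer to NB-ARC genes than chance
predicts? The observed statistic is the mean, over group-A genes, of the
closest distance to any group-B gene, where distance is the inter-interval
gap in bp (0 for overlapping or abutting genes, strand ignored). The null
distribution resamples m = |B| genes from the searched-gene universe
(without replacement, by default 1,000 times) and recomputes the statistic;
the p-value is one-sided for "closer than chance" with the same add-one
estimator. Conventions:

* A gene never measures distance to itself (same gene id is skipped);
  overlapping *distinct* genes legitimately contribute 0.
* A gene with no same-sequence partner has an **undefined** distance and is
  excluded from the mean (and counted); any finite sentinel for
  cross-chromosome pairs would distort the mean, so none is used.
* Sampling with replacement is available as a sensitivity flag.

## The synthetic-data generator

Every input the pipeline consumes can be generated with known ground truth.
Counts follow a Poisson log-linear latent-factor model: species s carries a
standard-normal latent factor \(z_s\) (immune-investment propensity), and
\[ N_{fs} \sim \text{Poisson}\!\left(T_s\, q_f \exp\!\big(b_f z_s +
   \sigma_f \varepsilon_{fs} - \tfrac{b_f^2 + \sigma_f^2}{2}\big)\right), \]
with \(T_s\) the proteome size, \(q_f\) the expected percentage fraction,
\(b_f\) the shared loading and \(\sigma_f\) idiosyncratic family noise.
The exponent correction keeps the expected percentage at exactly
\(100\,q_f\). The correlation between two family percentages has the closed
form implemented in `expected_pct_correlation()` (log-normal covariance
plus a Poisson noise term), which `calibrate_loading()` inverts to hit a
target Pearson r exactly.

Defaults are the study conditions the analysis assumes: 300 angiosperm
species (eudicot/monocot/basal in roughly observed proportions), mean
percentages inside the observed angiosperm ranges (LRR-RLK 1%, NB-ARC 0.8%,
LRR-RLP 0.25%, LysM-RLK 0.03%, LysM-RLP 0.01%), proteome sizes of
20,000–60,000 searched genes, a target r of 0.8 for the NB-ARC/LRR-RLP
pair, and total log-scale variance \(\log 2\), i.e. percentage coefficients
of variation near 100% — matching the very wide ranges real repertoires
show. Proteome emission plants one protein per simulated receptor whose
hit-table rows satisfy exactly one family rule, with E-values sampled well
inside the thresholds, plus decoys failing every rule; protein sequences
are random strings (classification consumes hit tables, not motifs), except
that planted LRR-RLKs embed a 10%-mutated copy of their subgroup's panel
kinase region so subgroup assignment can be exercised end to end. Gene
coordinates are uniform, except that a configurable fraction of subgroup-XII
genes is re-placed within a window (default 50 kb) of an NB-ARC gene to
plant clustering. Species trees are pure-birth (Yule); optionally the latent
factor mixes a standardized Brownian-motion trait evolved on the tree with
independent noise, giving phylogenetic signal of known strength.

What the generator deliberately does **not** emulate: realistic sequence
evolution, HMMER score distributions, correlated domain-hit errors,
annotation noise (split/merged gene models), or gene gain–loss dynamics on
the tree. Passing tests on synthetic data therefore demonstrate that the
*statistical machinery and rules* behave as specified — not that any
particular biological dataset is free of annotation artefacts.

## A known statistical limitation

With heavy-tailed (log-normal-like) percentage distributions, the sampling
spread of the Pearson correlation is wider than bivariate-normal theory
predicts: at the default spread, the across-replicate standard deviation of
\(\operatorname{atanh}(\hat r)\) at n = 300 is roughly double the Fisher-z
value \(1/\sqrt{n-3}\). Fisher-z confidence intervals for \(\hat r\)
consequently undercover the generating r (the acceptance script reports the
measured coverage). This is a property of applying normal-theory intervals
to skewed data, not an error in the estimator: the replicate *mean* of
\(\hat r\) sits on the calibrated target. Analyses of real repertoire data
should treat Fisher-z intervals on these correlations as optimistic.

## Problem sizes used by the test suite

The suite exercises the study conditions at sizes chosen to keep the full
run comfortably interactive: counts-level simulations at the full n = 300
species; proteome-level simulations with tens of planted receptors among
100–500 decoys; permutation tests with 99–999 permutations in tests (10,000
at analysis defaults); calibration suites with 1,000 replicates; exhaustive
oracles on 4-label matrices, 15-subset toy genomes and ≤15-residue
peptides.
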