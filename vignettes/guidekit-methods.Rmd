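---
title: "guidekit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{guidekit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

guidekit is a toolkit for comparative CRISPR target analysis of SpCas9 and
Cas12a (Cpf1), and for modelling Cas12a guide-RNA efficiency from pooled
knockout-screen data. This vignette documents the scientific model behind
each component, the conventions and tunable parameters, what the
synthetic-data generator does and does not emulate, and the design choices
made where more than one reasonable convention exists.

## Target and off-target enumeration

SpCas9 recognises a 5'-NGG-3' PAM immediately 3' of a 20-nt protospacer;
Cas12a recognises a 5'-TTTN-3' PAM immediately 5' of the protospacer. Because
NGG is GC-rich and TTTN is AT-rich, the relative availability of the two
enzymes' targets shifts with genomic GC content, which is why `guidekit`
exposes per-genome target densities (`target_density()`) and their ratio
(`cas9_to_cas12a_ratio()`); on a synthetic GC sweep the Cas9:Cas12a ratio
rises monotonically with GC.

Conventions, fixed once and used everywhere:

* **Coordinates** are 0-based half-open (BED convention) on the forward
  strand, spanning protospacer+PAM. This makes narrowPeak interval input
  directly comparable.
* **IUPAC N in a PAM** is a wildcard over A/C/G/T only. Genomic N never
  matches anything, and any candidate window containing N is skipped; this
  is conservative and avoids phantom targets in scaffolded assemblies.
* **Protospacers** are reported 5'→3' on the PAM-carrying strand: for Cas12a
  the 20 nt immediately 3' of TTTN, for Cas9 the 20 nt immediately 5' of NGG.
* **Overlapping and nested sites are all reported.** Counts are the statistic
  of interest; no greedy masking is applied.

Potential off-targets (`count_offtargets()`) follow the common
alignment-free search semantics: a candidate site must match the PAM
pattern exactly; mismatches are counted in the protospacer only, as exact
Hamming distance (no bulges); counts are tabulated per mismatch level 0–5
by default. The test suite checks both the enumerator and the counter
against independent brute-force position-by-position oracles on hundreds of
random genomes.

Cross-enzyme off-target comparisons (`per_guide_offtarget_ratios()`,
`offtarget_ratio_table()`) normalise counts by genome length, aggregate
per-guide ratios to a per-genome median with a 25–75% IQR, and compare
mismatch levels with a Kruskal–Wallis rank test (mid-ranks for ties);
pairwise levels use rank-sum tests with Bonferroni correction implemented
literally as `min(1, p * n_comparisons)`. When every value is tied the test
statistic is reported as 0 with p = 1 rather than NaN.

## GUIDE-seq meta-statistics

GUIDE-seq-style tables arrive as curated per-site read counts (no raw read
processing). `relative_cleavage()` expresses each site as a percentage of
the guide's on-target reads; guides with zero on-target reads are excluded
with a warning because the ratio is undefined. `cleaved_fraction()` reports
the share of predicted sites that carry at least one read — one read is the
detection threshold, since the input tables are already curated;
mismatch levels with no predicted site are reported as missing rather
than zero.

## Editing-outcome landscape

Allele tables (one row per observed allele: type, length, position, outcome
base, read count) are summarised read-count-weighted throughout, so results
are invariant to splitting an allele row into two rows whose read counts sum
to the original.

* `indel_spectrum()` — frequencies by variant type × length over indel reads.
* `del_ins_stats()` — the pooled deletion:insertion read ratio, plus a Welch
  t test and Cohen's *d* (pooled SD) on per-target deletion vs insertion read
  fractions. With a single target the ratio is still defined but t/d are
  reported missing.
* `snv_positional_distribution()` — per-position percentage of SNV reads
  over an analysis window, with the uniform expectation 100/window_length
  (2.56% for the default 39-nt window). The window length is a parameter
  because published descriptions of comparable analyses are inconsistent
  about the window actually sequenced (29 vs 39 positions); 39 is the
  default here and matches a 2.56% uniform line.
* `snv_read_fraction_filter()` — retains a target's SNV outcome only when
  SNV reads are *strictly* greater than 1% of target reads (the boundary
  case 1/100 is dropped).

Position conventions: offset 0 is the first base of the analysis window on
the PAM-carrying strand; a deletion's position is its 5'-most deleted base;
an insertion's position is the base to the left of the inserted sequence.
These are stored 0-based; display layers may convert to 1-based protospacer
numbering (position 17 of the 20-nt protospacer, a frequently discussed SNV
hotspot, is three nucleotides upstream of the protospacer's PAM-distal end).

## Sequence featurization

`tokenize()` maps a DNA string deterministically to a named numeric vector:
global mononucleotide counts (A,C,G,T), global dinucleotide counts (16,
lexicographic), positional mononucleotide one-hots (position-major,
0-based), positional dinucleotide one-hots, and GC fraction last. For a
length-L sequence with all families on the vector has
4 + 16 + 4L + 16(L−1) + 1 entries — 685 for L = 34. Counts are raw
integers, GC is a fraction, positional features are 0/1. The schema is a
pure function of length and families; a schema version string
(`FEATURE_SCHEMA_VERSION`) is embedded in trained models and checked at
prediction time so a model can never be scored on a drifted encoding.

The canonical Cas12a context is 34 nt on the PAM-carrying strand:

```
[4-nt 5' flank][TTTN PAM][20-nt protospacer][6-nt 3' flank]
```

i.e. four bases on the 5' side of the PAM and twenty-six on its 3' side,
with the PAM itself excluded from the 4+26 count. This layout is stated
prominently because "upstream/downstream of the PAM" phrasing is ambiguous
in parts of the literature; here it is always read on the protospacer
strand.

`tokenize_components()` tokenizes named components independently and
concatenates with prefixed names, so no dinucleotide spans a component
boundary and the composition of a relevant component (the protospacer) is
not diluted by irrelevant flanks. `featurize_contexts()` applies this to
34-nt contexts (flank5/PAM/protospacer/flank3 × global mono+di+GC = 84
features) and is the efficiency model's default encoding. The full
positional encoding remains available through `featurize_sequences()` and
family flags; which families enter a model is deliberately configurable
because no single canonical subset exists for this problem.

## Pooled-screen efficiency inference

In a knockout screen, guides that cut efficiently in *essential* genes
deplete over time, so efficiency can be read from the negative log-fold
change of guide abundance. The chain is:

1. `screen_lfc()` — counts-per-million per library, pseudocount 1 on cpm,
   `LFC = log2((cpm_t+1)/(cpm_ref+1))`. The pseudocount bounds the statistic
   for dropouts and distorts LFC by <1% for cpm ≥ 100.
2. `infer_efficiency()` — score = −mean LFC over post-reference timepoints.
   A slope-vs-time alternative is available behind `method = "slope"`; both
   are monotone-equivalent under the exponential depletion model below, and
   the mean is the simpler default.
3. `score_to_percent()` — maps the score to a 0–100 efficiency label under
   the depletion model `E[count_t] ∝ 2^(−t·k·eff/100)`; k defaults to
   0.75/week so a fully efficient guide loses ~3 log2 units by week 4,
   typical of essential-gene depletion; values are clipped to [0, 100].
4. `essentiality_filter()` — retains guides whose gene has Bayes Factor
   ≥ 6, a conventional high-confidence essentiality cutoff (the threshold
   is a parameter; gene joins are case-insensitive and unmatched genes are
   counted, never silently dropped). Gene dispensability would otherwise
   confound depletion with efficiency.
5. `annotate_accessibility()` — DNase narrowPeak overlap of ≥ 1 bp on
   half-open intervals labels a guide accessible (1) or not (0); chromatin
   state modulates cleavage and is kept as a validation stratifier, not a
   model feature, by default.

`build_training_table()` wires 1–5 into a labelled table of guide, 34-nt
context, efficiency label and accessibility.

## Random-Forest models and validation

All hyperparameters stay at `randomForest` defaults except the tree count,
whose default is 450; the defaults are pinned through the model object so a
library upgrade cannot silently change behaviour. Two tasks exist:

* **Regression** of efficiency (labels 0–100, predictions clipped to the
  same range at output). OOB error is the out-of-bag MSE.
* **Multiclass classification** of the SNV outcome base at a hotspot.
  Since the outcome can only be one of the three non-reference bases,
  chance accuracy is 1/3 and is recorded on the model; rows whose label
  equals the reference base are rejected. OOB error is the out-of-bag
  misclassification rate.

`cross_validate()` partitions samples into 5 folds by default —
unstratified for regression, stratified (round-robin within class, exact to
±1 per class per fold) for classification — and reports per-fold and mean
metrics plus pooled out-of-fold predictions. `validate()` computes MSE,
Pearson/Spearman with two-sided p, percentile ranks (mean-of-strict-and-weak
convention, so an all-tied list ranks at 50), confusion matrices with rows
as truth, and `roc_one_vs_all()` computes per-class ROC/AUC from class
probabilities via pROC. `permutation_cor_test()` assesses a held-out
correlation against label shuffles with the add-one correction.
`feature_importance()` normalises impurity importances to sum to 1 with
ties broken by schema order; in the degenerate all-zero case a uniform
vector is returned rather than NaN.

Determinism contract: given a seed, training, fold assignment and
prediction are bit-reproducible. An 80/20 visualization split, where used,
is a seeded shuffle-then-split.

## The synthetic-data generator

Every input the pipeline consumes can be generated with planted ground
truth (`generate_genome()`, `generate_screen()`, `generate_outcomes()`,
`generate_guideseq()`); each generator is a pure function of its
configuration including the mandatory seed. Defaults were chosen once to
emulate the structure of the real datasets this pipeline targets:

* **Genomes**: i.i.d. bases at a target GC; empirical GC is within ~0.02 of
  the dial from 10 kb. No repeats, no codon structure, no assembly gaps —
  adequate for testing PAM scanning statistics, not for benchmarking
  aligners.
* **Screens**: 687 genes × 3 guides = 2,061 guides (the scale of the
  "mini-human" Cas12a screen), reference plus weeks 1–4, mean depth 500
  reads/guide. Planted efficiency is a logistic transform of a weighted sum
  of protospacer features (by default GC-favouring mono- and dinucleotide
  weights), scaled to 0–100. Essential genes (15% of genes, leaving ~300
  guides after the BF filter — the filtered-cohort size this regime is
  known for) deplete exponentially at rate k = 0.75; non-essential genes
  stay flat regardless of efficiency, which is exactly the confound the BF
  filter removes. Per-guide abundance skew is log-normal (sd 0.5) and
  shared across libraries, as plasmid-composition skew is in real screens;
  each library also gets independent log-normal noise (sd 0.1) for
  PCR/counting overdispersion, and counts are Poisson. Bayes Factors are
  drawn so essential genes clear the default threshold (6 + Gamma) and
  non-essential genes sit around −5. 34% of guides fall inside generated
  DNase peaks.
* **Outcomes**: 55 targets × 2,000 reads; 41% of reads edited; 63.4% of
  variant reads are SNVs; deletions outnumber insertions 1.91:1; indel
  lengths are geometric (deletion p = 0.38, making 1-nt deletions ~25% of
  indels; insertion p = 0.6), with an optional deletion-length cap of 5 nt
  to emulate the alignment-truncation artifact seen in large
  lentivirally-integrated ("synthetic"-target) datasets; SNV positions are
  multinomial with a 3× single-position enrichment at position 17; outcome
  bases are uniform over the three non-reference bases unless a planted
  rule ties the hotspot outcome to the complement of another offset.
* **GUIDE-seq**: per-mismatch cleavage probabilities (1, .9, .6, .3, .15,
  .08) — 30% of 3-mismatch predicted sites cleaved — with read decay 0.5
  per mismatch and exponentially growing predicted-site counts.

What passing tests on these data do **not** show: performance on real
screens with copy-number effects, guide-specific PCR bias beyond log-normal,
or bona fide sequence-dependent repair outcomes; the generator plants
simple, recoverable structure so that every stage's statistics can be
verified quantitatively, which is a correctness argument, not a biological
benchmark. Headline numbers published for the real datasets (validation
correlations, cohort means, observed OOB errors) depend on those datasets
and are not reproduction targets for the synthetic pipeline.

## Numerical and degenerate-input choices

* Welch t on two zero-variance equal-mean groups returns t = 0, p = 1; the
  all-tied Kruskal–Wallis returns statistic 0, p = 1 (base R returns NaN/NA).
* Zero-variance prediction or truth vectors leave correlations missing with
  a message, never 0.
* A zero insertion denominator flags the deletion:insertion ratio as `Inf`
  while t/d still compute.
* Strict `>` on the 1% SNV read-fraction filter.
* Exit codes for the command-line layer: 0 success, 2 validation failure,
  3 I/O failure; logs to stderr, data to files, every table output stamped
  with tool version, seed and a config fingerprint.

## Problem sizes used by the test suite

The shipped tests run the enumeration oracles on 100 random genomes of
0.3–2.5 kb, the screen pipeline at its default 2,061-guide preset with
cross-validation on a 300-guide subsample, outcome recovery at 100,000
reads, hotspot recovery across 50 seeds, and the permutation null guard at
50 label shuffles — sizes chosen so the whole suite completes on a single
CPU in a few minutes while keeping every statistical check well-powered.
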