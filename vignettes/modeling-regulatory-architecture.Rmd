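---
title: "Modeling cis-regulatory architecture with structural features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cis-regulatory architecture with structural features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regarch)
```

## The modelling problem

Genes co-expressed in a tissue are assumed to share regulatory inputs, and
often more: a shared *arrangement* of binding motifs in their regulatory
regions (RRs). `regarch` formalises that arrangement as binary structural
features and learns which small, weighted subset of them best separates a
positive cohort of co-expressed genes from a negative background cohort.
The fitted object is a classifier only instrumentally — its real product is
the consensus feature set, an interpretable description of the architecture
(e.g. "motif A 100–200 bp upstream on the plus strand" or "two B sites
within 100 bp of each other").

## Regions and coordinates

An RR spans `upstream` (default 1500) bp upstream and `downstream` (default
500) bp downstream of the TSS, extracted on the gene's sense strand so that
"plus strand" always means the strand read 5'→3' toward the gene body.
Coordinates are 0-based and half-open everywhere; the TSS base is the first
downstream base, at sequence offset `upstream`. Regions truncated by a
chromosome end are N-padded by default so every region has identical length
and the distance bins align across genes (`boundary = "skip"` drops such
genes instead). When several TSSs are annotated for a gene, the most
upstream survives: minimal coordinate on plus-strand genes, maximal on
minus-strand genes.

## Scanning and threshold calibration

PSSMs are log-odds matrices in bits with a pseudocount fraction (default
0.01) of the background composition added to each frequency. Rather than an
analytic p-value, the hit threshold is calibrated empirically: all positions
of a background set (default: 200 random 2000-bp regions in the bundled
pipeline wrapper; 1000 in the reference recipe) are scored on both strands,
and the threshold is the empirical quantile giving a target rate of one hit
per 5000 bp, counting the per-position best of the two strands once.

Two numerical choices matter here. First, the background base composition is
estimated from the calibration set itself rather than assumed uniform; this
reflects real genomic composition, and it also makes the empirical score
distribution fine-grained (each mismatch pattern scores slightly
differently), so the quantile can approach the target rate closely even for
highly conserved motifs whose score distribution would otherwise collapse
onto a few discrete levels. Second, the threshold is the k-th order
statistic with `k = ceiling((1 - rate) * n)` and hits are scores `>=`
threshold, so the rescan rate on the calibration set is guaranteed to be at
least the target and can exceed it only by tie mass. Degenerate requests
behave sensibly: a target rate of 1 makes every position a hit, and a target
rate below ~1/n saturates at the maximum observed score (the insufficient-
data error fires only for interior quantiles backed by fewer than
`10/target_rate` positions). Windows containing N are never scored.

Motif housekeeping follows standard practice: redundant motifs are grouped
by significant matches (externally supplied, e.g. TOMTOM, at p ≤ 0.001, or
the internal ungapped PWM correlation in `pwm_similarity()`) and each
connected component keeps its highest-information-content member. Motif
enrichment uses an over-representation index defined here as the positive /
background hit-density ratio multiplied by the fraction of positive regions
containing at least one hit; this concrete formula is this package's own
(the commonly cited definition lives in literature we do not restate), so
ORI values are comparable within `regarch` runs but not necessarily with
other tools. The conventional acceptance cutoff is ORI ≥ 2.

## The feature space

Features are enumerated per region from its hit list with 100-bp bins,
anchored at the TSS (bins `[0,100)`, `[100,200)`, … in each direction).
An alternative reading of the recipe would center the innermost bin on the
TSS; we anchor at the TSS because the bin phrasing used when reporting
features ("~100–200 bp from the TSS") only reproduces with anchored bins.
Distances are start-to-start using each hit's 5'-most sense-strand base, the
anchor the hit reporter already uses. Pairwise distances are unsigned —
relative positioning is captured separately by order features, which record
only the motif-id sequence of 2–3 hits ordered by position. TSS-distance
and pairwise features are emitted both strand-specifically and as an
either-strand generalisation, so the either-strand variant is present
whenever a strand-specific one is; the filter later keeps whichever variant
carries more information. Order features never reference more than three
motifs.

## Filtering, weighting, selection

The raw library (hundreds of features from a hundred positives) is cut down
by the classic predominance filter: rank by SU with the class, drop
SU ≤ delta (default 0), then sweep the ranking and delete any feature whose
SU with an earlier retained feature is at least its SU with the class. Ties
in the ranking break by feature index, making the filter deterministic.

Retained features get Kullback-Leibler weights,
`w(i) = Σ_j P(o_ij) D_KL(C | o_ij)`, normalised to sum to 1. Conditional
probabilities use add-1 Laplace smoothing by default so empty cells of the
2×2 table never produce log(0); `smoothing = 0` recovers the plug-in
estimate used in the hand-verifiable oracle case (balanced classes, feature
identical to class, raw weight exactly 1 bit).

The subset search is a canonical GA: chromosomes are bit vectors over the
candidate features, fitness is the AUC of the weighted-sum score on the
training folds (classification accuracy at the Youden-optimal threshold is
also available as a fitness, but AUC is the reported metric and therefore
the default objective), parents are drawn by roulette selection,
recombination is single-point at rate 0.8, mutation flips each bit with
probability 1/k, and the best chromosome survives unchanged. The search
stops when the best chromosome reaches 90% training accuracy or after
`max_iterations` generations (default 10000; the bundled tests and
acceptance script use 200, which the planted benchmarks converge well
within). Population size defaults to 100. These hyperparameters are ordinary
canonical-GA settings and all configurable.

Cross-validation is stratified fivefold. A deliberate design choice: in
nested mode (the default used by `crm_fit()`), the correlation filter and
the KL weights are re-estimated on each fold's training part, so the
held-out AUC never sees test labels through the filter or the weights. The
reference workflow could compute filter and weights on a gene set disjoint
from the model-building set, which is leak-free by construction; with a
single cohort, nesting is the honest equivalent — without it, a null cohort
would show optimistically biased held-out AUC. The deployed model reported
to the user (weights, filtered set) is then computed once on the full
matrix. Cross-validation can be repeated (`n_repeats`; the reference recipe
uses 100, the default is 1) with fresh fold assignments and GA seeds, and
the repeat with the best mean held-out AUC is kept. Features present in at
least 3 of the 5 fold-winning chromosomes form the consensus model. Folds
with no surviving features score AUC 0.5 by convention (no information).
All randomness flows from the single seed in `ga_config()`; per-repeat and
per-fold substreams are derived deterministically from it.

## Scoring and conservation

`score_genome()` scans any region set, detects the consensus features with
exactly the same enumeration code used in training, and scores each region
by its summed feature weights; ranking ties break lexicographically by gene
id. Because weights are normalised over the weighted feature space, a score
of 1 is attainable only when the consensus set is the entire weighted set.
`conservation_scan()` repeats feature detection in ortholog RRs per species;
thresholds are recalibrated against each species' own sequence when it
supplies enough scanable positions for the quantile (`recalibrate = "auto"`),
since base composition differs between genomes, and reference thresholds are
kept otherwise.

## The synthetic study generator

`generate_study()` is first-class, tested code, not a test fixture: it
defines the study conditions under which the pipeline's behaviour is
demonstrated. It emulates a cohort genome — one chromosome of contiguous
2000-bp gene blocks, each on a random genomic strand with a TSS placed so
region extraction recovers the planted sequence exactly — with i.i.d.
background sequence and a planted structural grammar. The default grammar
has three elements (M1 in upstream bin 1 on plus, M2 in upstream bin 4 on
minus, an M3 pair spaced < 100 bp on plus), planted independently per region
with probability 0.9 in positives and 0.05 in negatives: strong but
imperfect penetrance of an architecture, with realistic contamination of the
background. Default motifs are 8-bp fully conserved random consensi planted
as consensus sequences, so detection is deterministic given calibrated
thresholds; `plant_mode = "sample"` draws instances from the PFM instead for
power studies, and lower `conservation` values produce degraded motifs.
Planted instances never overlap each other, though they may coincide with
chance background matches.

What the generator does *not* emulate: real genomic base composition
(isochores, repeats, CpG-like structure), correlated motif placement beyond
the grammar, chromatin context, and alternative TSSs. Passing the planted
benchmarks therefore demonstrates that the machinery recovers a known
architecture under clean conditions at realistic cohort sizes — not that any
particular biological cohort contains one.

## Problem sizes and reproducibility

The bundled tests and the acceptance script run the full pipeline at
n_pos = 100, n_neg = 500 (2000-bp regions), calibrate on 200 random
2000-bp background regions (1000 for the dedicated calibration-rate check),
and cap the GA at 200 generations with population 100 — sizes chosen so a
complete multi-seed benchmark remains a desk-scale computation while the
statistics (binomial error of the calibration rate, fold sizes of 20/100 in
CV) stay well conditioned. Every stochastic step is seeded; rerunning any
entry point with the same seed reproduces its output exactly, including
byte-identical study files from `write_study()`.

## Known limitations

* Thresholding is empirical-quantile based; motifs whose true occurrence
  rate in real promoters differs grossly from the background model will
  have miscalibrated hit rates.
* The ORI definition is package-specific (documented above).
* Feature enumeration treats hits as points (5'-most base); motif length
  enters only through scanning, so a pair feature's bin can differ by one
  for hits near bin edges compared to center-to-center measurement.
* The GA is a heuristic; with strongly redundant feature sets the consensus
  can include correlated shadows of a true feature (visible in the worked
  example). The weights, not the GA, carry the relevance interpretation.
* Order features ignore distance entirely; widely separated hits count the
  same as adjacent ones.
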