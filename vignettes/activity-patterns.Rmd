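---
title: "Inferring and classifying TF activity across a developmental grid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and classifying TF activity across a developmental grid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ectoactivity)
```

## The problem

During cranial neurulation the embryonic ectoderm resolves into neural
plate, neural plate border, neural crest and non-neural ectoderm. RNA
abundance alone is a poor readout of a transcription factor's (TF)
contribution to these decisions: many regulators are broadly transcribed
while acting only in one domain, or are present but post-translationally
silenced. `ectoactivity` implements a pipeline that separates *transcript
level* from *downstream activity*: it scores each TF by whether its known
target program moves in a given contrast, then classifies the resulting
activity landscape across a grid of (developmental stage, cell type)
identities, relates activity sign to chromatin accessibility at the TF's
binding motifs, and screens ligand-receptor communication between the
cell types of the three germ layers.

## The model

### Contrasts: one-vs-rest log fold changes over the identity grid

Cells are QC-filtered (caps on detected genes and mitochondrial fraction),
library-size normalized to the natural-log layer
$\mathrm{norm}_{gc} = \ln(10^4 \, x_{gc} / \sum_g x_{gc} + 1)$, and grouped
into identities: observed (stage, cell type) pairs. With the default
presence pattern (an undecided pan-ectodermal population at the three
earliest stages, the neural plate border at the 4-somite stage, neural
crest from 7 somites onward, and non-neural ectoderm plus dorsal and
ventral neural domains throughout) the grid has 21 identities. Each
identity is contrasted against all other cells; a gene is reported as a
marker when it is detected in at least a fraction `min_pct` (0.25) of
cells on one side and its natural-log fold change of de-logged means
exceeds 0.2 in magnitude. Significance uses the two-sided Mann-Whitney
rank-sum test with mid-ranks and tie-corrected normal approximation
(complete enumeration for small groups), BH-adjusted within each identity.
Markers are assembled into a genes $\times$ identities LFC matrix; entries
not passing the marker filters are 0 under the default `fill_policy`
("no evidence of change"), or `NA` if the caller prefers to drop them.

### Activity: a univariate linear model against signed regulons

A regulon assigns each TF a signed weight vector $x$ over the gene
universe (+1 activating edge, -1 repressing edge, 0 for non-targets). For
each identity's LFC column $y$, the activity score is the t-statistic of
the slope of the simple regression $y = a + bx$:
$$t = r \sqrt{\frac{n-2}{1-r^2}},$$
with $r$ the Pearson correlation over the $n$ genes of the LFC universe.
A positive score means the TF's canonical program is coordinately up in
that identity; a negative score means the program is down — which may
reflect repression of the TF's activity or a non-canonical program, not
necessarily absence of the protein. TFs with fewer than `min_targets`
(5) mapped targets are not scored. Scores are only interpretable where
the TF itself is transcribed, so `retain_expressed()` masks entries whose
mean normalized TF expression is at or below 0 in that identity.

Numerical conventions: zero variance in $x$ or $y$ yields score 0 and p
1 (an all-zero LFC column carries no evidence either way); a numerically
perfect fit ($1-r^2 < 10^{-12}$) is capped at $\pm 10^6$ so toy cases
remain finite; p-values come from the Student-t tail with $n-2$ degrees
of freedom and are also BH-adjusted per column.

### Pattern classification

All thresholds below are configurable; the defaults apply strict
comparisons at every boundary.

* **Quadrants** — crossing mean expression (threshold 1, log scale) with
  activity (threshold 0) labels each unmasked (TF, identity) as
  high/low expression $\times$ high/low activity. A value exactly on a
  boundary is "low".
* **Continuous** — within one cell type, TFs whose activity stays
  strictly positive (or strictly negative) at every stage where the cell
  type exists, with expression above zero throughout; an exact zero
  disqualifies both lists.
* **Exclusive** — at one stage, activity strictly positive in exactly one
  cell type and non-positive ($\le 0$) in every other cell type present.
* **Gradient** — activity above 1 in one cell type while all neighbours
  stay inside the closed band $[0, 1]$.
* **Top/bottom-k** — per stage, TF scores averaged over that stage's
  cell types (masked entries excluded, never imputed as 0), then the k
  highest and k lowest averages, ties broken lexicographically by symbol
  so selections are reproducible.

Exclusive and gradient can only co-occur for a TF whose neighbours all
sit exactly at 0; this is the single documented overlap and is covered by
a test. Masked (non-expressed) neighbours are ignored by the exclusive
and gradient scans: the comparison runs over the scores that exist.
Selected lists can be ordered by mean expression (`rank_by_expression()`)
and tested for gene-set over-representation with a one-sided Fisher exact
test against a user-supplied GMT collection, BH-adjusted across sets.

### ATAC motif occupancy

Motif occurrences (GFF) are restricted to open-chromatin peaks with a
minimum-overlap intersection (default 5 bp) and fragments are counted per
occurrence. Intervals are held as `GRanges`; BED and GFF enter through
`rtracklayer`, which performs the coordinate-convention conversions, so a
single 1-based closed convention is used internally (a deliberate choice:
the overlap-width semantics are identical to a half-open implementation,
and the container is the ecosystem's standard). Four statistics
summarize each TF: number of occurrences, summed reads over occurrences
with strictly more than 99 reads, the maximum read count, and the mean of
the five highest counts. `compare_activity_groups()` contrasts each
statistic between positive- and negative-activity TF groups with the same
rank-sum test; the package's claim of interest is the *null* one — that
negative activity scores are not explained by inaccessible motifs — so
the test is reported per statistic without pooling.

### Ligand-receptor communication

Group expression is the Tukey trimean $(Q_1 + 2Q_2 + Q_3)/4$ with type-7
quantiles — a conservative average that stays at zero unless at least a
quarter of the group expresses the gene (this is the "high stringency"
interpretation; a truncated mean would be laxer). Multi-subunit receptors
use the geometric mean of subunit trimeans, zero if any subunit is
absent. Communication strength is the mass-action Hill form
$$P = \frac{L \cdot R}{K_h + L \cdot R}, \qquad K_h = 0.5,$$
bounded in $[0,1)$, zero when either side is silent, and saturating.
Significance permutes the cell-to-identity assignment (default 100
permutations) and uses the add-one estimator
$p = (1 + \#\{P_\text{perm} \ge P_\text{obs}\})/(1 + n_\text{perm})$, so p
is never exactly zero; zero-probability entries get $p = 1$ by
convention. Pathway heatmaps sum retained ($p < 0.05$, positive) pair
probabilities into a source $\times$ target matrix whose row and column
sums are the sender and receiver strengths. Cofactor, agonist and
antagonist modulation present in the full CellChat model is deliberately
out of scope.

## What the generator emulates — and what it does not

`generate_expression()` produces the study conditions every recovery
claim is evaluated under. Defaults: 2,000 target-pool genes, 50 TFs with
20 targets each, 100 cells in each of the 21 identities, effect size 1.5
(natural-log units on target means), 10 planted activations.

Design choices that matter for interpreting the tests:

* **Counts** are negative binomial with per-gene log-normal baselines
  (median 5 counts per gene per cell, `sdlog` 0.4), shared dispersion
  0.05, and log-normal library factors (`sdlog` 0.2). This emulates deep,
  panel-like profiles rather than shallow droplet data: fold-change noise
  stays well below the 0.2 marker threshold, so the planted truth — not
  sampling noise — is the dominant structure. Consequently the passing
  recovery tests certify the *method's logic*, not its behaviour on
  sparse 10x-depth data.
* **Identity programs**: every identity elevates 20 dedicated genes
  (disjoint from all regulons and from each other). Real identities carry
  their own transcriptional signatures, and these programs reproduce the
  one-vs-rest asymmetry that real LFC columns have (each column's mean
  marker LFC is positive). Without them, unplanted identity columns would
  be empty or pure noise and the sign of a neighbour's activity score —
  which the exclusive rule depends on — would be a coin flip.
* **Regulons are disjoint** (the generator could allow bounded target
  overlap; drawing them disjoint keeps every planted signal attributable
  to exactly one TF). 20% of edges are repressing, so sign handling in
  the scoring model is always exercised.
* **Ligand/receptor genes** sit at a near-zero baseline (0.02 counts) and
  are raised 100-fold in their planted source/receiver identity,
  emulating the spatial restriction of real signaling ligands. Entries
  whose ligand or receptor side is unexpressed therefore have probability
  0 and p = 1 by convention.
* **ATAC tables** draw per-TF occurrence counts Poisson(100) and reads
  NB(mean 30, dispersion 1); the null scenario shares all parameters
  between the activity-sign groups, the shift scenario doubles the
  positive group's read means.

The generator does not emulate UMAP geometry, pseudotime, doublets,
ambient RNA, or droplet sparsity; conclusions about those aspects cannot
be drawn from the test suite.

## Problem sizes and runtime choices

The validation suite runs the full pipeline at the default conditions
over 5 seeds for activity recovery, 20 seeded replicates for
ligand-receptor recovery and for null retention (100 permutations each),
and 100 replicates for ATAC null calibration. Property tests that sweep
effect sizes use a reduced configuration (600 genes, 10 TFs, 30 cells per
identity) — large enough for stable ordering, small enough to keep the
sweep fast; the full-size recovery rates are asserted separately at the
default conditions.

## Open choices made here

* The scoring method behind "TF activity" is the univariate linear model,
  decoupleR's current default scorer for signed regulon resources such
  as CollecTRI; it is deterministic and oracle-checkable, and is the one
  scoring method implemented here.
* The mitochondrial QC default reads "0.4%" as the fraction 0.004; it is
  unusually strict, and both QC caps are plain arguments.
* The expression-retention filter uses the per-identity *mean* of
  normalized expression (not detection fraction), threshold strictly
  greater than 0.
* Genes failing the marker filters enter the activity input as 0 by
  default (`fill_policy = "zero"`); `"missing"` drops them instead.
* The exclusive rule's neighbour condition is non-positive ($\le 0$),
  the stricter of the two natural readings of "negative in adjacent cell
  types".
* Ties in top/bottom-k selections break by TF symbol; no canonical tie
  policy exists for lollipop-style selections, and a deterministic rule makes
  outputs reproducible.

## Known limitations

* Scores for TFs with few mapped targets are unstable; the `min_targets`
  floor (5) drops them rather than reporting noise, and `n_used` is
  reported so callers can apply stricter floors.
* Cross-species symbol matching is case-insensitive with an optional
  alias table; regulon targets that do not map are simply not used and
  are counted in the diagnostics.
* Permutation p-values are lower-bounded at $1/(1+n_\mathrm{perm})$;
  with the default 100 permutations, multiple-testing control across
  thousands of (source, target, pair) entries is coarse.
* The quadrant/exclusive/gradient thresholds are fixed conventions, not
  estimated from data.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 1)
sim <- generate_expression(cfg)
em <- normalize_counts(filter_cells(sim$matrix, sim$annot,
                                    max_genes = 5500, max_mito = 1))
grid <- build_identity_grid(sim$annot)
markers <- find_markers(em, sim$annot, grid)
activity <- activity_matrix(build_lfc_matrix(markers, grid), sim$network)
expr <- mean_expression_by_identity(em, sim$annot, grid)
activity <- retain_expressed(activity, expr)
quadrants <- quadrant_classify(activity, expr, grid)
exclusive <- exclusive_active(activity, grid, "HH9_7som")
tensor <- permutation_test(em, sim$annot, grid, sim$pairs,
                           n_perm = 100, seed = 1)
```

Every number this vignette claims about recovery or calibration is
computed by the test suite (`tests/testthat/`) or by
`scripts/acceptance.R`; the vignette itself asserts none beyond them.
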