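---
title: "Methods: differential epigenetic scoring and network propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential epigenetic scoring and network propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epirank)
```

# Overview

`epirank` answers one question: *between two biological conditions, which
genes show the largest coordinated epigenetic alteration, counting both
their promoters and their distal enhancers?* The pipeline has three stages —
element scoring, network propagation, and rank-list evaluation — plus a
synthetic-data generator that makes the whole chain testable without any
external download. This vignette documents the model, its assumptions, the
parameters that matter, and the numerical and design choices behind the
implementation.

# Stage 1: element scoring

## Regions and signal

Promoters (BED with the gene id in column 4) are reduced to their midpoint,
taken as the TSS, and extended to `tss ± extension` (default 1000 bp, so
2-kb windows). Using the midpoint rather than `start − ext, end + ext` makes
the behavior identical for near-point TSS annotations and interval
promoters; an extension of 0 is treated as the identity so raw intervals can
be passed through untouched. Coordinates are 0-based half-open throughout
(the BED convention; overlap everywhere means ≥ 1 shared base).

Candidate enhancers are promoter-interacting regions (PIRs). Because
interaction catalogs pool many tissues, PIRs are filtered for tissue
activity by requiring an overlapping H3K4me1 or H3K27ac peak in at least
`min_peak_samples` (default 2) distinct samples, pooled across both
conditions. Samples are counted, not peaks: three peaks from one sample are
one unit of support. The filter refuses to run silently without peak calls —
it must be disabled explicitly (`filter_pirs = FALSE`).

Per track, each element gets the coverage-weighted sum of overlapping block
values (`value × overlapped bases`). A plain sum of block values would
depend on how a given file splits identical coverage into blocks; the
coverage-weighted sum is representation-invariant (tested by splitting
blocks and elements). Values are then rescaled to intensity per 1 kb
(`scale = 1000`, settable to `NULL`) so 2-kb promoters and variable-length
PIRs live on one scale.

## Normalization and the difference matrix

Signals are power-transformed (`x^0.5` by default — variance stabilization
for count-like coverage; the exponent is a knob in (0, 1] because no single
value is canonical) and quantile-normalized **within each mark** across all
samples of both conditions jointly (via `limma::normalizeQuantiles`, ties
receiving the mean of the reference values). Normalizing within a mark
preserves each mark's dynamic range; normalizing both conditions together
preserves the between-condition differences that are the signal of
interest. Promoters and PIRs are normalized as one element set because they
feed a single decomposition.

The difference matrix is `D[g, m] = mean_A(g, m) − mean_B(g, m)` over the
normalized values. `D` is the entire interface between the signal layer and
the decomposition: any preprocessing that produces a sensible G × M
difference matrix can be substituted.

## Differential PCA

`dpca()` is the singular value decomposition `D = B V + E` with `B = U S`
(element coordinates) and orthonormal loading rows `V`. Two deliberate
choices:

* **No column centering by default.** Rows of `D` are already differences;
  the magnitude of change — not the deviation from the average change — is
  the quantity of interest. Centering is available as a flag.
* **No inferential layer.** Only the component coordinates are used
  downstream; standard errors or significance calls on components are out
  of scope.

Signs are stabilized by making the largest-magnitude loading of each
component positive; since element scores are `Σ_{r≤k} |B[g, r]|`
(default `k = 2`), the ranking is sign-agnostic anyway. With six marks the
first two components typically absorb the coordinated activating and
repressive changes, which is why `k = 2` is the default; `k` is exposed as
`n_dpcs`. Ties among singular values make the individual components
non-unique — every property tested (absolute coordinate sums, variance
explained, reconstruction, energy) is tie-safe.

Numerical contracts, enforced in the test suite: `B V` reconstructs `D` to
1e-8 relative Frobenius error, `Σ s_r² = ‖D‖²_F` to 1e-6 relative, variance
explained sums to 1 ± 1e-9. An all-zero `D` yields a defined result (zero
scores, zero variance explained, with a warning) rather than an error.

# Stage 2: network propagation

Promoters and retained PIRs become vertices of a directed graph with edges
PIR → promoter and vertex weights equal to the element scores. Two linkage
modes:

* `linkage = "interactions"`: an edge whenever one anchor of an interaction
  record overlaps a PIR and the other overlaps an extended promoter, in
  either anchor order; duplicates collapse to one edge. Records matching
  nothing are dropped and counted.
* `linkage = "nearest"`: each PIR links to the promoter with the nearest
  TSS (by PIR midpoint), ties toward the lower coordinate — the
  conventional fallback when no interaction data exist.

PIRs that end up linked to no promoter are excluded from the graph (they
could only hoard restart mass); isolated promoters are kept so every gene is
ranked.

Scores are propagated with personalized PageRank (igraph) using the
weight-proportional restart vector `p(v) = w(v)/Σw`. Dangling vertices —
promoters, which have no out-edges — hand their mass back according to `p`,
not uniformly, keeping the stationary distribution a function of the element
weights alone; the test suite pins this behavior against an independent
dense power-iteration oracle (agreement to 1e-9 on exhaustive small-graph
families, mass conservation to 1e-9). The damping factor defaults to the
classical 0.85 and is exposed (`damping`); within (0, 1) it trades off how
far enhancer mass travels versus how strongly the restart weights dominate.

The meta-gene score is the summed PageRank of a gene's promoter vertices
(sum keeps gene-level mass conservation; `gene_agg = "max"` is available).
Ranking is by descending score with deterministic lexicographic
tie-breaking. The promoter-only baseline ranks genes by their promoter
element scores without propagation; on an edgeless graph the two rankings
provably coincide (PageRank reduces to the normalized restart vector), which
is tested.

# Stage 3: evaluation

For a gene set `G` and a ranked list of N genes, the enrichment curve is
`eCDF_G(k) = Σ_{i≤k} δ_i / |G|` and its AUC is the mean of that step
function over k = 1..N — algebraically `1 + 1/N − mean_rank/N`, an identity
the tests enforce to 1e-12. Step integration (not trapezoidal) was chosen;
the two differ by O(1/N) and the closed form above makes the convention
explicit. Set genes absent from the ranked universe are excluded from `|G|`
rather than counted as failures, because curated sets are routinely larger
than any one ranked universe; the exclusion count is logged. A uniformly
random set has expected AUC `(N+1)/(2N)`; the Monte-Carlo calibration check
in the acceptance suite verifies this within three standard errors.

The rewiring null rewires the graph by double-edge swaps (default
`10 × |E|` attempts per permutation) that preserve every out- and in-degree
exactly, then recomputes PageRank, the ranking, and the set's AUC. The
empirical p-value uses the +1 correction `(1 + #{null ≥ obs})/(1 + n_perm)`
so it is never exactly zero. A drop of the observed AUC relative to the null
mean indicates the enrichment depends on the actual wiring, not on the
degree sequence.

# The synthetic epigenome

`simulate_epigenome()` emulates the study design end to end: two conditions
× `samples_per_condition` (default 3) samples × six marks (four activating,
two repressive) of nonnegative block signal over a toy genome. Genes are
placed on a 2-kb slot grid at 20-kb spacing; each gene draws
Poisson(`pirs_per_gene`, default 5) PIRs uniformly within ±1 Mb of its TSS
(real promoter-interaction networks average ~21 interacting fragments per
promoter with a long tail; 5 keeps desk-scale runs fast while preserving the
topology). Baseline intensity is lognormal per element × mark (log-mean
log 10, log-sd 0.5) times per-sample lognormal noise of log-sd `noise_sigma`
(default 0.3) — coverage-like, nonnegative, right-skewed. At a
`marker_fraction` (default 0.1) of genes, condition-A values of activating
marks are multiplied by `effect_size` (default 4) and repressive marks
divided by it, at the promoter, the linked PIRs, or both (`marker_mode`);
effects are multiplicative and applied before the power transform, as
fold-changes would be in real data. `effect_size = 1` plants nothing and is
the null configuration. Peak calls for H3K4me1/H3K27ac are emitted wherever
a track value exceeds that track's median, so the PIR support filter passes
by construction for all but constitutively weak elements — the filter, not
peak calling, is what is under test.

What the generator deliberately does **not** emulate: nucleosome-level
signal shape, read-level noise, batch or replicate covariance structure,
overlapping regulatory elements, many-to-many gene–promoter annotation, and
enhancers shared between genes. Passing tests therefore demonstrate that the
statistical machinery recovers planted multiplicative signal under
idealized, independent lognormal noise — not that it is robust to every
artifact of real ChIP-seq.

# Problem sizes and runtime choices

The test and acceptance workloads use 200-gene studies (≈ 1,200 elements ×
36 tracks) for recovery and sensitivity checks, a 1,000-gene study with 500
random sets of size 50 for AUC calibration, 20 replicates for the
enhancer-sensitivity rate, and 200 permutations for the rewiring null —
sizes at which every stage is exercised at full fidelity while a complete
run of suite plus acceptance script stays in the minutes range on one CPU.

# Known limitations

* Two-condition designs only; condition labels are fixed to `A`/`B` and
  `D = mean(A) − mean(B)`.
* Vertices are weighted, edges are not; interaction frequency or confidence
  is not modeled.
* Strand is ignored everywhere; no liftover between genome builds.
* Replicate variance enters only through condition means; no moderated
  variance modeling.
* The ECDF/AUC statistic is unweighted (every set gene counts equally).
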