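---
title: "Imputing chromatin traces: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing chromatin traces: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traceimpute)
```

## The problem

Chromatin tracing images the 3D positions of consecutive genomic loci in
single cells, one chromosome copy at a time. Detection is incomplete: half to
ninety percent of probes can be missing in a copy, and the missing pattern
differs from cell to cell. Because most analyses (clustering, insulation,
compartments, loops) consume the full pairwise structure, undetected loci
contaminate everything downstream. `traceimpute` fills both the missing
proximity-score entries and the missing 3D coordinates.

## Data model

A trace is an ordered set of loci with genomic intervals (0-based half-open,
BED convention) and an $N \times 3$ coordinate matrix in micrometres;
undetected loci are a boolean mask, never sentinel values. Distances
$D_{ij}$ are Euclidean and `NA` whenever either locus is undetected.
Proximity scores are $K_{ij} = \exp(-D_{ij}^2/\sigma^2)$.

Two conventions for the kernel exist in the field: the exponential form
above, and a half-decay form $2^{-D^2/\sigma^2}$ under which a pair exactly
$\sigma$ apart scores 0.5 rather than $e^{-1} \approx 0.368$. Both are
implemented (`half_decay` in `proximity()`); the exponential form is the
default. The bandwidth $\sigma$ defaults to the median of all observed
distances pooled over the supplied matrices. Whether to pool per cell, per
cell type or per dataset is genuinely open; pooling everything is the most
stable at small sample sizes and is what `trace_impute()` does unless a
`sigma` is passed.

## Structure similarity

Similarity between two copies is the RMSD after superposition restricted to
the loci detected in both. The superposition solves the *orthogonal*
Procrustes problem — reflections are permitted, which is deliberate: the
metric asks how congruent two shapes are, and microscopy coordinate systems
do not share a handedness guarantee. The solution is the classical SVD of the
cross-covariance of the centred sets; an independent brute-force
rotation-search oracle and `vegan::procrustes` cross-check it in the tests.

RMSD over a tiny overlap is spurious — three points can always be superposed
almost perfectly — so pairs with fewer than `min_overlap` shared detected
loci (default 10) are *incomparable*: they return `NA` and are excluded from
neighbor candidacy rather than being assigned a penalty value. At the
desk-scale study conditions used in the tests (60-locus panels masked to
80%), the expected both-detected overlap is $N(1-r)^2 \approx 2.4$ loci, so
the benchmarks lower the gate to 3, the smallest overlap with a
non-degenerate 3D alignment. This is a scale adaptation, not a tuning knob:
at the native scale of real panels (hundreds to thousands of loci) the
default gate is essentially never binding.

## Neighborhoods

Modes 1–2 first cluster cells on RNA counts (total-count normalisation,
log1p, PCA, kNN graph, Louvain at a fixed seed; precomputed labels always
take precedence) and only consider neighbors within a cluster; mode 3 ranks
all copies. The `m_fish = 100` smallest-RMSD candidates are averaged
entrywise on the *proximity* scale — averaging matrices rather than
coordinates avoids alignment artifacts and is exactly what the next step
consumes. FISH averages use measurement semantics (absent is missing; an
entry is missing only if missing in every neighbor), Hi-C averages use count
semantics (absent is zero).

Mode 1 embeds single-cell Hi-C by PCA on log1p counts of short-range entries
(bin separation ≤ 30, where single-cell contacts concentrate), takes the
`m_hic = 10` nearest cells in that space, averages their contact matrices,
and joins them to FISH cells through the externally supplied pairing table.
The choice of a PCA embedding is a documented stand-in: cross-modal
integration itself is out of scope here and its result is consumed as a
table.

## Stratified imputation

All fitting happens per genomic-distance stratum $v$ (pairs $j - i = v$),
because both FISH proximity and Hi-C contact frequency decay with genomic
distance and the exchange rate between them is distance-specific. Within a
stratum, the observed part of each source and the missing part of each
source are separately normalised to unit sum. On the observed pairs the
weights solve

$$\min_{a,b} \sum (a P_{nH} + b P_{nF} - P_{FISH})^2
\quad \text{s.t. } a \ge w_{bound},\ b \ge 0,\ a + b = 1.$$

With $b = 1 - a$ this is a one-dimensional bounded quadratic with a
closed-form clamped minimiser — identical optimum to an iterative
sequential-quadratic solver, but deterministic and exactly testable against
a grid search. Modes 2–3 fix $a = 0$ and solve the nonnegative
one-dimensional least squares for $b$ alone.

The Hi-C weight bound $w_{bound} = 0.4$ applies only for $v \le k$, where
$k$ maximises the Spearman correlation between the merged Hi-C and FISH
matrices over pairs with separation up to $k$ (smallest $v$ on ties); beyond
$k$ the bound is 0, letting the fit discard uninformative long-range Hi-C.

Missing entries receive $a P_{nH} + b P_{nF}$ (mode 1) or $b P_{nF}$
(modes 2–3), rescaled by an estimate of the stratum's missing total: the
observed FISH total divided by a proportion-of-observed, minus itself. The
proportion pairs each weight with its own modality's observed fraction.
Observed entries are returned bit-identical; imputed entries are clipped to
$[0,1]$.

Three degenerate situations need explicit policies at small $N$ that never
arise at the native scale of thousands of loci:

* a stratum with *no observed pairs* uses sentinel weights
  ($a = w_{bound}$, $b = 1 - w_{bound}$ in mode 1; $b = 1$ otherwise) and
  estimates its total from the cell's global ratio of observed FISH signal
  to neighbor signal, flagged in the weight table;
* a *single entry* covered by no neighbor takes the mean neighbor signal of
  its stratum part before normalisation — a hard zero there would
  systematically understate proximity;
* the imputed profile is used exactly as combined, without renormalisation,
  before rescaling.

## Coordinate inference

Proximity scores scaled by $c = 100$ and rounded half-away-from-zero act as
Poisson counts $k_{ij}$ with rate
$\lambda_{ij} = c\,\exp(-\|X_i - X_j\|^2/\sigma^2)$. The negative
log-likelihood $\sum \lambda_{ij} - k_{ij}\log\lambda_{ij}$ (the constant
$\log k!$ term cannot move the optimum and is dropped) is minimised over the
coordinates of the *undetected* loci only, over all pairs with at least one
undetected endpoint — anchoring against detected loci is what makes the
problem identifiable. Scaling counts and rate by the same $c$ keeps the two
sides of the model consistent; the scale itself is nearly irrelevant to the
argmin (checked in the tests by comparing $c = 50$ and $c = 100$).

Numerical choices: initialisation from genomic-position-weighted linear
interpolation (deterministic); box bounds equal to the detected bounding box
expanded by 50% of its width per axis (degenerate flat boxes get at least
$\sigma$ of room); $\lambda$ floored at $10^{-10}$ inside the logarithm;
analytic gradient
$\partial/\partial X_i = \sum_j (2/\sigma^2)(k_{ij}-\lambda_{ij})(X_i - X_j)$
(the $k/\lambda$ ratio cancels, so it is finite everywhere), verified by
finite differences at $10^{-5}$; L-BFGS-B with projected-gradient tolerance
$10^{-6}$ and at most 500 iterations, all configurable. Detected loci are
returned bit-identical.

## Downstream analytics

The insulation score of a boundary is $(\text{intra} - \text{inter}) /
(\text{intra} + \text{inter})$ over fixed windows, with the diagonal
excluded from intra (its constant 1 would bias every window equally).
Compartments divide the proximity matrix by an expected decay fitted as a
log-log linear regression of stratum means, correlate, and split bins by the
sign of the first eigenvector; the sign is oriented so bin 1 is positive —
the biological A/B orientation (gene density, etc.) is out of scope. Loop
calling tests each pair in the 100 kb–1 Mb span band against its pooled
±250 kb neighborhood with a one-sided Welch t-test (a loop is *closer* than
its neighborhood; the sidedness is our documented choice), adjusts by
Benjamini–Hochberg at FDR 0.1, groups candidates by 8-connected adjacency in
pair space, and reports the lowest-q member of each cluster as its summit.
The neighborhood half-width is configurable because its exact definition is
inherited folklore rather than a fixed rule. Clustering features flatten each
cell's proximity matrix and normalise it to unit sum before PCA: cell types
differ in the *pattern* of proximity, while the overall level mixes detection
depth with the per-stratum estimation noise of imputation and is treated as a
nuisance, in the same spirit as the ratio-to-total decay features.

## The synthetic generator

`generate_multimodal()` emulates the joint structure of a multimodal
chromatin-tracing study at desk scale. One confined AR(1) random-walk chain
per bundle is the shared genome backbone; each cell type applies its own
compartment-block attraction (alternating A/B blocks of 10 loci pulled
toward their compartment centroid), and types beyond the first switch a
small number of blocks (`flip_blocks = 2`) — mirroring the observation that
related cell subtypes share most 3D organisation and differ in localised
regions. Cells are per-locus jitters of their type backbone under a random
rigid motion; Hi-C cells are *independent* jitters of the same backbone with
Poisson-sampled counts proportional to proximity; RNA counts are negative
binomial with type-specific marker genes; the pairing table links same-type
cells.

The default geometry (`step_sd = 0.8`, `confinement = 0.75`,
`jitter_sd = 0.3`) places the median pairwise distance near 1.4–2 µm and
makes the chain rough at the bin scale — the regime of 1 Mb-resolution
tracing, where naive linear interpolation along the genome is a weak
baseline. What the generator deliberately does *not* model: loop-extrusion
dynamics, locus-specific detection efficiencies beyond an optional bias
profile, trans-chromosomal contacts, and doublet/ambient artifacts in RNA.
Passing benchmarks on these bundles therefore demonstrates correctness and
the qualitative orderings (imputation beats interpolation, imputed features
cluster better), not quantitative performance on any real dataset.

Problem sizes in the tests and the acceptance script — two types of 100
cells over 60 loci, masked at 50/60/70/80% following the standard protocol
(keep copies below 30% missing, mask uniformly to the target rate) — were
chosen so the whole suite runs in minutes on a laptop while keeping every
stage of the method exercised at realistic missingness.

## Known limitations

* At very high missing rates the RMSD ranking itself degrades (few shared
  loci), so mode 3 neighborhoods blur across cell types; modes 1–2 are
  preferred whenever RNA or Hi-C is available, matching the method's own
  motivation.
* The per-stratum totals are estimated from few observed pairs when $N$ is
  small; the sentinel/global-ratio fallbacks keep the estimate finite but
  noisy strata remain noisy.
* Imputed coordinates inherit the population-average geometry encoded in the
  neighbor matrices; cell-specific deviations at undetected loci are not
  recoverable and no uncertainty is attached to inferred positions.
* Everything is per-chromosome; joint multi-chromosome inference is out of
  scope.
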