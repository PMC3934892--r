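---
title: "Perceptually grounded comparison of color-naming charts: models and methods"
author: "chartmetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perceptually grounded comparison of color-naming charts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chartmetrics)
```

## The problem

Color-naming surveys in the World Color Survey (WCS) tradition show every
speaker a fixed chart of Munsell chips — 320 maximally saturated chromatic
chips arranged by hue and lightness plus 10 achromatic grey-scale chips —
and record the term used for each chip.  The usage of one term is a
*chart*: a vector indexed by chips, 0/1 for a single speaker, summed counts
for a language.  Most statistical questions about color naming (which
terms are similar across languages?  what clusters of naming patterns
exist?) reduce to choosing a dissimilarity between charts.

The trap is that the obvious choices — Euclidean distance between chart
vectors, or Pearson correlation of their entries — treat chips as
exchangeable coordinates.  Both are invariant under any permutation of the
chips applied to both charts, so they cannot see that Red is closer to
Pink than to Green.  They behave reasonably while two charts overlap and
collapse to a near-constant as soon as the supports are disjoint, no
matter whether the supports are perceptual neighbors or opposites.  This
package implements the alternatives that keep the perceptual geometry in
view, together with a simulator that makes every claim testable end to
end without any external data.

## The stimulus space

`wcs_grid()` builds the 330-chip chart (rows A–J from light to dark;
column 0 is the grey axis; rows B–I × columns 1–40 are chromatic).
Perceptual positions come from CIELAB, where Euclidean distance
(ΔE, the 1976 definition) approximates perceptual dissimilarity:

$$\Delta E_{ij} = \sqrt{(L_i-L_j)^2 + (a_i-a_j)^2 + (b_i-b_j)^2}.$$

`synthetic_lab_coordinates()` supplies a synthetic Lab table with the
qualitative geometry of the real chart: lightness linear in the row (95
down to 15 by default), chromatic chips on a hue circle of radius 40
(CIELAB chroma typical of saturated chips), hue angle $2\pi(c-1)/40$ for
column $c$, grey chips at $a = b = 0$.  Only ΔE76 is implemented —
the perceptual refinements ΔE94/ΔE2000 are deliberately out of scope.
Measured chip coordinates (e.g. the WCS `cnum-vhcm-lab-new` table,
reformatted to `chip_id / L / a / b` TSV) can be loaded with
`load_lab_table()` and override the synthetic ones everywhere.

## Ground-metric-aware distances

**Earth Mover's Distance.**  Charts are piles of mass over chips; the EMD
is the minimum work (mass × ΔE) to turn one pile into the other:

$$\mathrm{EMD}(P,Q) = \min_{f \ge 0} \sum_{ij} f_{ij}\,\Delta E_{ij}
\quad\text{s.t. } \textstyle\sum_j f_{ij} \le P_i,\;
\sum_i f_{ij} \le Q_j,\; \sum_{ij} f_{ij} = \min(|P|,|Q|),$$

divided by the total flow.  Charts are normalized to unit mass by default
(language vectors have wildly different totals; a flag disables this).
The transportation problem is solved exactly in compiled code by
successive shortest augmenting paths with Johnson potentials.  Two
numerical choices matter.  First, zero-mass bins are dropped, so the LP
size is the product of the support sizes, not $330^2$.  Second, regular
stimulus grids make many chip distances exactly equal, and such tied
instances can drive degenerate augmenting-path solvers into pathological
phase counts; the solver therefore adds a deterministic per-arc
perturbation of relative size $10^{-11}$ (and re-sums the optimal flow
under the unperturbed costs, so the reported value is exact to well below
every tolerance used in the package).  The test suite pins the solver
against two independent oracles: the closed-form EMD for 1-D histograms
under the line metric (the L1 distance of the CDFs) and a generic
two-phase simplex solution of the same LP.

Because the EMD needs only a chip-to-chip distance matrix, it extends to
charts collected on *different* stimulus sets: `cross_support_emd()`
accepts a rectangular ΔE matrix between the two chip sets, which is how
datasets from different elicitation designs can be compared on one scale.

**Quadratic χ².**  A cheaper cross-bin distance.  With a chip similarity
matrix $A$ and normalizer exponent $m$,

$$Z_i = \Big(\sum_c (P_c + Q_c) A_{ci}\Big)^m, \qquad
\mathrm{QC}^A_m(P,Q) = \sqrt{\sum_{ij}
  \frac{P_i - Q_i}{Z_i}\,\frac{P_j - Q_j}{Z_j}\, A_{ij}},$$

with the convention $0/0 := 0$.  $A = I$, $m = 0$ recovers plain
Euclidean distance (a unit-tested identity).  The default $m = 0.9$ is the
value recommended by the distance's authors; it attenuates differences in
heavily used regions, which in practice penalizes rarely used terms —
visible in the rankings below.

**The similarity kernel.**  Both QC and the de-correlation transform use
the exponential similarity matrix

$$K_{ij} = \exp(-\Delta E_{ij} / \sigma).$$

σ (CIELAB units) controls how far perceptual credit extends.  The default
σ = 30 makes off-diagonal similarities span roughly 0.03–0.81 on the
synthetic table — a wide spread of values, neither saturated nor
vanishing; it is configurable everywhere it appears.  The exponential of a
Euclidean metric is positive semidefinite; `similarity_matrix()` attaches
the numerically smallest eigenvalue as a diagnostic (≈ +0.099 on the
synthetic 330-chip table).

## The de-correlation mapping

Perceptually close chips elicit correlated responses.  The kernel $K$
models exactly that expected correlation, and factoring it as
$K = R^\top R$ (Cholesky; upper-triangular $R$ fixed for determinism)
yields a linear map $x \mapsto Rx$ under which the kernel bilinear form
becomes the canonical inner product:

$$\langle Rx, Ry\rangle = x^\top K y, \qquad
\|Rx - Ry\|_2 = \sqrt{x^\top Kx - 2x^\top Ky + y^\top Ky}.$$

After the transform, *classical* tools — k-means, PCA, anything built on
Euclidean geometry — are implicitly ΔE-aware: two disjoint single-chip
charts land close together exactly when their chips are perceptually
close.  Note the factorization must be applied to the *similarity*
matrix: a distance matrix is not positive semidefinite and admits no such
factor.  If the kernel is numerically borderline, a single retry with
jitter $10^{-10} I$ is attempted before failing with the offending
eigenvalue.

## Matched-restart k-means and the hierarchy

`kmeans_restarts()` runs Lloyd's algorithm from `restarts` random
initializations (uniform choice of data points; k-means++ behind a flag),
keeps the best-inertia solution, and reports *stability*: the fraction of
restarts whose centroid set coincides with the best run's after optimal
matching (assignment problem, solved exactly by dynamic programming over
column subsets; the restart-agreement tolerance is a relative L2 of
$10^{-6}$, since floating point makes "exact same centers" meaningless).
Empty clusters during Lloyd iterations are re-seeded at the point farthest
from its assigned centroid, preferring points distinct from all current
centers — this is what lets duplicated initial centers escape to uncovered
regions and is the mechanism behind perfect restart agreement on cleanly
separated data.

`cluster_hierarchy()` runs this independently for each $k$ in a range and
reads the sequence left to right, matching each level's centroids into the
next level's by optimal partial assignment (*persistence links*).  The
pathology the de-correlation is meant to cure is clusters *splitting and
re-merging* as $k$ grows.  We flag it at the level of cluster centers: an
event is a centroid present at some level, *absent* at a later level (no
centroid within 1% of the overall centroid diameter), and *present again*
at a yet later level.  A well-behaved hierarchy has none: centers persist
once picked, and coarse centers that dissolve never return.  We
deliberately do **not** flag mere membership regrouping between
consecutive levels: when the data hold, say, eight true clusters and
k-means is forced to 3, the optimal coarse partitions are balanced groups
whose boundaries shift as $k$ grows even for a perfect metric — that is an
artifact of under-specifying $k$, not the vanish-and-reappear behavior the
flag is for.  The detector is unit-tested on a hand-built pathological
hierarchy.

Cluster contents are displayed with `cluster_sum_charts()` — entrywise
sums of the *untransformed* charts per cluster, rendered by
`render_chart_grid()` as the Munsell chart with darker cells for higher
values — so results are inspectable in response space even though the
clustering ran in the transformed space.

## The simulator and what it does (and does not) emulate

`simulate_responses()` emulates WCS-style elicitation with known ground
truth.  Terms have focal chips; each speaker names *every* chip with
exactly one term, drawn with probability
$\propto \exp(-\Delta E(\text{chip}, \text{focal})^2 / T^2)$.  The
*temperature* $T$ (CIELAB units) is the boundary softness: $T = 0$ is
deterministic nearest-focal (Voronoi) naming; the default $T = 10$ blurs
boundaries by roughly one to two hue columns (the synthetic hue step is
about 6 ΔE), which is a realistic amount of inter-speaker disagreement —
region cores are stable, boundary chips are genuinely ambiguous.  In
`ring` mode the focals sit at equally spaced hue columns of a
middle-lightness row, so each term has two hue-adjacent terms and one
antipodal term *by construction* — the geometry needed to probe adjacency
rankings.  Defaults: 8 terms, 20 speakers.

Two consequences of the geometry are worth knowing.  The grey chips are
equidistant from every ring focal, so they are named uniformly at random
at any positive temperature — a faithful miniature of why analyses that
restrict to chromatic patterns exclude charts touching the achromatic
column (`filter_achromatic()`).  And the ring is rotationally symmetric,
so forcing k-means below the true term count produces arc partitions that
are optimal only up to rotation; restart agreement below $k =$
`n_terms` is accordingly low, and only the full-$k$ solution is unique.

What the simulator does *not* model: non-responses, synonym competition,
salience differences, orthographic variation, or the frequency imbalance
of real lexicons (term frequencies differ here only through boundary
noise).  Tests passing on this synthetic data therefore validate the
*machinery* — solver exactness, transform identities, restart matching,
ranking logic — and the qualitative geometry of the claims, not any
quantitative statement about real WCS languages.

## The two study conditions used by the validation suite

*Clustering condition* — ring, $T = 2$ (small: chromatic naming is
essentially deterministic, so each term's surviving charts are exact
duplicates), achromatic exclusion, de-correlation, $k = 8$, 100 restarts.
Expected outcome, and what the tests assert: stability 1.0, exact
recovery of the generating partition, and zero split-and-re-merge events
across $k = 2..8$.

*Ranking condition* — ring, $T = 5$.  At this temperature the term
supports are *nearly disjoint*, which is precisely the regime where
permutation-invariant metrics lose the adjacency signal: all seven
non-reference terms sit at essentially the same Euclidean distance and
sampling noise decides their order, while EMD, QC and the de-correlated
Euclidean distance still see that hue-adjacent terms are 30 ΔE away and
the antipodal one 80.  (At the default $T = 10$ the supports overlap at
the boundaries and even raw Euclidean distance ranks neighbors first —
consistent with the observation that permutation-invariant metrics only
fail once responses are disjoint.)  The suite asserts that EMD, QC and
the de-correlated ranking place both hue-adjacent terms before the
antipodal term on every tested seed, and that raw Euclidean fails this on
at least one.

## Worked example

```{r example}
grid <- wcs_grid()
lab <- synthetic_lab_coordinates(grid)
D <- ground_distance_matrix(lab)
K <- similarity_matrix(D)

cfg <- simulation_config(n_terms = 8, n_speakers = 20, temperature = 5,
                         seed = 3)
focals <- generate_focal_points(grid, lab, cfg)
rt <- simulate_responses(grid, lab, focals, cfg)
lv <- language_response_vectors(speaker_response_vectors(rt, grid))

# t2 and t8 are the hue neighbors of t1; t5 is antipodal
head(rank_by_distance("synth:t1", lv, "emd", D = D), 4)
head(rank_by_distance("synth:t1", lv, "euclidean"), 4)
```

```{r cluster-example}
sv <- filter_achromatic(speaker_response_vectors(
  simulate_responses(grid, lab, focals,
                     simulation_config(temperature = 2, seed = 11)),
  grid), grid)
X <- apply_decorrelation(factor_similarity(K), sv)
res <- kmeans_restarts(X, 8, restarts = 100, seed = 5)
res$stability
table(res$assignments, sv$info$term)
```

## Numerical choices and limitations

* Problem sizes in the validation suite: EMD oracle batteries use 200
  8-bin and 200 6-bin pairs; metric axioms 500 sparse triples over the
  full 330-chip geometry; clustering 100 restarts for each $k$ in 2–8 on
  ~50 charts.  These sizes exercise every code path while keeping the
  whole suite in the tens of seconds.
* The exact assignment solver for centroid matching is exponential in
  $k$ (bitmask DP) and capped at 16 columns — ample for the $k \le 11$
  hierarchy range it serves.
* Ties: nearest-chip projection and nearest-focal naming break ties by
  lowest index; Lloyd assignment by first centroid.  All stochastic entry
  points take explicit seeds and are reproducible bit for bit.
* The EMD here uses a dense flow formulation suited to desk-scale chip
  counts (hundreds of bins); computing, say, a full distance matrix over
  thousands of language vectors is a batch-computing exercise outside
  this package's scope.
* `centroid_representative()` implements the classical single-chip
  reduction (speaker means, then language mean, projected to the nearest
  chip) for comparison purposes; the package's position is precisely that
  distribution-level analysis should be preferred to it.
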