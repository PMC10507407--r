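---
title: "Methods: interactome topology and colony morphometry in osteonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interactome topology and colony morphometry in osteonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteonet)
```

osteonet implements two analysis tracks that together position a
candidate protein — the motivating case is desmin in bone-marrow stromal
cells — within an osteogenic signalling context: topological analysis of
a confidence-filtered protein–protein interaction (PPI) network, and
morphometry of cell colonies in differentiation assays, with the
classical inferential tests used alongside. This vignette states the
models, the conventions, the tunable parameters with their defaults, and
the limits of what the synthetic-data tests demonstrate.

## The network model

A network is a **simple undirected graph**: protein nodes with a
seed/partner provenance, and edges carrying a STRING-style combined
confidence score in [0, 1] (the 0–1000 integer export dialect is
normalised by 1000 on input). Self-loops are dropped, duplicate pairs
collapse to the maximum score, identifiers are whitespace-trimmed and
case-sensitive.

Three preprocessing conventions matter:

* **Confidence filtering** keeps edges with score ≥ `min_score`
  (default 0.9, the conventional "very high confidence" level). The
  comparison is inclusive because the threshold names the confidence
  level itself. Filtering is idempotent and monotone; nodes isolated by
  the filter are retained but flagged (`isolated_nodes()`), leaving
  their fate to the caller.
* **Connected-core reduction** replaces the interactive practice of
  re-running a database query at progressively fewer interactors until
  the graph forms one uninterrupted chain. `reduce_to_connected_core()`
  makes this reproducible: non-seed nodes are removed greedily in
  increasing-degree order (lexicographic tie-break) while the induced
  subgraph remains a single connected component containing every seed,
  stopping at `max_partners` retained non-seeds or when no removal
  preserves connectivity. A deterministic greedy rule was chosen over
  fidelity to an unrecorded manual procedure; the endpoint of interest
  (a connected, seed-complete core of bounded size) is guaranteed by
  construction.
* Distances are **hop counts**: the combined score is a confidence, not
  a length, so edges are unweighted in every index.

## Topological indices

For a node $v$ with degree $k(v)$:

* **Betweenness** $BC(v) = \sum_{\{s,t\}, s \ne v \ne t}
  \sigma_{st}(v)/\sigma_{st}$, summed over unordered pairs, endpoints
  excluded, pairs in different components contributing zero. Computed
  with the standard single-source accumulation (Brandes) algorithm;
  reported **unnormalized** (raw pair fractions) with a normalized
  variant ($\div (n-1)(n-2)/2$) alongside, since tools differ in
  convention and the unnormalized value is taken as canonical here.
* **Eccentricity** $Ecc(v)$ is the maximum hop distance to any node of
  $v$'s component (0 for an isolated node).
* **Closeness** $CC(v) = (n_c - 1) / \sum_u d(v, u)$ within the
  component of size $n_c$ (0 for an isolated node). The harmonic
  alternative for disconnected graphs is deliberately not used; instead
  each node's component is reported so consumers can exclude
  fragments.
* **Local clustering** $C(v) = 2T(v)/(k(v)(k(v)-1))$ with $T(v)$ the
  edge count among neighbours; $C(v) = 0$ when $k(v) < 2$. The global
  **Acc** is the plain mean over all nodes, so low-degree nodes drag the
  mean down — the common tool default, documented because it changes
  the value.

The test suite checks every index against an oracle that never runs the
package's own traversals: hop distances and geodesic counts are read off
powers of the adjacency matrix ($\sigma_{st} = (A^{d(s,t)})_{st}$, and a
node lies on a geodesic iff $d(s,v) + d(v,t) = d(s,t)$, contributing
$(A^{d_1})_{sv} (A^{d_2})_{vt} / \sigma_{st}$), and triangles come from
$\mathrm{diag}(A^3)$. Ten thousand random connected graphs on up to 7
nodes agree to $10^{-9}$, alongside closed forms for paths, stars,
cycles and complete graphs.

## Roles: hubs, bottlenecks, backbone, upstream signal

Hubs are the top `fraction` (default 0.10) of nodes by degree,
bottlenecks the top fraction by betweenness. The decile size rounds
**up** (⌈0.10·24⌉ = 3) and ties at the cutoff expand the set: floor
rounding on 24 nodes could select only 2, which cannot represent three
proteins sharing top-decile degree. Ranks use competition ranking.

A node is flagged as an **upstream/early signal** when it combines
hub-grade degree with peripheral information flow: betweenness below
the network median, eccentricity strictly above the median, closeness
strictly below the median. The qualitative pattern ("high k but low BC,
high Ecc, low CC") is operationalized as strict median comparisons —
the plainest cutoff that needs no extra parameter; medians are computed
over all nodes and the fraction is configurable.

The **backbone** is the union of hubs and bottlenecks, minus any
upstream-signal node (default `exclude_upstream_from_backbone = TRUE`).
This resolves a real tension in the role taxonomy: a protein can carry
top-decile degree yet sit upstream of both arms of the main pathway, and
reporting it inside the backbone would misstate its role as an
initiator that feeds the backbone. The plain union remains available by
flag.

## Colony morphometry

Segmentation is deliberately simple and fully deterministic: threshold
(`intensity_threshold`, default 0.3 on [0, 1] intensities, colonies
bright on dark), fill interior holes (4-connected background components
not touching the border), label 8-connected components, and discard
components below `min_area` (default 50 px) as speckle. Pixel labeling
runs as connected components of the 8-neighbour pixel graph.

**Area** is the pixel count (convertible to µm² via `pixel_size`).
**Perimeter** is measured on the outer boundary traced by
Moore-neighbour following, then simplified by a dominant-point
(Douglas–Peucker) pass at 1 px tolerance before summing segment
lengths. The tolerance is the key numerical choice: the raw 8-connected
chain (axial steps 1, diagonal √2) systematically overestimates smooth
perimeters by about 5 % (staircase quantization), which would bias a
disk's isoperimetric quotient down to ≈ 0.91; a 1 px tolerance absorbs
staircase excursions (amplitude ≤ ~0.7 px) while preserving true
corners, whose deviation grows without bound. On reference shapes this
yields disk (r = 50) ≈ 1.01, axis-aligned square ≈ 0.801 (ideal π/4 ≈
0.785), 2:1 ellipse ≈ 0.85 (Ramanujan ideal 0.841) — all within the
±0.03 discretization tolerance documented for compact shapes of a few
hundred pixels. **Circularity** 4πA/P² is clamped at 1.05 (ε = 0.05);
thin, few-pixel-wide shapes fall outside the estimator's validity and
simply hit the clamp.

Colony classification follows two rules taken as fixed biology: an
aggregate is a **colony** only above 14 cells (more than 1.75 cell
doublings at this cell type's replication kinetics), and a colony is
**sparse** (S) when nuclei are individually countable, **dense** (D)
otherwise. Countability is an input flag: how observers operationalize
it is not reducible to the image statistics available here, so the
package does not guess. **CFE** is colonies per 10⁵ seeded cells,
computed per condition; comparing conditions is a plain ratio of CFEs.
The ordinal staining scale is `-` below 25 %, `+` for 25–50 %, `++`
above 50 % up to 75 %, `+++` above 75 %; the printed scale leaves
50–51 % ambiguous and the gap is closed at exactly 0.50 belonging to
`+`. Quadrant counts use half-open boundaries (a colony on a dividing
line belongs to the lower-index quadrant, hence is counted exactly
once).

## Statistics

* **One-way ANOVA**: classical fixed-effects decomposition
  (`stats::oneway.test` with equal variances); zero within-group
  variance with equal means is special-cased to F = 0, p = 1.
* **SNK**: ordered means, span of stretch $r$ compared against
  $q_{1-\alpha}(r, df_w)\sqrt{MSW/n_h}$ with studentized-range
  quantiles from base R's `qtukey` (numerical distribution, no lookup
  tables) and $n_h$ the harmonic mean of the two group sizes in each
  comparison (Kramer adjustment — the convention for unequal n is not
  universal, so it is stated here). Spans are tested widest-first and a
  retained span blocks everything nested inside it, which makes the
  procedure coherent by construction; 2000 null simulations put the
  family-wise error at ≈ 0.04–0.05.
* **Chi-squared**: Pearson statistic on a 2×2 table without continuity
  correction by default (Yates by flag), margins required positive.
* **Sample size**: smallest per-group n whose noncentral-F power
  ($\lambda = f^2 k n$, $df_1 = k-1$, $df_2 = k(n-1)$) reaches the
  target; f = 0.50, α = 0.05, power = 0.80 with two groups gives
  n = 17. Published power analyses in this assay family sometimes
  report much smaller n from repeated-measures designs whose
  configuration (measurement count, sphericity, correlation) is rarely
  stated; the helper implements the transparent one-way design and
  exposes its parameters rather than claiming to reproduce any specific
  under-specified answer.

## What the generators emulate — and what they do not

`gen_planted_graph()` builds two blocks joined only through one bridge
node, so every cross-block geodesic passes it (dominant betweenness by
construction, verified against the oracle); one block member is wired
to its whole block (strict maximum degree). The bridge attaches to
several nodes spread across each block so no single neighbour funnels
the relayed traffic into a competing betweenness peak. Defaults (24
nodes, 42 edges, 14 seeds, scores uniform on [0.9, 1]) mirror the
dimensions and confidence regime of the interactome analysis the
package is built around. Planted roles are recovered by
`classify_roles()` in ≥ 95 of 100 seeded replicates (100/100 in the
shipped runs).

`gen_colony_field()` renders bright colonies on a noisy dark background
in a 512×512 field: dense colonies as near-confluent uniform texture
(nuclei not separable), sparse colonies as a dimmer carpet with
resolvable bright nuclei — mirroring the countability criterion — plus
sub-`min_area` speckles and Gaussian background noise. Condition
presets plant the morphometric contrast of interest: control colonies
larger and more irregular (elongated ellipses, lobed blobs; radii 18–32
px), differentiated colonies smaller and rounder (disks and mild
ellipses; radii 9–18 px); sparse colonies carry 15–60 cells and dense
ones 60–250. Each field ships an exact truth table (rasterized areas,
ideal circularities from closed forms or numerical polar integration,
cell counts, classes).

These generators validate the *machinery*, not the biology: passing
tests show that segmentation recovers planted components exactly and
areas within 5 %, and that the pipeline's direction of effect follows
the planted contrast. They do not show robustness to uneven
illumination, touching colonies, staining artefacts or focus drift,
none of which the generator emulates; real micrographs need parameter
tuning (`intensity_threshold`, `min_area`) and visual QC.

Several published quantities are **deliberately not asserted** anywhere:
the average clustering coefficient (0.653) and per-protein index values
of the motivating interactome require its unpublished edge list, and the
CFE pair 4.4/11.1 requires unpublished raw colony counts. The
acceptance machinery reports what the package computes on its own
fixtures and checks directions and calibrations instead.

## Degenerate inputs and tie-breaks

Empty networks cannot be constructed; empty images segment to an empty
colony list (not an error); an all-equal ANOVA returns F = 0, p = 1;
`top_decile` on constant values returns every node (tie expansion);
greedy core reduction breaks degree ties lexicographically; colony
masks are ordered by topmost-leftmost pixel. All generators take an
explicit seed, restore the caller's RNG state, and are byte-identical
across runs; pipeline reports embed the resolved configuration and its
MD5 hash and contain no timestamps, so reruns are bit-identical.

## Problem sizes in the shipped checks

The oracle-equivalence sweep uses 10⁴ random connected graphs on 4–7
nodes; role recovery uses 100 planted 24-node graphs; SNK calibration
uses 2000 null simulations of 4 groups × 10 observations; morphometry
checks use 512×512 fields with 6 colonies and reference shapes of
~10³–10⁴ px. These sizes make every check exact enough to be
discriminating while keeping a full run in well under a minute on one
core.
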