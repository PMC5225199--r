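---
title: "Morphometry of bistratified retinal arbors: models, conventions and design choices"
author: "arborMetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry of bistratified retinal arbors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arborMetrics)
```

# Scope and data model

`arborMetrics` analyzes single-neuron reconstructions of narrow-field,
bistratified retinal interneurons (AII amacrine cells). A reconstruction is
a set of rooted point trees in SWC convention — each point has a position in
micrometers, a radius, and a parent — plus a soma traced as closed contours
at a series of focal planes, and a retinal layer model given by two depths:
the INL/IPL border and the IPL/GCL border. The inner plexiform layer between
them is divided into five equally thick strata S1–S5, S1 adjacent to the
INL; S1–S2 form sublamina *a* (lobular dendrites), S3–S5 sublamina *b*
(arboreal dendrites).

The coordinate convention is fixed throughout: `x` is the lateral slice
axis, `y` is retinal depth increasing from INL toward GCL, `z` is the
optical axis. Soma contours are polygons in the XY plane stacked along `z`,
mirroring how a soma is traced at successive focal planes; the soma
projection used for projection area, perimeter and Feret calipers is
therefore the XY outline.

# Segments, orders and per-cell metrics

A **branch segment** is the part of a dendrite between two bifurcations, or
between a bifurcation and an ending; stems run from a tree root to the first
bifurcation. Each segment's path includes its start point so geometry is
continuous, while for exclusive accounting the shared point belongs to the
upstream segment. Counting conventions: a *node* is a non-root point with
two or more children (a trifurcation is one node), an *ending* is a leaf, so
`n_segments = n_nodes + n_endings` and, for a single purely bifurcating
tree, `n_endings = n_nodes + 1`.

Two branch-ordering schemes are provided. Under **centrifugal** ordering,
stems are order 1 and every bifurcation increments both daughters. Under
**central-shaft** ordering the continuing daughter keeps the parent's order
and only side branches increment. The continuing daughter is chosen as the
one with the larger radius at its first own point; ties fall back to the
smaller deviation angle from the parent's final direction, then to the
larger subtree length. This rule reflects that the natural "shaft" of these
cells is the thick apical dendrite, which thereby stays at order 1 along its
whole length; no reconstruction-format field marks the shaft explicitly, so
thickness is the only usable signal.

Surface areas and volumes treat each edge as a conical frustum
(lateral surface $\pi (r_1 + r_2)\,s$ with slant
$s = \sqrt{L^2 + (r_1 - r_2)^2}$; volume $\pi L (r_1^2 + r_1 r_2 +
r_2^2)/3$). Zero-length edges between coincident points are skipped.
Contraction is the Euclidean end-to-end distance of a segment divided by its
path length, in (0, 1].

**Partition asymmetry** at a bifurcation with daughter-subtree tip counts
$n_1, n_2$ is $|n_1 - n_2| / (n_1 + n_2 - 2)$, defined as 0 when both
daughters are single terminal branches. A "stub" bifurcation — one daughter
terminal, the other bifurcating further — scores exactly 1 regardless of the
deep daughter's size. An alternative mode counts daughter-subtree nodes
instead of tips. **Bifurcation angles** are measured between daughter
chords (bifurcation point to daughter-segment end point); **tilts** measure
each daughter chord against the reversed direction of the parent's final
edge (180° = continuing straight, 0° = doubling back) and report the smaller
(most backward) daughter per bifurcation. Per-cell SDs of angles and tilts
are population SDs (divide by *n*) over that cell's bifurcations.

For directions distributed uniformly over the sphere the pair angle has
mean $\pi/2$ and SD $\sqrt{\pi^2/4 - 2}$ (90.0° and 39.2°), and the smaller
of two independent axis angles has mean $3\pi/8$ and SD
$\sqrt{3\pi^2/8 - 2 - (3\pi/8)^2}$ (67.5° and 32.1°). Both closed forms are
implemented analytically and as seeded Monte-Carlo estimates
(`randomBranchingBaselines`); note that 67.5° sits exactly on a rounding
boundary, so a Monte-Carlo estimate legitimately rounds to 67 or 68.

## Fractal dimension

The fractal dimension quantifies how much a branch resembles a random walk:
1 for steady growth in one direction, 2 for a random walk. The naive
per-point regression of log path length on log Euclidean distance is
strongly attenuated on meandering paths, because the Euclidean distance —
the regressor — is the noisy quantity; it cannot reach 2 even on a true
random walk. The package therefore estimates D per branch from
window-averaged displacements: for a set of log-spaced path-length lags, the
mean Euclidean displacement over all windows of that lag is computed, and D
is the inverse slope of log displacement against log lag, fitted over the
monotone growth regime (the fit stops once mean displacement drops below
90 % of its running maximum, as it does for tightly coiled trajectories).
This reproduces D = 1 exactly on straight branches, D = 2 (within sampling
error) on simulated random walks, and values between the two on helices.

## Helicity and distances

Helicity is the normalized scalar triple product
$(v_1 \times v_2)\cdot v_3 / (|v_1||v_2||v_3|)$ over sliding windows of
three consecutive edge vectors within a segment; planar trajectories give
0, right/left-handed corkscrews constant positive/negative values.
Euclidean distance statistics are unweighted over all reconstruction
points, measured from the soma centroid — the volume-weighted centroid of
the contour stack, or the mean root position when no contours exist.

## Diameter correction and capacitance

Light microscopy cannot resolve the thinnest processes of these cells, so
reconstructions are corrected against the caliber observed in
electron-microscopic material: the diameters of the 10 thinnest
reconstruction points (one per unique segment) are averaged and a single
constant is added to every process diameter so this average equals the
target (default 0.23 µm) exactly. The operation is idempotent, errors if
it would produce non-positive diameters, and leaves the soma untouched.
Expected capacitance is total surface area (soma + dendritic frusta) times
a specific membrane capacitance of 0.01 pF/µm².

# Varicosity detection

A varicosity is a spatially discrete swelling whose maximum diameter is at
least 80 % larger (ratio 1.8, configurable) than the reference diameter
immediately before and after the swelling. The automated detector works on
the reconstructed radius profile along every root-to-tip path: candidates
are local diameter maxima; on each side the flank reference is the minimum
diameter reached while the profile keeps decreasing away from the peak,
within a path-distance window capped at 5 µm. "Immediately before and
after" has no stated spatial extent in the field, so the
decrease-until-rise rule with a 5 µm cap is this package's declared
interpretation, exposed as `flankWindow`. For terminal swellings the distal
flank requirement is waived. One varicosity is reported per contiguous
supra-threshold run; detections shared between overlapping root-to-tip
paths are de-duplicated by peak point. Comparisons use a relative tolerance
of 1e-9 so that a profile exactly at the 1.8 ratio counts as detected
despite floating-point representation. The detector is scale invariant.
Varicosities at bifurcation points belong to the parent segment.

# Spatial profiles

**Sholl analysis** uses nested spheres at 1 µm separation centered on the
soma centroid. Crossings are counted geometrically per edge: the squared
distance along an edge is a quadratic in the edge parameter, so each
monotone piece contributes one crossing per sphere radius strictly inside
its range; a crossing exactly at a shared vertex is counted once (assigned
to the edge that ends there), and a tangent touch counts zero. Shell
quantities are computed by clipping edges exactly at the sphere radii;
points exactly on a sphere belong to the inner shell. All shell sums equal
whole-cell totals to 1e-9 relative. **Laminar profiles** clip edges
linearly at the stratum boundaries; a point exactly on a boundary goes to
the stratum nearer the INL (deterministic tie-break).

**Dendritic fields**: the arbor is split by an XZ plane; the distal part
(toward the INL) holds the soma, apical trunk and lobular dendrites, the
proximal part the arboreal dendrites. Surface fractions are percentages of
the total (soma + dendrites) surface, with crossing edges clipped at the
plane and the soma assigned to the side of its centroid. The split depth is
normally chosen by eye in practice; `autoSplitDepth` provides a default —
the waist of the 1 µm-binned, lightly smoothed length-density profile
between the two dominant depth modes, where the second mode is the
candidate with the deepest valley toward the dominant peak (so a shoulder
of the same band is never mistaken for the lobular mode). Field hulls are
2D convex hulls of all reconstruction points of each part projected onto
the XZ plane (the retinal surface), with Feret maximum as the largest
pairwise vertex distance and Feret minimum by exact rotating calipers over
hull edges. The 3D convex hull (volume and surface) is computed by an
incremental hull written in the package, since no installed dependency
provides one; it is validated against cubes, regular tetrahedra and
rotation invariance.

**Density–territory scaling** fits a straight line to log10(branch
density) against log10(hull volume), density being total dendritic length
divided by 3D hull volume; the reference line (slope −0.55, intercept
0.45) describing the general scaling of neural arbors across many cell
types is returned alongside for comparison.

# Population analysis

All per-cell metrics plus per-layer process lengths enter a cells ×
metrics matrix, centered and normalized to unit SD per column. Metrics are
excluded when (i) effectively duplicate (|r| ≥ 0.999, always), (ii)
strongly correlated (|r| > 0.80) with a retained metric *and* listed as
geometrically related — judgment the package encodes as a candidate list
defaulting to everything outside the shipped 27-metric inclusion set — or
(iii) near-constant (coefficient of variation < 1e-3; the near-90°
bifurcation angle is the canonical example, and no numeric threshold is
standard, so 1e-3 is this package's choice).

PCA is the eigen-decomposition of the correlation matrix; a component's
variance fraction is its eigenvalue divided by the number of included
metrics (the eigenvalues sum to that number). Two eigenvalue-significance
procedures are provided: a Monte-Carlo null comparing each eigenvalue with
the (1 − α) quantile of the matching eigenvalue over standard-normal
datasets of identical shape (the default; α defaults to 0.05 as no value
is standard), and the classical broken-stick expectation
$\sum_{i \ge k} 1/i$. The literature sometimes labels the former "broken
stick"; both are implemented so either reading is available. Components are
retained sequentially — a component counts as significant only if all
earlier ones are — which keeps isolated late false positives from
inflating the component count on pure-noise data.

Bootstrap coefficient z-scores resample cells with replacement (10 000
replicates by default), re-run the PCA, correct each component's sign by
the sign of its scalar product with the original component (so corrected
scalar products are non-negative), and count — without silently reordering
— replicates whose leading eigenvalue order swaps. The z-score is the
original coefficient magnitude over its bootstrap SD; z > 2 is flagged
(roughly p < 0.05 without multiplicity correction, deliberately
uncorrected). Excluded metrics are regressed on each significant
component's scores, flagging R² > 0.4. Ward clustering (`ward.D2` on
Euclidean distances of the normalized matrix) is assessed by the largest
ratio of successive linkage heights near the top of the dendrogram:
clusters are reported only when that gap is at least 2, otherwise "no
separable clusters".

# The synthetic generator

No public reconstructions of this cell type exist, so validation rests on
`generateAII`: a stochastic growth model producing bistratified arbors with
complete ground truth. A thick apical trunk (maximum diameter ≈ 3 µm)
descends from a spherical contour-stack soma, emitting lobular side chains
in S1–S2 and branching into an arboreal subtree in S3–S5. Chains grow
segment by segment (segment lengths ≈ 2.9 ± 1.1 µm before wander, unit
steps of 0.9 µm with persistent-direction noise that yields contraction
near 0.9); at each segment end an event is drawn: a stub bifurcation, a
side-chain spawn, or termination (plain or a tip bifurcation). Default
rates (stub 0.35 of non-forced events, side 0.25, termination 0.12 with
85–90 % tip bifurcations) give node counts of roughly 60–280, total lengths
of roughly 500–1700 µm, and partition asymmetry dominated by the stub/tip
mix, emulating the reconstructed population's ranges. Reserved node budgets
(18 % lobular) keep both compartments present regardless of the random
event sequence, and a backbone chain with a guaranteed minimum number of
stub bifurcations ensures every cell carries central-shaft orders well past
10.

Two constructions make the ground truth exact rather than approximate.
First, radii are constant within a segment and strictly decrease toward an
asymptotic floor across bifurcations, so radius profiles are monotone along
every root-to-tip path and the inserted varicosities are the *only* local
diameter maxima; insertion scales a single point's diameter to at least 2.1
times the local flank (clear of the 1.8 criterion), so the detector's
precision and recall are exactly 1 on generated cells by construction.
Second, the thick daughter at a stub bifurcation is the terminal one —
varicose endings are thick — which makes the analysis' thickness-based
shaft-continuation rule reproduce the generator's recorded orders exactly,
and incidentally yields the deep central-shaft orders characteristic of
these cells.

`generatePopulation` spreads lateral territory size over roughly a tenfold
volume range. In planted-scaling mode the population is made to follow
log10(density) = intercept + slope · log10(volume) with small lognormal
scatter (0.015 log10 units by default): each cell is generated lean
(regenerating with a smaller node budget if it overshoots), then terminal
branches are extended with interior meander — aimed at anchors inside the
territory so the hull is essentially unchanged — until total length sits on
the planted line for the measured hull volume, re-measuring and topping up
in up to three passes. Ground truth records the planted law, per-part
surface areas at the default split depth (20 µm, the S2/S3 border of the
50 µm IPL used by the generator), every inserted varicosity, and
per-segment orders under both schemes.

What the generator does **not** emulate: tissue deformation and tracing
errors (spurious nodes, trifurcations), diameter measurement noise along a
branch, spines, true developmental branching statistics, and any
correlation structure between metrics beyond what the growth model
induces. Passing recovery tests therefore demonstrates the correctness of
the analysis code under the stated geometric model, not the biological
fidelity of the generator.

# Acquisition optics

The Nyquist sampling distances for multi-photon excitation are
$\Delta_{xy} = \lambda_{ex} / (4 k n \sin\alpha)$ laterally and
$\Delta_z = \lambda_{ex} / (2 k n (1 - \cos\alpha))$ axially, with
refractive index n (1.338 for water), photon count k (2), and half-aperture
angle $\sin\alpha = NA/n$; the two-photon lateral resolution limit is
$0.61\lambda/(NA\sqrt2)$. `checkSampling` passes an axis when its sampling
interval does not exceed the corresponding Nyquist distance.

# Numerical conventions and degenerate inputs

- SWC writing uses 17 significant digits, so write → read round trips are
  bit-exact; sidecars are JSON with full-precision numbers.
- Boundary ties are deterministic everywhere: stratum boundaries bin toward
  the INL, Sholl spheres bin points toward the inner shell, duplicate
  metric columns drop the later column.
- Degenerate inputs error early with informative messages: orphan parent
  ids and non-positive radii at parse time, collinear clouds in axis
  alignment, coplanar/collinear point sets in hulls, equal layer
  boundaries, split planes outside the arbor. `validateMorphology` is the
  reporting (never-erroring) counterpart for cycles, detached trees and bad
  radii.
- All randomness is seeded explicitly; the same seed reproduces generated
  cells byte-for-byte in serialized form.

# Problem sizes

The shipped tests run single generated cells (roughly 900–1100 points),
a 15-cell population for the summary-statistics checks, a 40-cell planted
population for the scaling-slope recovery, 20 replicate 43 × 27 metric
matrices (with 1000-replicate Monte-Carlo eigenvalue nulls) for the
component-count recovery, 10^6 Monte-Carlo samples for the angle
baselines, and five 10^4-step random walks for the fractal-dimension
anchor. These sizes were chosen so each check has comfortable statistical
margin while the whole suite stays quick on a single core.

# Known limitations

- The soma surface uses perimeter-equivalent frusta between contours plus
  end caps; tracing software implements proprietary variants, so absolute
  soma surfaces may differ by a few percent from other tools.
- The soma projection uses the convex outline of contour vertices; deeply
  non-convex somata would be slightly overestimated.
- The shaft-continuation rule is thickness-based; on reconstructions where
  daughter radii are unreliable the central-shaft orders inherit that
  unreliability (the centrifugal scheme is unaffected).
- Varicosity detection operates on reconstructed radii, not on image-space
  circle fits; reconstructions that under-sample swellings will
  under-detect regardless of the criterion.
- `partitionAsymmetry` skips trifurcations (counted and reported) rather
  than generalizing the two-daughter formula.
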