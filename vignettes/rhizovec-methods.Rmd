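---
title: "rhizovec: models and design choices"
author: "rhizovec authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rhizovec: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizovec)
```

## The problem

Root systems of plants grown in thin transparent containers (rhizotrons)
can be digitized as *vector* objects: every root is a polyline with
per-node diameters, placed in the rhizotron coordinate frame, and linked to
its parent root in the branching hierarchy. In the split-and-combine
workflow the root system is physically separated into fragments (typically
one first-order axis plus its laterals), each fragment is scanned and
traced separately, and the tracings — registered in a common frame by an
acetate overlay — are recombined into a single root system. The vector
representation supports architectural trait analysis by root order and,
because it is spatially registered, can be crossed with any raster map of
the soil, such as time series of soil water content from light-transmission
imaging.

`rhizovec` implements the computational half of this workflow: the data
model and RSML I/O, the merge of registered partial tracings, the
architectural trait suite, the root–soil crossing, and seeded synthetic
generators that make the whole pipeline testable without scans.

Coordinates are in cm with x rightward and y downward (depth), origin at
the rhizotron's top-left corner; the default frame is 50 x 50 cm.

## Data model and validation

`RootSystem` holds a forest of `Root` objects; each root carries its
polyline (`x`, `y`, `diameter` per node), branching order (1–3), parent id
and the arc-length position of its insertion on the parent. Class validity
enforces only structural sanity (unique ids, resolvable parents), while
`validateSystem()` *reports* scientific violations — cycles, dangling
parents, order inconsistencies, out-of-range insertions, negative
diameters — without refusing to represent them. This split is deliberate:
the merge workflow legitimately holds intermediate states (orphan laterals
whose parent was traced in another scan), exactly as the interactive
tracing workflow does before manual correction.

## Merging partial tracings

`mergeTracings()` translates every fragment by its registration offset,
pools the roots (suffixing ids on collision), and then attaches every
parentless lateral to a candidate parent of order one less. The insertion
point is the nearest-point projection of the lateral's first node onto the
candidate polyline; the lateral is attached when that distance is at most
`attachTolerance`, by default **0.5 cm**, commensurate with the placement
accuracy of an acetate registration. Candidates are ranked by distance with
ties broken by lexicographic root id, so merges are reproducible; laterals
with no candidate in tolerance are kept as orphans and listed in the merge
report rather than deleted. Because no polyline is resampled, total length
and surface are conserved exactly (to floating-point) by construction,
and the merge result is invariant to the order of the parts.

Insertion positions are not serialized in RSML; both the reader and the
merge recompute them by the same projection rule, and the synthetic
generator places each lateral's first node exactly on its parent polyline,
so split–merge and write–read round trips reproduce systems exactly.

## Trait suite

Segments are conical frusta with linearly interpolated diameter. For end
diameters $d_1, d_2$ and length $L$:

* length: euclidean node distance;
* lateral surface: $\pi \frac{d_1 + d_2}{2} L$ (mean-diameter cylinder; no
  slant correction — per-segment taper is small);
* volume: $\frac{\pi}{12} L (d_1^2 + d_1 d_2 + d_2^2)$ (exact frustum);
* projected area: $\frac{d_1 + d_2}{2} L$, the quantity a binary scan
  mask measures.

Both surface and volume are additive under subdivision because diameter is
linear in arc length, which is what makes the *distal cumulative* measure
well defined: `distalCumulative(system, root, s, measure)` sums the chosen
measure over the root tipward of arc position $s$ plus the whole subtrees
of laterals inserted at positions $\ge s$. The boundary convention — a
lateral inserted exactly at the query position is *included* — is a design
choice; the quantity is non-increasing in $s$ and, at the base of an axis,
equals the whole-tree total. Under the assumption that everything distal
of a cross-section must be supplied through it, the cumulative volume
profiles axial water-flow demand along an axis.

Depth profiles clip every segment exactly to half-open horizontal slabs
$[k b, (k+1) b)$ (default $b = 1$ cm), so per-order bin sums equal
per-order totals and are invariant under bin refinement.

Per-order diameter statistics summarize each root by its length-weighted
mean diameter and compare orders with pairwise Welch (unequal-variance)
t-tests at $\alpha = 0.01$, without multiplicity correction — with three
orders the comparisons are few and the convention matches common practice
in root phenotyping figures. Letters come from an insert-and-absorb
compact letter display over the non-rejection graph; orders with fewer
than two roots are reported without a letter.

Orientation along a root is the unsigned angle between the local secant —
taken over a centered arc-length window, default **1 cm**, clamped at the
root ends — and the vertical-down direction: 0° is plumb, 90° horizontal.
The unsigned convention avoids an arbitrary left/right sign.

Fitter's topological indices treat each axis and its laterals as a tree of
*links* (internodes between branching points and tips): magnitude is the
tip count, altitude the number of links on the longest base-to-tip path,
and the exterior path length the sum of link depths over all tips.
Laterals inserted at exactly the same arc position share a branching
point. For a herringbone tree altitude equals magnitude, which is used as
a limit-case check.

## Crossing roots with soil water maps

Raster maps are `SoilGrid` objects: a matrix of water-content indices in
[0, 1] with an origin, a square pixel size and a timestamp. The analysis
follows three steps: (1) `downsampleGrid()` reduces a high-resolution map
by exact k×k block means (a 50 × 50 cm map at 0.1 cm/pixel becomes 50 × 50
pixels of 1 cm²; block means conserve the global mean exactly, and a
non-integer factor is an error rather than a silent crop); (2)
`distanceMap()` finds, for every pixel center, the euclidean distance to
the closest root segment, recording the nearest root's id and order;
(3) `joinSoilRoot()` merges the grid series with the distance map into a
long table of one row per pixel and timestamp.

Distances are measured from pixel *centers* (at `(index − 0.5) · h`) to
the root *centerline*: root radii (a few mm) are below the 1-cm pixel
scale, so subtracting them would add complexity without precision. The
distance map is computed once and reused for all timestamps — root growth
over a three-day observation window is treated as negligible. Nearest-root
ties are broken by lexicographic id for determinism.

`distanceBinnedSeries()` aggregates the long table into mean water content
and pixel count per timestamp and half-open distance bin, default 1-cm
bins from 0 to 15 cm with an overflow bin beyond; the n-weighted mean over
bins reproduces each timestamp's global mean exactly.
`fitDepletionProfile()` fits $W(d) = W_0 - A e^{-d/\ell}$ to one
timestamp's binned profile by weighted nonlinear least squares, recovering
the depletion length scale $\ell$.

## Synthetic generators

The generators are first-class, tested code: they define the ground truth
against which every downstream stage is verified.

`generateRootSystem()` emulates the root system of a 20-day old maize
plant: one primary axis plus 2–3 seminal and 2–4 adventitious axes (5–8
first-order axes in total) with up to third-order laterals, grown in a
50 × 50 cm frame. Growth is a stepwise heading random walk: at each 0.5 cm
step the angle to the vertical is reduced by a per-order gravitropism
fraction (0.25 / 0.08 / 0.02) and perturbed by gaussian heading noise
(8 / 18 / 25° per step), so axes dive while laterals wander — matching
the qualitative division of labor between vertically exploring thick axes
and horizontally exploring fine laterals. Laterals arise as a Poisson
process (0.6 /cm on axes, 0.2 /cm on second-order roots) outside an apical
unbranched zone (4 and 1.5 cm), with insertion exactly on the parent
polyline. Growth is clamped at the rhizotron walls. The model is
deliberately minimal — it is a fixture engine with known ground truth, not
a published functional–structural growth model.

Basal diameters default to 0.45 / 0.15 / 0.08 cm for orders 1–3 (±10%
per-root jitter, 20% linear taper to the tip). These preserve the strong
order-1 ≫ order-2 > order-3 ordering seen in maize while keeping even
third-order strokes at or above one pixel at the 5–10 px/cm resolutions
used for mask rendering; substantially thinner (field-realistic, sub-mm)
laterals would be sub-pixel at those resolutions and would turn the mask
comparison below into a test of the stroke floor instead of the geometry.

All draws come from one seeded private stream in a documented order (axis
counts, then per axis: base jitter, heading, target length, diameter,
per-step noise, then its laterals depth-first), so output is byte-stable
per seed and the caller's RNG state is untouched.

`splitSystem()` inverts the physical dissociation: one partial tracing per
axis with its whole subtree, offsets (0, 0).

`renderMask()` rasterizes the system as a binary image, stroking each
segment at its local mean diameter with a one-pixel floor — the synthetic
analog of an ex-situ scan. The scan-vs-vector area comparison is run *per
fragment*, as the scanning protocol does: a whole-system union mask
under-counts wherever roots overlap in 2D (crown bundling, crossing
laterals — precisely the problem split-and-combine scanning avoids),
whereas summed fragment masks track the vector projected area closely,
with a small residual deficit from laterals overlapping their own parent
near insertions.

`generateWaterSeries()` builds water maps from the distance map:
$W = \mathrm{clip}(W_0(t) - A(t) e^{-d/\ell} + \varepsilon,\ 0,\ 1)$, with
bulk content $W_0(t)$ declining linearly with cumulative daytime hours
(0.0035/h from 0.75; transpiration stops at night), a depletion amplitude
$A(t)$ ramping with daytime hours from 0.15 to 0.4 — depletion is present
from the start of the observation window, since the water supply is
interrupted before imaging begins — and reduced by 30% at night to mimic
nocturnal redistribution of soil water toward the depleted zone around
roots, a length scale $\ell = 2$ cm, and gaussian noise (sd 0.01).
Daytime is 06:00–18:00; timestamps default to every 4 h over 72 h.

A known statistical limit: with $\ell = 2$ cm the expected water-content
difference between neighboring 1-cm bins beyond ~10 cm from the roots is
of order $10^{-4}$, far below the bin-mean noise
($\mathrm{sd}/\sqrt{n} \approx 10^{-3}$ on a 50 × 50 grid). Strict
monotonicity of measured bin means over the full 0–15 cm range is
therefore not observable at realistic noise levels, even though the fit
recovers $\ell$ to within a few percent (the near-root bins dominate the
least squares). Tests of measured-profile monotonicity across all bins
fail for this reason and the failure is expected; the noise-free profile
is strictly monotone, which is verified separately.

## Numerical conventions

* Geometry round trips are exact to well below 1e-9 cm: RSML serializes
  numbers with `%.12g`, and repeated writes are byte-identical.
* Nearest-point projection resolves distance ties toward the smallest arc
  length; nearest-root ties in distance maps toward the smallest id.
* Zero-length segments contribute nothing to measures and collapse to
  their first node in projections; single-node roots are treated as points.
* Declared RSML units (m, dm, cm, mm, um, inch) are rescaled to cm on
  read; an unknown unit is a format error, not a guess.
* Degenerate inputs error loudly: empty systems for distance maps,
  zero-surface systems for proportions, non-divisible grids for
  downsampling.

## Problem sizes in the test suite

The suite verifies oracle equivalences (brute-force distance grids,
exhaustive tipward enumeration, link-graph search, dense-sampled
projections) on 20–50 seeded systems generated in a 20 × 20 cm frame with
sparser branching, on 15–30 pixel grids, and runs the full water pipeline
on the default 50 × 50 cm / 1 cm configuration; mask regressions use 30
full-size systems at 10 px/cm. These sizes were chosen so the whole suite
completes in about a minute while still exercising several hundred
thousand oracle comparisons.

## Limitations

* The generator produces a final architecture only — no time-resolved
  growth, and no repulsion between roots, so 2D self-overlap is denser
  than in a real rhizotron where roots partly avoid each other.
* The water model is phenomenological: no Richards-equation flow, no
  hydraulic coupling to the plant, and night refilling is a fixed
  amplitude reduction rather than a transport process.
* Passing tests on synthetic systems demonstrate the correctness of the
  computational chain, not the biological fidelity of any particular
  trait value; real tracings bring measurement errors (missed roots,
  mis-attached laterals) that the generator does not emulate.
* Only 2D RSML is supported, and the legacy pre-RSML SmartRoot XML dialect
  is not parsed.
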