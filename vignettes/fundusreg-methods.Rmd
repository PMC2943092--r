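---
title: "Vessel-graph registration of retinal fundus images: models, parameters and design notes"
author: "fundusreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel-graph registration of retinal fundus images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusreg)
```

## The registration problem

Pairs of fundus photographs of the same retina — taken at different times,
from different viewpoints, or on different devices — must be brought into a
common coordinate frame before longitudinal comparison. Intensity-based
registration struggles on fundus images: large textureless regions, uneven
illumination and viewpoint-dependent shading make global similarity
surfaces unreliable. The retinal vasculature, in contrast, is a stable,
well-spread anatomical structure, and its branching pattern is essentially
a fingerprint of the retina.

`fundusreg` registers image pairs through a hierarchy of vessel-derived
features:

1. **Vessel centerline detection.** Oriented matched filtering with a
   second-order Gaussian-Hermite kernel, threshold probing, and thinning
   produce a one-pixel-wide vessel skeleton.
2. **Vascular structure graph (VSG).** Bifurcations and segment endpoints
   become nodes; vessel segments become edges attributed with the vessel
   path distance (arc length along the skeleton) and the Euclidean
   endpoint distance, each normalized by its mean over edges so the
   attributes are invariant to scale.
3. **Graduated-assignment graph matching** finds global node
   correspondences by maximizing the quadratic assignment objective
   $E(M) = \sum_{i,i',j,j'} M_{ii'} M_{jj'} W_{ii'jj'}$ over one-to-one
   assignments, where $W_{ii'jj'}$ compares the attributes of edge $(i,j)$
   in one graph with edge $(i',j')$ in the other and is zero when either
   edge is absent.
4. **STRUCT-SAC** eliminates wrong matches: instead of random sampling it
   deterministically hypothesizes a similarity transform from each matched
   node of degree 2–3 together with its matched neighbours, tests the
   sample's local geometric consistency, verifies the hypothesis globally
   with a Huber-robust score, and keeps the best model.
5. **Quadratic ICP** refines the alignment of the two centerline point
   sets under a 12-parameter second-order polynomial model, coarse to
   fine, with gated nearest-neighbour correspondences and a trimmed
   weighting of pairs.
6. **Evaluation** reports the vessel centerline error measure (CEM — the
   median distance between corresponding centerline points after
   registration; below 3.0 px counts as success), normalized correlation
   (NCC), normalized mutual information (NMI) and the overlap percentage.

Because no clinical image pairs ship with the package, a synthetic phantom
generator provides fundus-like image pairs with known ground truth; it is
first-class, tested code and the basis of the package's validation.

## The matched filter

The vessel cross-section is modelled by the 1-D kernel
$$H(x) = \bigl(1 + a\,(x^2 - 1)\bigr)\,
  \frac{1}{\sqrt{2\pi\sigma^2}} e^{-x^2/2\sigma^2},$$
with $x$ in pixels. With $a = 0$ this is a plain Gaussian; $a > 0$ raises
the kernel's centre relative to its flanks, modelling the central light
reflex seen on wide vessels. Filtering at orientation $\theta$ applies the
analytic second derivative $H_{vv}$ across the putative vessel and a
smoothing Gaussian along it, implemented separably in a coordinate frame
rotated so $\theta$ is horizontal. The per-pixel maximum over 12
orientations (15° apart) is the vessel response; the sign convention makes
dark-on-bright vessels positive (a smoothed intensity dip has a positive
second derivative at its minimum).

Parameters that matter, with defaults:

| parameter | default | meaning |
|---|---|---|
| `a` | 0.3 | Hermite weight (0 = pure Gaussian profile) |
| `sigma` | 1.5 px | cross-profile scale; match to the typical vessel half-width |
| `sigmaAlong` | 3 px | along-vessel smoothing; longer than `sigma` because vessels are locally straight, which buys noise suppression for free |
| `nOrientations` | 12 | orientation bank over [0°, 180°) |

Numerical care the implementation takes, all verified by tests against
ground-truth phantoms:

* the sampled $H_{vv}$ is mean-corrected so flat image regions give
  exactly zero response;
* rotation resampling **clamps** out-of-frame source coordinates —
  reflecting them would fold distant vessels back into the frame as ghost
  structures;
* per orientation, responses whose rotated-frame source fell outside the
  frame are invalidated (under a large rotation the corner wedges would
  otherwise be filled with streaked border content), and the pipeline
  zeroes a 12 px frame border.

## Segmentation: threshold probing and ridge localization

Probing grows regions from seed pixels downward through a sequence of
thresholds and accepts regions by size (30–50 000 px). Both the seed level
and the probe floor are anchored to a noise scale estimated from the
*negative* response tail: vessels only push the response positive, so the
negative tail is a vessel-free yardstick, and the thresholds remain stable
no matter how much of the frame the vessels cover (global quantiles of the
positive responses do not: they collapse when vessels are sparse).

Thinning a thresholded response *band* puts the centerline at the band's
medial axis, which drifts wherever the bands of neighbouring vessels
merge — junction positions then depend on which branches happen to crowd
each other, and two views of the same retina disagree. The pipeline
therefore restricts the mask to the cross-profile **non-maximum
suppression ridge** of the response before thinning. The ridge is a
repeatable centerline estimate, and junction repeatability across views is
what the downstream graph matching lives on.

## Graph construction

Skeleton pixels with one branch are endpoints; pixels with three or more
branches (by crossing number) are bifurcations; adjacent bifurcation
pixels merge into one node. Walks along the skeleton from node to node
produce the edges; steps count 1 (axis neighbours) or $\sqrt 2$
(diagonal). Clean-up rules:

* **short spurs** (path length < 10 px ending in a leaf) are removed —
  they are thinning artifacts;
* **short internal edges** between two junctions are *contracted*
  (endpoints merged): deleting them, the literal reading of "remove small
  edges", disconnects the vessel network;
* degree-2 nodes left over are dissolved by concatenating their edges;
* connected components with less than 200 px of total vessel path are
  dropped as segmentation debris, and skeleton pixels lying deeper than
  6 px inside the mask (deeper than any plausible vessel) are removed.

Edge attributes are normalized by their means over edges
($a_1 = d_{vp}/\overline{d_{vp}}$, likewise $a_2$ for the Euclidean
distance), which makes them exactly invariant under a similarity transform
of the image — the property that lets graph matching ignore the unknown
warp entirely.

## Graduated assignment, and a note on balancing

The compatibility of two edges is
$w = \tfrac12\,(1 - |\Delta a_1|/L_1) + \tfrac12\,(1 - |\Delta a_2|/L_2)$,
with $L_r$ the attribute maximum over both graphs. Graduated assignment
relaxes the assignment matrix to doubly substochastic (one slack row and
column absorb unmatched nodes, so unequal graph sizes are handled),
iterates a softassign update $M \propto \exp(\beta Q)$ with
$Q_{ii'} = \sum_{jj'} M_{jj'} W_{ii'jj'}$ under Sinkhorn row/column
normalization, and anneals $\beta$ geometrically from 0.5 to 10 (growth
1.075). Two implementation notes:

* the gradient is computed on a compatibility operator rescaled to unit
  mean positive entry — a uniform rescaling is equivalent to rescaling
  $\beta$ and keeps the canonical annealing schedule meaningful for any
  graph size;
* the exponential update subtracts the per-row maximum; a diagonal row
  scaling does not change the Sinkhorn limit and avoids overflow.

Hard correspondences are the entries that are maximal in both their row
and column and exceed $1/(\min(n_1,n_2)+1)$.

Bistochastic balancing of the edge-similarity matrix (alternate row and
column normalization to convergence) is implemented and tested, but **off
by default**: on vascular graphs whose edge similarities are strictly
positive and fairly homogeneous, balancing drives the matrix toward
uniformity and in our experiments collapses matching recall from about
0.65 to almost zero — a single sweep suffices. Balancing plausibly helps
when the similarity matrix is sparse or strongly heterogeneous; it can be
re-enabled with `matching$normalize = TRUE`.

## STRUCT-SAC

A matched node is *stable* if at least two of its neighbours are matched
correctly. STRUCT-SAC traverses every matched node of degree 2 or 3 in
either graph (a deterministic sample schedule — no randomness unless the
optional inner subsampler for oversized neighbour sets is enabled), maps
the node and its matched neighbours to the other graph, and

1. tests **local consistency**: matched edges must exist on both sides
   with attribute differences at most 25% of the attribute maximum, and
   every pair of neighbours must subtend the same angle at the center
   within 20° (subtended angles are similarity-invariant);
2. estimates a closed-form least-squares **similarity transform** from
   the sample (Umeyama's solution, constrained to a proper rotation);
3. scores the hypothesis **globally**: a fresh correspondence set is
   built by mutual nearest neighbours within a 15 px gate between the
   reference nodes and the transformed floating nodes, and
   $\varepsilon(\theta) = \sum \rho^2(\|r\|)$ accumulates the squared
   Huber penalty ($\sigma = 3$ px) of the residuals.

Models are *ranked* by $\varepsilon$ plus a saturated penalty
$\rho(\text{gate})^2$ for every node that found no partner: the raw score
sums only over gated pairs, so a wrong model that happens to gate three
accidental pairs would otherwise beat the true model that gates thirty.
The penalized score is the natural continuation of the robust loss beyond
the gate. A model must gate at least 3 pairs to be admissible; if no
sample passes the local test, the stage signals "insufficient stable
structures", mirroring the known failure mode when fewer than three
stable nodes exist.

The squared Huber value follows the printed form of the score; the more
conventional reading (kernel applied to the squared norm) is available as
`huberMode = "conventional"`.

## Quadratic ICP

The fine stage registers the two centerline point sets under
$$\begin{pmatrix}x'\\y'\end{pmatrix} =
 A \begin{pmatrix}x^2\\y^2\\xy\end{pmatrix} +
 B \begin{pmatrix}x\\y\end{pmatrix} + c,$$
twelve parameters fit by weighted linear least squares on the monomial
basis, independently per output coordinate. Coordinates are rescaled to
$[-1,1]$ about the centroid before fitting (the monomial design matrix is
numerically hopeless at 700-pixel coordinates) and the coefficients are
mapped back to pixel units algebraically, so the stored transform is
exact. Three resolution levels subsample the point sets with strides 4,
2, 1 and gates 20, 10, 5 px; each iteration pairs the transformed source
points with their gated nearest target points (a grid-hash search, exact
within the gate), drops pairs with residuals above 2.5× the median
(recomputed every iteration; Huber weighting is available), and refits.
Iteration stops when the mean residual changes by less than $10^{-3}$ px
or after 50 iterations per level. Fewer than 6 usable pairs at the finest
level raises a divergence failure.

## Evaluation

* **CEM**: median of $\|p - T(q)\|$ over mutual-nearest-neighbour
  correspondences (10 px gate) between the reference centerline and the
  transformed floating centerline; success means CEM < 3.0 px, strictly.
* **NCC**: Pearson correlation over the warped overlap (2 px eroded to
  avoid border interpolation artifacts). The sign convention is standard;
  well-registered pairs of the same modality score close to +1.
* **NMI**: $(H(A)+H(B))/H(A,B)$ over a 64-bin joint histogram (2 for
  identical images); the $[0,1]$ variant $2I/(H(A)+H(B))$ is available.
* **Overlap**: the fraction of reference pixels whose pre-image under the
  transform falls inside the floating frame (the quadratic model is
  inverted pointwise by Newton iteration).

NCC and NMI are computed on unpreprocessed intensities.

## The phantom generator

`phantomSpec()` fixes every knob of the synthetic scenes; the same spec
reproduces bit-identical phantoms from its seed, through a private RNG
stream. The generator emulates:

* **geometry** — two binary vessel trees rooted near one image edge and
  fanning out in diverging directions, like the temporal arcades; curved
  segments with per-generation length decay 0.72 and *wide* per-segment
  length jitter (uniform on [0.55, 1.6] of the base length). The jitter
  is deliberate realism: real vascular segment lengths vary strongly, and
  that variability is what makes the attributed graph distinctive —
  near-uniform segment lengths would make edge-attribute matching
  ill-posed for any method;
* **appearance** — dark vessels with Gaussian cross profile (width
  tapering by generation from 3.2 px half-width), an optional central
  reflection ridge to exercise the $a \ne 0$ kernel, a smooth
  illumination gradient (amplitude 0.12) and additive Gaussian noise
  (sd 0.015) on a 0.85 background, at 600×700 px;
* **ground truth** — the warp (similarity, or quadratic by generating in
  the floating frame and mapping forward), node correspondences, and
  controllable structure noise: a fraction of floating nodes without any
  true partner (grafted spurious branches) and optional deletion of leaf
  branches. Overlap is controlled by solving the warp translation for a
  target overlap percentage.

What the phantoms do *not* emulate: the optic disc and macula, pathology,
vessel crossings ("over/under"), modality differences, and the vignetting
aperture of real fundus cameras. Passing tests on phantoms certify the
algorithmic chain — detection, graph abstraction, matching, consensus,
refinement — under known ground truth; they do not certify clinical
performance.

## Problem sizes used by the validation suite

Unit tests run on 300×360 px phantoms with depth-3 trees; the end-to-end
battery and the acceptance script use the full 600×700 px default scenes
with depth-4 trees, similarity warps with scale 0.9–1.2, rotations up to
30° and overlaps of 60% and above, which a single registration handles in
well under half a minute. The matching oracle compares graduated
assignment against exhaustive permutation search on graphs of up to 6
nodes, where the brute force is cheap and exact.

## Known limitations

* Junction localization after thinning is repeatable to roughly 1–2 px;
  junctions closer than about 10 px merge, and terminal twigs shorter than
  the vessel width are invisible to any detector at this resolution, so
  two views never produce literally identical graphs. STRUCT-SAC absorbs
  this, but scenes whose matched subgraphs are small can still fail —
  the stage then reports "insufficient stable structures" rather than
  guessing.
* The quadratic assignment objective with two length attributes can
  genuinely prefer a wrong but structurally consistent alignment on
  near-symmetric trees; this is a property of the objective, not of the
  optimizer, and the global geometric verification of STRUCT-SAC is the
  package's defence.
* The quadratic model extrapolates poorly outside the vessel support;
  transforms should only be trusted over the registered overlap.
* CEM itself has a blind spot: because its correspondences are gated
  mutual nearest neighbours, a wrong registration that locks one subtree
  onto another can still report a sub-3-px median. A simultaneously low
  NCC is the tell-tale; inspect both before trusting a single number.
* Runtime is dominated by the oriented filtering (12 rotations of the
  full frame); about 10–20 s per 600×700 pair on one CPU.
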