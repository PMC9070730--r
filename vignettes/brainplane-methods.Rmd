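---
title: "Methods: semi-manual atlas mapping of coronal image stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-manual atlas mapping of coronal image stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainplane)
```

`brainplane` maps cells detected in a coronal image stack of a cleared
mouse brain onto a labeled reference atlas. This vignette explains the
model behind each stage, the assumptions it rests on, the tunable
parameters and their defaults, what the synthetic phantom does and does
not emulate, and the numerical and design choices that were genuinely
open.

## The anterior–posterior alignment model

A coronal stack acquired anterior-first defines an unknown, strictly
decreasing map from plane index $z$ to anterior–posterior position
$\mathrm{AP}(z)$ (mm from bregma). Clearing protocols shrink and swell
tissue nonuniformly along this axis, so $\mathrm{AP}(z)$ is *not* the
straight line between the endpoints; on our phantoms (and on published
cleared-brain data) the deviation reaches hundreds of micrometers —
enough to assign cells to the wrong plate outright.

We model $\mathrm{AP}(z)$ as piecewise linear between *anchors*
$(z_i, \mathrm{AP}_i)$. The two endpoint anchors are assigned manually;
internal anchors come from matching reference atlas plates to image
planes. The matching is the *choice game*: a coarse-to-fine ternary
search in which the user compares the reference plate against three
candidate planes spaced by the current step of the schedule (default
200, 100, 30, 10 planes). Choosing a flank recenters the search at that
plane with the step unchanged; choosing the middle advances to the next
smaller step; choosing the middle at the finest step terminates. The
matched plane is then *defined* to lie at the reference plate's AP —
the anchor stores the plate's coordinate exactly, mirroring how a
trained anatomist uses plates as ground truth.

Two design points here were open and are worth recording:

* **Prediction uses the whole current map.** The initial middle plane
  is the plane whose interpolated AP (from *all* anchors aligned so
  far, not only the endpoints) is closest to the reference AP. Earlier
  anchors can only improve the starting point; this generalizes the
  simplest endpoints-only seeding.
* **Candidates are clamped to the feasible window.** The matched plane
  must fall strictly between the anchors whose APs bracket the
  reference AP (AP monotonicity leaves no alternative), so candidate
  planes are clamped into that window exactly as they are clamped to
  the stack bounds, and no impossible choice is ever presented. A
  chooser response that would still violate monotonicity (possible for
  a human mis-click) is rejected with a message and re-prompted.
* **The step is not decremented on a flank choice.** Recentring keeps
  the step; only a middle choice refines it. With a truthful chooser
  this terminates: each flank choice strictly reduces the AP distance
  to the target, and a middle choice at step $s$ certifies the target
  lies within $s$ planes, so the final plane is within the finest step
  of the truth.

The *midpoint check* then audits each interval between consecutive
anchors at its midpoint plane; a rejected midpoint triggers a new round
of the choice game at the midpoint's interpolated AP, and the result is
inserted as an additional anchor. One pass is made over the intervals
that existed at entry.

The *morph profile* summarizes the fitted deformation. For the interval
between anchors $i$ and $i+1$,
$$ r_i \;=\; \frac{\Delta z_i / |\Delta \mathrm{AP}_i|}{Z_{tot} / |\mathrm{AP}_{tot}|}, $$
the local planes-per-mm normalized by the whole-stack average, so a
linear morph gives $r_i \equiv 1$ and the $|\Delta\mathrm{AP}|$-weighted
mean is identically 1 (this is a conservation law, tested to $10^{-9}$).
The exact normalization behind published morph-ratio plots is not
standardized; this formula is our declared choice. The companion
*linear-prediction error* table reports, per plane, the difference (in
µm) between the all-anchor interpolation and the endpoints-only line —
the error a purely linear model would commit.

## Plate registration

Each registered plate gets a 2D nonrigid warp fitted from
correspondence points. Initialization is automatic: the tissue mask is
an Otsu threshold on log intensity (log compression makes the
autofluorescent tissue/background split robust to bright somata), the
outer contour of the largest connected component is traced, and
`nPoints` (default 32) samples at equal arc length are paired with
equal-arc-length samples of the plate outline. Both contours start at
their dorsal-most point and run clockwise — a deterministic pairing
that respects the bilateral symmetry of coronal sections. The point set
supports add/remove/move edits with a full undo stack, so a console
user can refine the registration and always revert.

The warp family is the thin-plate spline,
$f(p) = a_0 + A p + \sum_i w_i\, U(\lVert p - s_i \rVert)$ with
$U(r) = r^2 \log r^2$, solved by the standard bordered linear system;
$\lambda \ge 0$ on the kernel diagonal trades control-point fidelity
for smoothness (default $\lambda = 0$: interpolating, every control
point maps exactly to numerical precision). Forward (image→atlas) and
inverse (atlas→image) splines are fitted independently by swapping
source and target roles rather than inverting one spline numerically —
simpler, symmetric, and accurate to well under a pixel for the mild,
well-spread deformations plate registration produces (verified by
round-trip tests). Collinear or duplicated controls make the system
singular and are rejected with a clear error.

## 2.5D segmentation and duplicate cleanup

Segmentation is per-plane: difference-of-Gaussians band-pass at two
physical scales (defaults 5 and 20 µm, i.e. 1 and 4 px at 5 µm pixels —
scales below one pixel are refused), an absolute threshold on the
band-pass response (default 0.05 on [0, 1]-normalized intensities; a
quantile mode is available), connected components, an area gate
(defaults 100–2000 µm², bracketing a 10–25 µm soma footprint and
rejecting both speckle and the tissue-edge response ring), and per
object the intensity-weighted centroid in physical µm plus the peak raw
intensity.

At a 2.5 µm z-step a soma spans several planes and is detected once per
plane. Cleanup builds a graph linking two detections iff their in-plane
centroid distance is ≤ `xyThreshUm` *and* their axial separation
$|\Delta z| \cdot z_{step}$ is ≤ `zThreshUm`; each connected component
becomes one cell at its maximum-intensity member (ties to the lower
plane, for determinism), with `n_merged` recording the component size.
Grouping is deliberately **transitive**: a cell smeared across many
planes forms a chain whose extremes exceed the z threshold pairwise but
is still one cell. Defaults are 10 µm in xy and 7.5 µm in z (three
planes at 2.5 µm), our documented choices for somata of ~10 µm
diameter. The production path finds candidate neighbors by spatial grid
binning rather than all-pairs comparison, but is required — and tested
on random instances up to 2000 detections — to agree *exactly* with a
brute-force all-pairs connected-components oracle. Enlarging either
threshold can only merge components, so cell counts are monotone
non-increasing in both thresholds.

## Forward warp, region assignment, counting

Each cleaned cell receives $\mathrm{AP} = \mathrm{AP}(z)$ from the
alignment map and is pushed through the forward warp of the registered
plate nearest in AP; exact ties (to a $10^{-9}$ mm guard against
floating-point representation) break toward the more anterior plate.
Warp interpolation *between* plates is deliberately out of scope — the
per-plate registration model has no information between plates — so
cells whose nearest registered plate is farther than a cutoff (default
half the largest inter-plate AP gap) are flagged unmapped instead of
being extrapolated. Region assignment is a nearest-pixel lookup in the
plate's integer label mask; label 0 (outside tissue), out-of-bounds
landings and unmapped cells all fall into a synthetic `unassigned` row
so cell totals are conserved.

The count table lists every ontology region with its direct count, its
rolled count (direct plus all descendants; the root's rolled count is
the total of assigned cells), and a percentage. The percentage
denominator includes unassigned cells: conservation is then checkable
($\sum$ direct counts = cells in), at the cost that the root's
percentage reads below 100 when cells fall outside the atlas — users
preferring assigned-only percentages can renormalize from the counts.
ROI extraction takes the union of descendant sets of the requested
acronyms, and the sunburst export writes the d3-style nested hierarchy
whose node values are direct counts, so every subtree sums to its
root's rolled count and arc lengths are proportional to totals.

## The phantom: what it emulates, what it does not

The phantom module generates the full study conditions for every stage:

* **Stack geometry.** Default 300 planes of 256×256 px at 5 µm pixels
  and 2.5 µm z-step. The AP span is $n \cdot z_{step}$ (0.75 mm) — a
  *partial-brain* stack whose plane spacing and AP extent are
  physically consistent, which is exactly the regime where a 10-plane
  alignment error equals 25 µm of AP.
* **Morph.** $\mathrm{AP}(z)$ is a linear ramp plus a smoothed-tent
  deviation with amplitude up to 0.4× the span and peak position in
  [0.45, 0.55]; monotonicity is guaranteed by that slope budget and
  re-verified at construction (very short stacks near the cap can fail
  discretely and error out cleanly). This mimics the local
  compression/expansion seen in cleared tissue without claiming any
  particular published shape.
* **Atlas.** Five identical plates of nested ellipses under a 7-region,
  3-level ontology — the shipped, programmatically generated example of
  the atlas-bundle format.
* **Cells.** Default 25 cells placed uniformly in the leaf regions,
  eroded 2 px from borders and at least 60 µm (6 in-plane σ) apart —
  separation chosen so that two cells' detection footprints cannot
  bridge above threshold, making *exact* count recovery the correct
  expectation rather than an accident. Each cell is a 3D Gaussian blob
  (σ 10 µm in-plane, 3.5 µm axial, amplitude 0.5–0.85) that crosses
  the detection threshold on ~5 adjacent planes: the
  duplicate-generation mechanism the cleanup stage must undo. Additive
  Gaussian noise (σ = 0.01) sits an order of magnitude below the blob
  response.
* **Oracle chooser.** Ground truth supplies a truthful chooser: it
  picks the candidate whose true AP is nearest the reference (ties to
  the middle) and accepts midpoints within a tolerance (default 25 µm;
  0 forces maximal anchor insertion).

What the phantom does **not** emulate: optical point-spread and
attenuation, intensity falloff with depth, staining artifacts,
anisotropic tissue tearing, in-plane nonrigid deformation (phantom
tissue exactly matches its atlas plates, so registration is a
self-registration), and cells of heterogeneous size or clustered
spatial statistics. Passing the phantom suite therefore demonstrates
the correctness of the *bookkeeping and geometry* — alignment,
registration machinery, deduplication, warping, counting — not the
detection performance of the segmentation filter on real
immunolabeling, which always needs per-dataset parameter tuning.

## Numerical choices and degenerate inputs

* Checkpoints are plain text; doubles are written with 17 significant
  digits, which R parses back bit-identically, so resumed analyses are
  exact. Warp files store control pairs and coefficients; reloading
  refits the (deterministic) spline from the pairs.
* Problem sizes in the test and acceptance runs — 300-plane phantoms
  for alignment studies (100 choice-game draws, 20 recovery seeds), up
  to 2000 detections per cleanup-oracle instance, one full 300-plane
  end-to-end run — were chosen so the whole suite completes in a few
  minutes on a single core while still exercising every code path at
  realistic scale.
* Degenerate inputs fail loudly and specifically: unmatched or
  duplicated z indices in file names; interpolation before both
  endpoints are anchored; reference APs outside the anchored range;
  zero-length AP intervals in the morph profile; singular spline
  systems; segmentation scales below one pixel; loading a checkpoint
  that was never written (distinguished from a corrupt one); atlas
  masks with ids missing from the ontology.
* Ties are always broken deterministically (lower plane for equal peak
  intensities, anterior plate for equal AP distances, middle candidate
  for equal oracle distances), so every pipeline output is reproducible
  from its seed.

## Known limitations

Alignment assumes the stack is acquired parallel to the coronal plane
(no tilt correction) and strictly anterior-first. Registration is
per-plate 2D; there is no blending of warps between plates and no
intensity-based refinement. Segmentation is a fixed linear filter, not
a learned detector, and performs no cross-plane intensity
normalization. The ontology model requires a single root and tree
(non-DAG) parent links.
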