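---
title: "Tracking multiple small organisms: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking multiple small organisms: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

msotrack tracks groups of small aquatic organisms — zebrafish larvae,
*Artemia*, *Daphnia* — through time-lapse microscopy video and keeps their
identities consistent over time, even when segmentation is imperfect:
organisms pause for long stretches, overlap one another, and share the frame
with bubbles and impurities. This vignette explains the models behind each
stage, the parameters that matter, and the choices made where the design was
genuinely open. It states no empirical result that the package's tests do
not themselves compute.

## The pipeline

1. **Segmentation.** An adaptive per-pixel Gaussian-mixture background model
   separates moving/dark organisms from the (mostly static, brighter)
   background. The foreground is cleaned by a median filter, a morphological
   erosion with a flat diamond structuring element, and removal of
   connected components of implausible size. Each surviving 8-connected
   component is reduced to its pixel-mean centroid.
2. **Association.** Detections in consecutive frames are linked by
   minimum-total-cost one-to-one assignment (rectangular Kuhn–Munkres) on
   Euclidean distances, after a median-based distance gate removes
   detections too far from every candidate to be a moving organism.
3. **Gap bridging.** Trajectory fragments produced by mis-detection or
   occlusion are rejoined: fragment ends search fragment starts 2 frames
   ahead, then 3, … up to `max_search_frame` (default 6), again by
   minimum-cost assignment; the missing positions are filled by uniform
   linear interpolation and flagged.
4. **Kinematics.** Per-transition velocity, acceleration and heading, with
   per-individual summaries.
5. **Evaluation.** CLEAR MOT scoring (MOTP/MOTA) of tracks against ground
   truth.
6. **Synthetic scenes.** A generator that produces renderable scenes with
   exact ground truth, used throughout the test suite.

## Background model

Each pixel carries up to `max_components` Gaussians with weights summing
to 1. A frame value matches the nearest component within
`match_k` (2.5) standard deviations; weights relax as
$w \leftarrow (1-\alpha)\,w + \alpha\,o$ (o = 1 for the matched component,
else 0), and the matched mean and variance move with step $\alpha/w$. A
pixel is **background** only when its matched component's weight exceeds
the threshold $c_f$; an unmatched value creates a new component (weight
$\alpha$) and is foreground.

Two consequences matter for bursty movers:

* **Stationary retention.** A newly stopped organism seeds a component whose
  weight needs about $\log(1-c_f)/\log(1-\alpha)$ matched frames to exceed
  $c_f$. Until then the organism keeps being detected. With
  $\alpha = 0.005, c_f = 0.25$ this is ≈ 57 frames (≈ 4 s at 14 fps); the
  retention-property test measures exactly this.
* **Choice of the default α.** The movement model below implies geometric
  stationary-period lengths. With activity ≤ 7.5% the mean pause is tens of
  frames and the geometric tail easily exceeds 57 frames, so a ~57-frame
  retention would drop organisms mid-recording with appreciable
  probability. The package default is therefore `alpha = 0.001`
  ($c_f = 0.25$), a retention of ≈ 288 frames (≈ 20 s at 14 fps): longer
  than any plausible pause in the desk-scale scenes the package validates
  on, while still absorbing genuine background changes over a few hundred
  frames. Recordings with drifting illumination should raise `alpha` and
  accept the shorter retention.

**Initialisation.** The first component of every pixel is seeded with a
temporal *quantile* (default 0.8) of the first `burn_in_frames` (25) frames,
at weight 1. A median would be poisoned wherever an organism covers a pixel
for more than half the window — which happens whenever a path lingers or
hugs a wall. Because the supported scene class has dark organisms on a
brighter background, a high quantile recovers the true background under any
pixel the organism vacates for at least ~20% of the window. Set
`init_quantile = 0.5` for polarity-neutral behaviour. Masks are produced
for every frame including the burn-in window (the model is seeded from
those frames, then updated through them in order).

**Cleaning.** The median filter acts on a binary mask, where the window
median equals the majority vote; it is computed with an integral image.
Erosion uses a flat diamond structuring element (radius
`erosion_radius`, default 1) with everything outside the frame treated as
background; it widens the boundary between organisms in near contact so
their centroids stay accurate. The size gate keeps components within
`[organism_area/4, 4*organism_area]` — wide enough for two fully merged
organisms, narrow enough to drop specks and large artefacts.

## Association and the noise gate

The cost of linking source $S_i$ to target $T_j$ is their Euclidean pixel
distance; the rectangular assignment minimises the total cost over one-to-one
matchings, so the number of detections may change between frames. The
solver is a Jonker–Volgenant shortest-augmenting-path implementation; among
equal-cost optima an infinitesimal lexicographic perturbation makes the
result deterministic (lowest source index with lowest target index). The
test suite checks it against exhaustive permutation enumeration.

The gate computes one threshold per frame pair, $\delta \cdot
\mathrm{median}(D)$ over *all* entries of that pair's cost matrix, before
any rejection (the alternative — recomputing the median after each
rejection — is circular). A source row whose minimum entry strictly exceeds
the threshold is declared a segmentation noise fragment; its point is
removed outright, never entering the bridging pools, and a fragment emptied
this way disappears. The default $\delta = 3$ is deliberately permissive;
because the threshold scales with the *median inter-object distance*, the
gate is effective exactly when organisms are mutually close (e.g. confined
to a housing well) and noise is peripheral. The known failure mode — an
organism sprinting so fast that it outruns the threshold — is accepted, not
patched.

## Bridging and interpolated positions

A fragment end at frame $t$ and a fragment start at frame $t+j$ are
bridged for $j = 2, \dots,$ `max_search_frame`, smallest $j$ first, with
ties within a gap length resolved by minimum-total-cost assignment. The
window default of 6 encodes the observation that fragments belonging to the
same organism are nearly always separated by fewer than 6 frames; "2nd to
6th frame" is treated as inclusive of 6. No distance gate applies during
bridging — the window is the only constraint — and fragments never bridged
keep their own identities (an organism leaving the field of view returns as
a new identity).

The missing positions are filled by uniform linear interpolation between
the flanking detections: for a gap of $j$ frames the $k$-th estimate is
$x_s + (k/j)(x_t - x_s)$ (likewise for $y$), the one-step case being the
midpoint rule. The estimates are flagged `interpolated = TRUE` and count as
ordinary positions downstream: they keep every trajectory gap-free (so
kinematics are defined at every transition) and they are eligible matches
during evaluation — reconstructing occluded positions is precisely what the
bridging stage is for.

## Kinematics

With $dt = 1/f_s$: velocity is the per-transition displacement divided by
$dt$ (px/s); acceleration is the first finite difference of velocity over
one frame interval (px/s²) — the natural reading of "change of speed" — and
no smoothing is applied by default; heading is `atan2(dy, dx)` in
$(-\pi, \pi]$, reported in image coordinates (y down) with a flag for the
mathematical convention, and *undefined* (NA) for zero displacement rather
than an arbitrary 0. Per-individual summaries report median, mean, min and
max velocity (the box-plot statistics), the same for |acceleration|, and
the count of defined headings.

## Evaluation

Hypotheses and ground truth are matched per frame by minimum-cost
assignment among pairs within `gate` pixels (default: twice the organism
radius; the matching rule is this package's choice, as CLEAR MOT only
presumes a correspondence). Unmatched ground truth counts a miss, an
unmatched hypothesis a false positive, and a matched ground-truth object
whose hypothesis identity differs from its previous matched frame an
identity swap. Then

$$\mathrm{MOTP} = \frac{\sum_{i,t} d_{i,t}}{\sum_t N_t}, \qquad
  \mathrm{MOTA} = 1 - \frac{\sum_t (M_t + FP_t + SII_t)}{\sum_t g_t},$$

with $N_t = g_t$ the ground-truth object count. Using the ground-truth
count in both denominators (rather than the detected count) is what makes
the ideal MOTA exactly 1 for a perfect tracker; MOTP's numerator runs over
matched pairs only, its denominator over all ground-truth objects as
printed. Ground-truth rows flagged invisible (occluded) stay in the
evaluation: their true positions exist, and bridged hypothesis points are
expected to recover them. MOTA may be negative when errors outnumber
objects.

## The synthetic-scene generator

The generator emulates the statistical structure the tracker assumes, not
the appearance of real recordings:

* **Bursty movement** — a two-state Markov chain per organism: a stationary
  organism starts moving with per-frame probability `p_start_move`, a
  moving one stops with `p_stop_move`; the stationary activity fraction is
  their ratio. Defaults (0.06/0.74) give 7.5% activity, the upper end
  reported for larval zebrafish. Burst steps have Gaussian length (4 ± 1
  px/frame) along a slowly wandering heading. Only the activity *proportion* is well characterised for these
  organisms, so the chain is the simplest process matching that statistic.
* **Startle onset** — organisms stay in the moving state for the first
  `startle_frames` (15) frames, mirroring the elevated activity recordings
  show in their first seconds (response to camera/handling). This is also
  what makes the burn-in window informative: each organism clears its own
  footprint early, so the quantile initialisation sees the true background.
* **Walls and collision avoidance** — positions reflect off the frame (or
  an optional `arena` rectangle, the housing well); steps that would bring
  two centres within `min_separation` (3 radii) are suppressed and the
  heading reversed. Separation is thus a generator *invariant*: occlusions
  are produced only by the purpose-built crossing-pair scene, never by
  accident. Real larvae do cross; tests that need overlap use
  `make_crossing_pair()`, which arranges two straight constant-velocity
  paths (a slow cruiser and a faster darter passing over it) whose rendered
  disks form a single component for an exact, chosen number of frames.
* **Noise fragments** — static or drifting disks of configurable area;
  with `noise_appear_prob < 1` they blink: at most one fragment flashes per
  frame, only on alternating frames, so no two flashes are ever adjacent.
  A flash that were to persist across consecutive frames would be tracked —
  correctly — as a (spurious) near-stationary object, which is a property
  of the method, not of the generator; single-frame flashes isolate the
  behaviour the distance gate is designed to remove. A flash in the very
  last frame can never be gated (it is never a source), so noise-bearing
  test scenes use an odd frame count, whose last frame is flash-free.
* **Rendering** — organisms are flat disks (darker than the uniform
  background) plus Gaussian pixel noise; sufficient for centroid-based
  tracking, and deliberately not photorealistic. Rendered blob centroids
  agree with ground truth to < 0.5 px, which bounds the measurement error
  of every downstream accuracy figure.

What passing tests on these scenes shows: correct association, bridging,
gating, metric computation, and segmentation behaviour under the stated
statistical assumptions. What they do not show: robustness to deformable
bodies, shadows, illumination drift, water ripples, or dense crowding —
real-video properties the generator does not emulate.

## Numerical and design notes

* Coordinates are image-convention throughout: x = column, y = row, origin
  at the top-left pixel centre, pixels and frames 0-based in every file
  format.
* Component labelling is 8-connected; labels follow raster order of
  discovery.
* The assignment tie-break, the once-computed gate median, the inclusive
  bridging window, and interpolated points' eligibility in evaluation are
  all deliberate choices documented above.
* Degenerate inputs: empty frames and empty detection tables propagate as
  empty results; an all-rejected frame pair leaves all targets unmatched;
  MOTP/MOTA on empty ground truth are reported as undefined (`NA` with a
  warning) rather than 0.
* The noise-gate validation scene confines three organisms to an 80 × 80 px
  well with five blinking fragments ≥ 274 px away and analyses it with
  `delta = 2`: the worst-case median pairwise distance inside such a well
  is ≤ 113 px, so the threshold is provably below the noise distance —
  rejection there is geometric certainty, not luck. The package default
  stays `delta = 3`.
* Problem sizes used in the validation suite: 480 × 640 px, 90–200-frame
  scenes with 2–5 organisms (the scale of the *Daphnia*-type recordings);
  the Markov-activity check uses a single organism over 10,000 frames.

## Known limitations

* Purely positional costs: no appearance model, no velocity prediction —
  two organisms that swap places while merged beyond the bridging window
  cannot be disambiguated.
* The gate threshold scales with inter-object distances, so it loses power
  when organisms are spread across the whole frame.
* An organism stationary from the first frame through the entire recording
  is indistinguishable from background for any background-subtraction
  method; detection begins with first movement.
* AVI/MP4 containers are not decoded; extract frames to PNG or multi-page
  TIFF first (`ffmpeg -i video.avi frames/%05d.png`).
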