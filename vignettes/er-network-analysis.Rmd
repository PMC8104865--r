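---
title: "Methods: ER network morphometry, tracking and kinetics"
author: "ernetdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ER network morphometry, tracking and kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ernetdyn)
```

## Scope and model

The peripheral endoplasmic reticulum is, in a 2-D confocal section, a
planar graph: tubules are edges, three-way junctions are the dominant
vertices, cisternae are filled patches, and the regions enclosed by the
network ("polygons") shrink as the network densifies. `ernetdyn`
quantifies this architecture from calibrated fluorescence frames
(pixel size in µm, frame interval in s) and its dynamics from
time lapses, and ships a synthetic generator with exact ground truth so
that every stage is testable.

Coordinates are 0-based, x right, y down, pixel centers at integer
coordinates; all files written by the package record this convention.

## Segmentation

`normalize_frame()` rescales the `low_pct`–`high_pct` percentile window
(defaults 0.5/99.5) to [0, 1]. Percentile rescaling is this package's
concrete choice for intensity uniformization; it is affine-invariant
and robust to hot pixels, and the percentiles used are echoed into every
run report. A frame whose intensity range is relatively smaller than
10⁻⁹ is rejected as constant — this guards against meaningless
thresholds being computed from pure floating-point ripple after
smoothing.

`otsu_threshold()` maximizes between-class variance over an `n_bins`
histogram (default 256, right-closed bins). Foreground is *strictly
above* the returned threshold, fixing the ambiguity Otsu's method
leaves open, so masks are reproducible bit for bit; ties in the
variance scan break toward the smaller threshold. The pipeline smooths
with a Gaussian of `smooth_sigma_px` (default 1.2 px, matched to the
default PSF width) before thresholding; this matched filter suppresses
shot-noise raggedness in the mask that would otherwise fragment the
skeleton.

`enhance_tubules()` computes a phase-congruency map from a log-Gabor
quadrature filter bank (defaults: 4 scales, 6 orientations, minimum
wavelength 3 px, scale multiplier 2.1, bandwidth parameter 0.55).
Phase congruency is contrast-invariant and peaks on ridge-like
structures, which makes it a useful gate for dim tubules; the noise
floor is estimated from the median smallest-scale amplitude (Rayleigh
model, mean + 2 SD). The method's published description names no
parameter values, so the defaults above are this package's choice and
are recorded per run.

`detect_cisternae()` opens the mask with a disc (default radius 3 px —
about one tubule width, so tubules vanish and sheets survive) and
refines each surviving component with a region-based (Chan–Vese-style)
active contour for `ac_iterations` (default 50) steps: pixels move to
the side (inside/outside) whose mean intensity they are closer to, with
a 3×3 majority rule playing the role of the curvature penalty.
Region-based evolution was chosen over edge-based snakes because
cisternae are bright, homogeneous patches with weak edges against the
tubule mesh.

## Skeleton and morphometry

`skeletonize_mask()` applies Zhang–Suen thinning followed by a
simple-pixel cleanup pass that removes the staircase artifacts the
thinning leaves behind (pixels whose foreground neighbors remain
mutually connected and whose removal cannot merge background regions;
end points are never removed). Without this pass, mid-tubule staircase
pixels carry three neighbors and masquerade as junctions — on synthetic
networks they roughly doubled the apparent junction count. The result
is a minimal 8-connected skeleton: no fully set 2×2 block remains,
components and holes are preserved.

`classify_pixels()` uses the standard neighbor-count classes
(≤ 1 end point, 2 tubule, ≥ 3 junction); isolated pixels count as end
points. `junction_tubule_ratio()` reports junction over tubule pixel
counts by default; whether the published ratio counted pixels or
objects is not stated, so object counting (junction components over
branch segments) is exposed as `mode = "objects"`.

`extract_polygons()` labels the background of skeleton ∪ cisternae and
keeps components that do not touch the image border (unbounded regions
have undefined area). Foreground objects use 8-connectivity throughout
the package, but polygon extraction labels the background with
4-connectivity: this is the topological dual — an 8-connected
single-pixel diagonal line does not separate an 8-connected background,
so enclosed regions would leak through diagonals otherwise. Perimeter
is the contour step length (1 axial, √2 diagonal, the same metric as
branch lengths); for degenerate regions of one or two boundary pixels
the equivalent-circle perimeter 2√(πA) is used so circularity stays
bounded. Circularity 4πA/P² is checked in tests with a 5%
discretization allowance (a digitized circle measures ≈ 0.94).
Elongation is the major/minor axis ratio of the second-moment ellipse
(with the 1/12 per-pixel variance term), the standard reading of
"elongation" absent a printed formula.

`branch_lengths()` walks maximal tubule-pixel paths between critical
(end-point/junction) pixels; pure loops count once. Two directly
adjacent junction pixels with no tubule between them contribute no
branch.

## Junction tracking

`make_spot_image()` keeps junction-class components larger than
`min_junction_px` (default 3 px, strict), multiplies them by the raw
frame intensity and blurs with `blur_sigma_px` (default 2 px). A
single-pixel skeleton usually yields 1–2 px junction clusters, which
the "> 3 px" filter would annihilate; the pipeline therefore first
grows junction pixels into the binary mask (`junction_grow_px`,
default 2 px), recovering tubule-width junction objects. The growth is
an explicit optional argument — with the default 0 the operation
matches its plain contract.

`detect_spots()` takes local maxima above a threshold (pipeline
default: 10% of the spot-image maximum), enforces a minimum separation
(default 5 px, brightest first) and refines positions with the
intensity-weighted 3×3 centroid.

`link_spots()` solves, per frame pair, the extended linear assignment
problem with cost = squared distance, links beyond `max_link_px`
(default 7 px) forbidden, and birth/death alternatives priced at
`max_link_px²`. Pricing the alternatives at the radius cost makes
"forbidden beyond the radius" exact: a link is taken iff its distance
is below the radius and it lowers the global cost. The candidate graph
is first split into connected components (cross-component links are all
forbidden), and each component is solved exactly with a dense
Jonker–Volgenant-style solver — the decomposition changes nothing about
optimality and keeps each solve tiny. `close_gaps()` runs a second
assignment between tracklet ends and starts (default 10 px, 1–3 skipped
frames; "max frame gap of 3" is read as 3 frames — a frame gap is
temporal by definition). Chains of merges are followed; no tracklet is
used twice.

`filter_tracks()` keeps tracks *longer than* `min_frames` (default 10,
strict: a 10-frame track is removed). Length is counted as frames with
a detection, which also discards sparse chains glued together by gap
closing; first-to-last span is available as `measure = "span"`, and the
two agree on gapless tracks.

`velocity_stats()` reports one speed per consecutive spot pair
(gap-spanning pairs use their true elapsed time) and the cumulative
distribution; speeds are magnitudes since the published distribution is
one-dimensional. `estimate_diffusion()` fits the ensemble MSD over lags
1–4 by weighted least squares (weights = pair counts) and reports
D = slope/4. The exact instantaneous-velocity-based formula referenced
by the original pipeline is not reproduced in print, so the MSD fit is
this package's documented estimator. The default fit includes a free
intercept: localization error adds a constant ≈ 4σ_loc² to every MSD
lag, and a through-origin fit would inherit a bias of order
σ_loc²/(DΔt) — at D = 0.01 µm²/s and Δt = 0.1 s that exceeds 25% for
σ_loc ≳ 0.25 px, swamping the quantity of interest. A zero-intercept
fit remains available (`intercept = "zero"`) and is appropriate for
noise-free coordinates. Negative slopes clip to D = 0 with a flag.

## Kinetics

`integrated_roi_trace()` sums intensities in a disc or polygon ROI per
frame and subtracts an equal-pixel-count background ROI (size equality
is enforced in pixels; shape is free — discs by default, since only
"identical size" is prescribed). `normalize_trace()` implements the two
published modes — minmax (initial → 0, max → 1) and max-division — both
idempotent, with errors on constant or non-positive input.
`radial_traces()` places minmax-normalized ROIs at fixed distances
(default 8/12/16 µm) along a bearing (default: toward the image
center); the ROI radius is deliberately a required choice with a plain
default (6 px) because no radius is published. The matching acquisition
default is 1 frame per 500 ms for 90 s; the dynamics default of
1 frame per 100 ms for 5 s matches the live-imaging acquisition.

## The synthetic generator

`generate_network()` builds a jittered-Voronoi tessellation by exact
half-plane clipping. Generic Voronoi vertices are three-way, so the
ground-truth junction count is the interior vertex count; bounded cells
(cells not touching the field border) are the ground-truth polygons.
Vertices are deduplicated at 10⁻⁵ px; edges running along the field
border are excluded, and isolated corner vertices are dropped. Fields
smaller than 8 px mean seed spacing are rejected as degenerate.
`render_network()` draws edges as 1-px Bresenham lines, adds optional
cisterna discs, convolves with a Gaussian PSF (default σ 1.2 px ≈ a
120-nm-SD PSF at 100 nm/px) and applies Poisson shot noise plus
Gaussian read noise (default SD 2) — chosen because the model is
moment-checkable (background variance = mean + σ_read²).
`simulate_dynamics()` moves every interior vertex by independent 2-D
Brownian steps of per-axis variance 2DΔt while border vertices stay
fixed, redrawing edges each frame and recording exact trajectories.
`simulate_photoactivation()` propagates an activated disc with the
Gaussian heat kernel under reflective boundaries (mass-conserving), and
`simulate_transport_trace()` produces 1 − exp(−k(t−t₀)) rises.

Default study conditions (the package's own choice of realistic scale):
100 nm pixels, 0.1 s frame interval, tubule peak ≈ 100 counts over
background 5, read noise 2; morphometry recovery uses 20 networks of
30 seeds on 256² px; dynamics uses 140 seeds on 640² px (≈ 235 interior
junctions) for 50 frames at D ∈ {0.01, 0.05, 0.2} µm²/s; luminal
spread uses D = 2.5 µm²/s on 400² px for 60 s. These sizes keep the
default validation runs comfortably on a laptop while leaving estimator
noise well below the tolerances being checked.

What the generator deliberately does *not* emulate: photobleaching,
3-D geometry, tubule elongation/retraction and cisterna remodeling,
uneven illumination, and motion of the network between Voronoi
topologies. Passing tests therefore demonstrate correctness of the
measurement chain under a known forward model, not robustness to every
property of real micrographs. Two consequences observed on the
synthetic data are worth knowing: first, jittered-Voronoi geometry
contains near-degenerate vertex pairs (very short edges) that merge
into a single spot under the PSF, so a tracked spot may follow the
centroid of a sub-resolution junction pair rather than one vertex —
the tracker-fidelity invariant is therefore checked on a
hexagonal-lattice network whose edges are uniformly resolvable; second,
at high D the Brownian vertices wander across edge lengths and the
drawn network self-intersects (the generator warns when the step SD
exceeds a quarter of the mean edge length).

## Numerical choices and degenerate inputs

Assignment problems with no feasible perfect matching raise an error
(they cannot occur with birth/death alternatives present). Constant
frames are rejected by normalization and thresholding; empty masks
cannot be skeletonized; a skeleton without tubule pixels has no defined
junction/tubule ratio; traces that never rise cannot be
minmax-normalized, and `radial_traces()` propagates that error
per distance. Empty spot lists, empty polygon lists and empty track
lists are valid results, not errors. All generator operations are pure
functions of their arguments including the seed; a single top-level
seed spawns per-stage child seeds deterministically (`child_seed()`),
so whole runs are reproducible and two stages never share a stream.

## Limitations

- 2-D only; overlapping tubules in thick cells will read as junctions.
- The diffusion estimator assumes free diffusion over lags 1–4; confined
  or directed motion is out of scope (no motion-model switching).
- Group summaries report means ± SD only; inferential statistics are
  intentionally left to downstream tools.
- The phase-congruency gate roughly doubles per-frame cost and is off
  by default in the pipeline; it pays off mainly for low-contrast
  tubules.
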