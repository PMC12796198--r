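---
title: "Queue-driven smart microscopy: models and design choices"
author: "autoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Queue-driven smart microscopy: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind **autoscope** — the acquisition
engine, the coordinate conventions, the analysis building blocks, and the
simulated microscope — together with the design decisions taken where several
reasonable choices existed, and what the desk-scale simulations do and do not
demonstrate about real instruments.

# The acquisition model

An experiment is a dynamic priority queue of *acquisition tasks*. Each task
carries a hierarchy level, one or more named *configurations* (complete
parameter trees imaged back-to-back at one location, e.g. the same ROI with
2D and 3D depletion patterns), a delay in seconds, and the sequence number
assigned at enqueue time. Pop order is ascending (level rank, sequence)
among tasks whose eligible time (enqueue clock + delay) has passed: lower
rank preempts, FIFO within a level, and pop order is therefore total and
deterministic. When only future-eligible tasks remain, the loop advances the
clock to the earliest eligible time — this single mechanism supports both
fixed-sample pipelines (delay 0 throughout) and reactive timelapse imaging
(long-delay search frames, short-delay event frames).

Parameter trees are nested named lists under a canonical schema
(`stage/x|y|z` µm, `scan/offset`, `scan/range`, `scan/pixel` per axis in µm,
`mode`, `channels`, `power` %, `dwell` s). A backend adapter is expected to
map canonical paths onto its own namespace; nothing else in the package
needs to know a vendor's key names.

Callbacks attached to a level run after every acquisition on that level, in
registration order, *after* the measurement has been persisted — so a
detector always reads stored data, and a crash between acquisition and
analysis loses nothing. A callback exception is logged and the remaining
callbacks still run (an unattended overnight run must not die because one
detector threw on one odd image); `abortOnError = TRUE` reverses this.
Stopping criteria are pure predicates over the loop state, evaluated once
per iteration after all callbacks — not between them, so one iteration's
task generation is atomic.

## Task generation and broadcasting

Generators are ordered lists of *building blocks*, each a function of the
loop state returning a list of partial parameter trees: length 0 vetoes the
invocation, length 1 broadcasts against the others, length N produces N
tasks. All lengths above 1 must agree, otherwise a broadcast-mismatch error
names the offending blocks. Merging is a recursive deep merge in block order
with three fixed rules: later blocks override earlier ones on leaf
conflicts; list/vector leaves are replaced wholesale, never concatenated;
a scalar and a subtree at the same path is a structural error. Later-wins
makes "general settings first, then specifics" read naturally; element-wise
list merging was rejected as unpredictable. Deep merge is associative on
conflict-free inputs and has the empty tree as identity, both checked by
randomized property tests.

Configuration *variants* multiply configurations **within one task** rather
than emitting separate tasks: the variants are imaged back-to-back at one
location without re-queueing, matching the measurement/configuration model
of point-scanning control software.

The spiral position generator is fixed as the outward square spiral
(+x, +y once; −x, −y twice; +x, +y three times; …), chosen because it is
parameter-free and space-filling; its first five steps from the origin at
pitch 1 are (0,0), (1,0), (1,1), (0,1), (−1,1).

# Coordinates and ROI bookkeeping

Pixel indices are 0-based and may be fractional. Along each axis the
physical coordinate of index *i* is
`stage + offset − range/2 + (i + 0.5) · pixel` (pixel-centre convention);
arrays are stored `[channel, z, y, x]`. Out-of-grid indices extrapolate
linearly rather than erroring — sub-pixel detection refinement near an edge
should translate, not crash. Scan windows derived from detected ROIs reuse
the parent's stage position (offsets move the scanner, not the stage),
ranges are padded to a per-axis minimum field of view (degenerate point ROIs
are valid input), and an ROI whose window would exceed the scanner limits is
skipped with a log entry instead of raising — again, long unattended runs
must survive edge detections.

Re-detections of already-imaged objects are discarded by an append-only ROI
registry: a candidate box is dropped iff its 3D IoU with any registered box
exceeds 0.3 **or** its centre lies inside a registered box. The IoU
threshold and the centre rule are this package's choice: IoU alone misses
the case of a small re-detection nested inside a large imaged region, which
the centre test catches cheaply.

# Analysis building blocks

*Spot detection* is difference-of-Gaussians (σ small < σ large, in px):
local maxima of the response above a threshold, kept greedily in descending
response order under a minimum pairwise separation, with 3-point parabolic
sub-pixel refinement per axis (clamped to ±0.5 px; maxima on the outermost
pixel ring are ignored because they cannot be refined).
*Colocalization* pairs two channels' detections greedily in ascending
distance order, one-to-one, keeping pairs within a pixel radius; greedy
(rather than optimal-assignment) matching is adequate at DNA-FISH spot
densities, where pairs are far sparser than the matching radius.

*Segmentation* defaults to thresholding plus 26-connected 3D components
(frontier flood fill), size-filtered and relabelled 1..L in descending size.
Learned segmenters plug in through the same integer label-mask contract.
*Pole extraction* takes, per axis, the centroid of the voxels attaining the
extreme coordinate (the centroid resolves ties over the whole extreme set)
and returns six cubes of the tile size centred there; a single-voxel mask
degenerates to six coincident tiles, which downstream deduplication
collapses.

*Pre-scan gating* is the plain intensity criterion — pass iff at least 50
pixels exceed 50 counts — applied to a very coarse (1 µm pixel) scan, so
empty fields of view are skipped at a tiny fraction of an overview's cost.

*Focus updates* score each plane of the triggering z-stack and emit a
corrected absolute stage z, clamped to ±`maxStep` (default 1 µm) per
update; when the metric's peak-to-mean ratio is below `minContrast`
(default 1.05, i.e. an empty field of view) the correction is zero and
flagged unconfident. The metric is **plain intensity variance**. Two
mean-normalized variants were implemented and rejected on measured
behaviour: variance/mean² peaks at the stack extremes for plateau-like
objects (nuclei), and variance/mean is centre-peaked only while objects
cover less than roughly offset/brightness (~10 %) of the plane, which made
focus tracking unstable at realistic densities. Plain variance of a
plateau object peaks at the plane of largest cross-section — the nucleus
equator — for any coverage below one half. The best plane is refined by
parabolic interpolation around the argmax (skipped at the stack ends). Note
the corrections are derived from the *previous* field of view's stack, so
the applied focus lags the sample surface by one grid step; this lag is
visible as a small systematic underestimate when regressing applied focus
positions on stage coordinates.

*Stitching* selects previously acquired same-level tiles whose scan windows
overlap the current one laterally and fuses their z-maximum projections on
a canvas aligned with the current tile's pixel lattice, placed by stage/scan
coordinates alone or with an extra integer-pixel phase-correlation
registration of each neighbour against the current tile's overlap region
(minimum 8 px overlap; correlation peaks below 0.05 fall back to zero
shift, e.g. featureless overlaps). Fusion is "latest wins": the newest data
are the least drifted, and a provenance map records the source tile per
pixel. The canvas keeps the current overview's z extent as one thick plane,
so boxes detected on it inherit the overview's depth; fusing full 3D
volumes was rejected as needless for detection. The current tile is never
shifted — everything registers *to* it.

# The simulated microscope

The simulator exists to exercise control logic at desk scale, not to model
photophysics quantitatively.

**Scene.** Nuclei are axis-aligned ellipsoids resting on a tilted slide
surface `z = a·x + b·y + c`, carrying a diffuse body stain with a soft edge;
spots are point emitters either on the ellipsoid shell (nuclear-pore-like)
or as interior two-channel pairs at a fixed small separation (DNA-FISH-like,
80 nm default); transient *events* are extended emitters (default Gaussian
extent 0.8 µm — a signalling transient is not a diffraction-limited point)
existing over a clock interval. Placement is a seeded Poisson process with
overlap rejection; identical seeds give byte-identical scenes. Default
nucleus semi-axes are 4–6 µm lateral and 2–3 µm axial (Jurkat-like ~10 µm
nuclei); spot peak brightness defaults to 150 expected counts and the body
stain to 120 counts per voxel at the reference settings (30 % power, 10 µs
dwell).

**Optics.** Gaussian PSFs per mode: confocal σ 0.11 µm lateral / 0.30 µm
axial; 2D-depletion STED σ 0.035 µm lateral (axial unchanged); 3D-depletion
σ 0.045 µm lateral / 0.10 µm axial. The lateral σ grows by 1 %/µm of
height above the slide (refractive mismatch away from the coverslip).
Emitters render as amplitude × Gaussian; expected counts are linear in
dwell and power by construction. Shot noise is Poisson, plus rounded
Gaussian read noise (σ 1) and a detector offset (2 counts), stored as
16-bit with saturation. Vectorial/Airy PSFs, triplet dynamics and adaptive
illumination are deliberately out of scope.

**Bleaching.** Each z-plane exposure delivers dose to every spot in the
scanned xy column — the illumination cone traverses the whole depth, which
is exactly the mechanism that builds the along-stack brightness gradient
when a whole volume is scanned coverslip-to-interior. Remaining brightness
multiplies by `exp(−dose)` per plane; the in-focus dose rate is 0.022 per
plane for STED (60× less for confocal) at reference power/dwell, chosen so
a typical whole-nucleus STED stack loses ≈40 % from bottom to top. A
Lorentzian axial attenuation of the dose (`1/(1+(Δz/zR)²)`) is available;
the default is the uniform column, which keeps the dose of a small tile low
relative to a full stack. Pole tiles are acquired deepest-first in the
benchmark, so the dimmest, most aberrated regions are recorded before any
further exposure of their column.

**Clock.** Acquisition time = per-measurement setup (0.3 s) + per-plane
settling (20 ms) + per-line flyback (0.2 ms) + dwell × voxels + stage
travel (10 ms/µm) — realistic galvo-scanner magnitudes that reproduce the
defining scaling of point-scanning microscopy: time grows with scanned
volume, so six 2×2×2 µm pole tiles are cheaper than one whole-nucleus
stack, increasingly so for larger nuclei.

**Drift.** A seeded random walk (σ per √minute, advanced between query
times) plus a deterministic thermal sinusoid that vanishes at t = 0. Drift
is frozen within one acquisition (applied per measurement, not per line) —
a documented simplification that keeps rendering simple while still
displacing neighbouring tiles relative to each other.

**Determinism.** Every stochastic element (scene, noise, drift steps) draws
from sub-seeds derived from the scene seed and an operation counter, with
the user's RNG state saved and restored; identical seed + configuration
yields byte-identical logs and stores, which the test suite asserts.

# Study conditions and problem sizes

The scenario functions fix the desk-scale study conditions: the focus-map
demo runs a serpentine 10×10 grid at 50 µm pitch over a slide tilted by
(a, b) = (0.004, −0.006) — a few µm per mm, a realistically uneven slide —
with ~4 nuclei per field of view and 10-plane overview stacks (0.4 µm z
pixel). The bleaching benchmark uses 20 single-nucleus scenes with 60
surface spots each, whole-nucleus STED stacks at 60 nm lateral / 250 nm
axial pixels versus six 2 µm pole tiles; brightness is read at ground-truth
spot positions and summarized as per-depth-bin (stack) or per-tile (poles)
medians per nucleus before pooling, mirroring a per-cell parts-of-the-stack
comparison. The stitching comparison uses a row of three 50 µm tiles at
48 µm pitch (2 µm overlap) with border nuclei wider than the overlap; the
pre-scan sweep covers six densities from 0.25 to 8 nuclei per field of view
on 5×5 grids; the reactive timelapse watches one location with 30 s search
and 2 s event delays around a scripted 95–160 s event. These sizes keep any
single scenario under a minute on one CPU while leaving every mechanism —
priority preemption, broadcasting, dedup, gating, registration, bleaching,
delays — exercised end-to-end.

# What passing the simulations does and does not show

The simulator reproduces *directions and mechanisms*: bleaching declines
along a whole stack but not across pole tiles; pole tiles are faster and
increasingly so for larger nuclei; stitching recovers border objects;
skipped-FOV fraction falls with density; focus tracking recovers slide
tilt. The corresponding real-instrument magnitudes (absolute speedups,
bleaching floors, pre-scan times) are properties of specific hardware,
samples and settings and are **not** claimed or calibrated here. Real data
also contain structured backgrounds, aberrations and segmentation failure
modes the scene model does not emulate, so detector thresholds tuned in
simulation are starting points, not transferable constants.

# Known limitations

Single-threaded acquisition only; no live hardware adapter is bundled (the
microscope interface is four generics, and the simulator demonstrates the
swap); stitching fuses 2D projections, not volumes; bounding boxes are
axis-aligned; the bleach model has one rate per mode and no recovery;
proprietary container formats are not read or written — measurements
persist as multi-page 16-bit TIFF plus a JSON sidecar carrying everything a
proprietary container would.
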