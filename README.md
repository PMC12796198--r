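# autoscope

A queue-driven automation engine for smart (feedback) microscopy, with a
simulated confocal/STED microscope so that complete acquisition pipelines run
and are testable entirely at desk scale.

Point-scanning super-resolution (STED) trades resolution for speed and
photobleaching: acquisition time scales with the scanned volume, and every
exposure consumes fluorophores. Both costs drop dramatically when the
microscope images *selectively* — fast confocal overviews find the objects
worth imaging, and slow, damaging super-resolution scans are spent only on
small regions of interest. Automating that decision loop is what this package
does. It is aimed at microscopists and imaging-facility developers who want
to prototype, test and reason about smart-microscopy pipelines (hierarchical
overview–detail imaging, pre-scan gating, on-the-fly stitching, software
autofocus, reactive timelapse) without a microscope attached.

## The engine

An experiment is a **dynamic priority queue of acquisition tasks**. A task
wraps one or more *configurations* — complete measurement parameter trees
(stage position, scan offsets/ranges, pixel sizes, imaging mode, powers,
dwell) imaged back-to-back at one location — plus a hierarchy level and an
optional delay. The main loop repeats:

1. pop the highest-priority eligible task — ascending (level rank, sequence),
   so details (rank 1) preempt overviews (rank 2), FIFO within a level;
2. apply each configuration and acquire; persist the measurement;
3. run the level's callbacks, which analyse the new image and may enqueue
   further tasks;
4. evaluate stopping criteria (image count, elapsed time, "nothing found for
   k fields of view", custom predicates).

Callbacks are `AcquisitionTaskGenerator`s assembled from small **building
blocks**, each emitting 0 (veto), 1 or N partial parameter trees; outputs are
broadcast (singletons repeated to length N) and deep-merged in block order
into complete tasks. Shipped blocks include constant settings from file,
grid/spiral/list stage positions, stage inheritance, image-based focus
updates, difference-of-Gaussians spot detection with two-channel
colocalization, threshold + 26-connected-components 3D segmentation,
pole-tile extraction, pre-scan gating (50 pixels above 50 counts), and
on-the-fly tile stitching with phase-correlation registration and
already-imaged-ROI discard (IoU > 0.3 or centre containment).

The microscope is an interface of four generics (`applyParameters`,
`acquireFrame`, `clockTime`, `waitUntil`). The bundled
`simulatedMicroscope()` renders a seeded `VirtualScene` (ellipsoidal nuclei
on a tilted slide, pore-like surface spots, colocalizing FISH-like spot
pairs, transient events) with Gaussian mode-dependent PSFs, Poisson + read
noise, dose-dependent per-spot photobleaching, stage drift and a simulated
acquisition clock — so an entire overnight experiment runs in seconds,
deterministically for a given seed.

## A worked example

```r
library(autoscope)
demo <- runHierarchicalDemo(seed = 1)
demo$log
#> ExperimentLog: 12 acquisition(s), stopped for 'max-images:12' at clock 63.74s
demo$counts
#>   detail overview
#>        8        4
head(demo$acquisitions[, c("level", "sequence", "clock", "x", "y")], 6)
#>      level sequence clock   x   y
#> 1 overview        1 14.65  80  80
#> 2   detail        2 15.12  80  80
#> 3 overview        3 30.22 125  80
#> 4 overview        4 45.31 125 125
#> 5   detail        5 45.79 125 125
#> 6   detail        6 46.27 125 125
```

Confocal overviews walk an outward spiral over a simulated slide; after each
overview, colocalizing two-channel spot pairs are detected and 2 µm STED
detail stacks are enqueued at higher priority around them — the log shows the
details being imaged *before* the next overview, and the clock is the
simulated acquisition clock (an overview of 334×334×12 voxels costs ~15 s,
a detail stack ~0.5 s). The ROI registry deduplicates re-detections across
overlapping fields of view.

The same pipelines can be described declaratively; a two-level demo ships
with the package:

```sh
Rscript inst/cli/autoscope.R run inst/extdata/demo.yaml \
    --max-images 10 --seed 1 --out out/
Rscript inst/cli/autoscope.R summarize out/
```

which writes 16-bit TIFF stacks plus JSON sidecars, a JSONL event log, a
focus-map CSV and the ROI-registry audit file under `out/`.

Higher-level studies are packaged as scenario functions:
`runFocusMapDemo()` (software autofocus across a tilted 10×10 stage grid),
`runBleachingBenchmark()` (whole-nucleus STED stacks vs six 2×2×2 µm pole
tiles: along-stack bleaching gradient, none across tiles, and pole tiles
faster on every nucleus), `runStitchComparison()` (border-straddling nuclei
recovered only with on-the-fly stitching), `runPrescanSweep()` (fraction of
skipped fields of view vs sample density) and `runReactiveTimelapse()`
(delay-based slow-search/fast-event imaging).

## Limitations

The simulator uses Gaussian PSFs and a simple exponential dose-bleaching
model — adequate for exercising control logic, not for quantitative
photophysics. Live hardware adapters (e.g. for Imspector-controlled
microscopes), proprietary container formats and learned segmentation models
are out of scope; the latter plug in through the detector/label-mask
contracts. See the methods vignette (`vignettes/methods.Rmd`) for the full
model description and design rationale.
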