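---
title: "Methods: registration, segmentation and motif mapping in mesomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: registration, segmentation and motif mapping in mesomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesomap)
```

# The problem

Mesoscale wide-field imaging records fluorescence from the whole dorsal
cortex of a mouse through a transparent-skull window. Group analysis
requires mapping every recording into a common anatomical frame. `mesomap`
implements that mapping as a deterministic, testable toolchain: landmark
registration in both directions, boundary segmentation and its quality
metrics, region-ROI extraction, and functional-map construction from
spontaneous activity motifs. Trained neural detectors (landmark and
boundary networks, deformation-field estimators) are deliberately outside
the package: their outputs enter through provider interfaces (landmark
CSVs, mask files, deformation-field TIFFs), and a synthetic phantom
generator supplies ground-truth inputs for validation.

# Coordinate conventions

Pixel coordinates are `(row, col)`, 1-based, pixel centers at integers,
rows increasing posterior — the native indexing of R matrices, applied
uniformly so warps, masks and landmark tables never mix conventions. The
millimetre frame is anchored at bregma (`(0, 0)` mm): x is lateral
(positive toward increasing columns), y anterior (positive toward
decreasing rows). The default scale of the bundled atlas is 0.05 mm/px, a
typical magnification for a ~12 mm field of view on a 256-px sensor; it is
a parameter of `coord_system()`, not an assumption.

# The bundled atlas and the nine landmarks

`synthetic_atlas()` draws a 256 x 256, exactly mirror-symmetric
parcellation: an elliptical cortex split at the midline into 10 paired
regions per hemisphere (motor strip, somatosensory block, visual and
retrosplenial sectors). It is a stand-in with the same structure as an
Allen-derived top-view parcellation — integer label image, region table,
mirrored acronyms — so every test and example runs without external data;
a real atlas loads through `load_atlas()` unchanged.

Nine landmarks drive registration: the lateral extreme, frontal-pole tip
and posterior retrosplenial tip of each hemisphere, plus the top-center
midline point, bregma and lambda. Their millimetre coordinates default to
positions computed from the bundled atlas geometry; users with a published
coordinate table supply it via `read_landmark_defs()` and the defaults are
ignored. This was a genuinely open choice: the alternative — hard-coding
one published table — would have tied the package to a specific atlas
build, while geometric defaults keep the synthetic ground truth exactly
self-consistent.

# Registration

Per hemisphere the available-landmark ladder is:

1. **Three usable landmarks or more**: an exact three-point affine through
   a selected triple. The default triples are (lateral extreme, top-center,
   lambda) per hemisphere; `mode = "confidence"` instead maximizes summed
   detector confidence over all non-collinear triples (ties resolve to the
   default triple, so equal confidences reproduce the default behavior);
   `mode = "user"` passes explicit triples, falling back to the first three
   indices on the left and the last three on the right.
2. **Exactly two**: a two-point similarity (rotation + uniform scale +
   translation, never shear or reflection).
3. **One hemisphere empty**: one whole-brain transform fitted on every
   usable point.

A landmark is *usable* when its confidence reaches `min_confidence`
(default 0.5, configurable). The mock detector's confidence model,
`exp(-d^2 / 2 sigma^2)` with `d` the sampled jitter, means benchmark runs
with deliberate jitter pass `min_confidence = 0` — the threshold is a
guard against poor detections on real data, not part of the geometry.

The two hemisphere warps meet at the midline: the line through the
observed bregma and lambda when both exist, else the vertical through
bregma. Each output pixel is assigned by exactly one hemisphere according
to its side of that line; one nearest-region dilation pass closes
single-pixel seam gaps, and the result is clipped to the brain mask. The
collinearity screen for triples uses triangle area below
`1e-6 x (image diagonal)^2`. In brain-to-atlas direction an optional
olfactory-bulb mask is warped with its hemisphere's transform and
composited onto the atlas canvas. Piecewise-affine registration
(Delaunay-triangulated control points, per-triangle exact affines,
nearest-triangle extrapolation outside the hull) covers alignment from
sensory activation peaks; dense deformation fields are *consumed*
(`apply_deformation()`), never estimated.

Intensity images are resampled bilinearly; label and mask images use
nearest-neighbor so IDs stay integral.

# Segmentation and metrics

The boundary baseline is Otsu's threshold on a 256-bin histogram after
min-max scaling to [0, 255], followed by mask cleaning (largest connected
component, hole filling). Ties among maximizing bins resolve to the lowest
bin; the threshold is reported on the original intensity scale.

The four quality metrics: percent area difference is
`100 x |pred XOR truth| / (H x W)` — frame-normalized, the only
denominator that is stable under crops and rescaling; SSIM uses the
standard luminance-contrast-structure form with an 11 x 11 Gaussian window
(sigma 1.5), `k1 = 0.01`, `k2 = 0.03`, dynamic range 255; PSNR is
`10 log10(max^2 / MSE)` with an infinite sentinel for identical images.

Vessels are flagged by adaptive thresholding (pixel below local block mean
minus an offset) and removed by fast-marching inpainting: hole pixels are
filled boundary-inward in increasing distance-to-known order, each
replaced by an inverse-squared-distance-weighted average of first-order
estimates from known pixels within a radius (default 3 px). The
gradient-extrapolation term is what lets linear intensity ramps
reconstruct essentially exactly; a plain weighted mean of values plateaus
at the hole boundary and misses a ramp's interior by ~10%.

# ROI extraction

Region ROIs come from the warped label image: optional one-pass 3 x 3
dilation (background pixels take the smallest neighboring region ID —
a deterministic tie rule, applied to the composite label image), contour
tracing along the 0.5-level between region and background pixels (outer
boundaries only, counter-clockwise), and the pole of inaccessibility as
the label anchor. The pole is found by quadtree grid refinement: cells are
prioritized by center-distance plus half-diagonal and subdivided until no
cell can beat the incumbent by more than the precision (default 0.5 px;
the returned clearance is within precision of the true maximum). Spatial
numbering orders ROI centers by column then row per hemisphere; any
maximal chain of centers whose columns pairwise differ by less than 5 px
is treated as one vertically aligned group and re-sorted top to bottom.
Chaining (20, 24, 28 forming one group) is the resolution chosen for the
transitivity question the pairwise rule leaves open — it is the only
order-independent closure of the relation. Export goes to JSON (lossless
round-trip, mask stored as linear pixel indices) or a minimal MAT-file
(one uint8 mask per ROI, readable by MATLAB and `scipy.io.loadmat`).

# Activity and motifs

ΔF/F is `(F - F0) / F0` with `F0` the per-pixel mean over a configurable
baseline window — the full recording for spontaneous data, the
pre-stimulus frames for evoked data (the baseline definition is exposed
because no single choice suits both). Stimulus-triggered averages cut
`pre + post` windows around event frames; sensory maps take the per-pixel
post-stimulus maximum, with the argmax peak (ties toward smaller row then
column) and the intensity-weighted centroid of pixels at or above 0.75 of
the maximum.

Motif discovery is convolutional NMF by multiplicative updates on the
masked pixels-by-time matrix. The objective is the halved squared
Frobenius reconstruction error plus `lambda` times a cross-orthogonality
penalty (the smoothed overlap between one motif's data correlation and
another's temporal weights) that discourages two motifs from explaining
the same events. `lambda` defaults to 0 — the planted-motif simulations
separate cleanly without it — and is exposed because real recordings with
correlated motifs need it; updates are deterministic given the seed, keep
both factors nonnegative, and the objective trace is non-increasing to
within 1e-6 relative per step. Motif images are per-motif maximum temporal
projections, zeroed outside the brain mask and min-max normalized; an MBFM
is the pointwise maximum of normalized motif images.

Clustering is PhenoGraph-style: k-nearest neighbors (Euclidean, default
k = 15 truncated to n-1), edges weighted by the Jaccard overlap of
neighbor sets, Louvain community detection (igraph) with seed-controlled
tie-breaking, labels relabeled by descending community size. Silhouette
scores use Euclidean distances with the standard zero convention for
singletons. Templates are built per cluster from its "center" motifs — the
members whose mean correlation with the rest of the cluster falls in the
top half (configurable quantile); clusters are ranked by size and the six
largest kept by default. Matching assigns each new motif to its
best-correlated template when Pearson r reaches the threshold (default
0.5, configurable; ties to the lower template index) — the threshold value
is a package default, chosen as the midpoint between unrelated (~0) and
same-pattern (~1) correlations observed on the synthetic motifs.

# The phantom generator

`make_phantom()` scales the bundled atlas into the requested frame and
renders a two-level cortex-on-background image with optional dark Bezier
vessel curves and additive Gaussian noise (defaults: 256 x 256 frame,
intensities 20/200 on the 8-bit scale, noise sd 5, six vessels of width
3 px — contrast and vessel density in the range of single raw GCaMP
frames). Misalignments are similarity transforms sampled from configurable
ranges (defaults ±30°, scale 0.8–1.2, translation ±20 px, the ranges used
throughout the registration benchmarks); shear is deliberately excluded
since skull-mounted imaging misaligns rigidly up to magnification.
Activity simulation plants K region-footprint motifs with half-sine
temporal envelopes and a lateral sweep, convolves them with random onset
trains and adds zero-clipped Gaussian noise (default sd 0.2 of the motif
amplitude).

What the phantom does *not* emulate: realistic vascular trees, hemodynamic
contamination, regional expression gradients, breathing/motion artifacts,
or non-rigid tissue deformation. Passing tests therefore demonstrate the
correctness of the geometry, factorization and bookkeeping — not detector
robustness on real images, which belongs to the out-of-scope trained
models.

# Numerical choices and degenerate inputs

* Collinear point sets, coincident similarity points, singular affines,
  constant images (Otsu), all-hole inpainting masks, zero-area polygons,
  empty graphs and single-cluster silhouettes raise errors naming the
  problem; zero-variance motifs are left unassigned with a warning.
* All generators and factorizations are pure functions of their seed;
  seeds are propagated explicitly through pipeline configs, so identical
  configs produce byte-identical CSV/JSON artifacts.
* Deformation-field TIFF pages store displacements mapped affinely onto
  [0, 1] (`d / (2 max(H, W)) + 0.5`) because baseline TIFF writers clamp
  float samples to the unit interval.
* Benchmark problem sizes: 256 x 256 phantoms for registration (100–200
  random misalignments), 64 x 64 phantoms with T = 200–300 frames for
  motif factorization, 30–60 motif images for clustering. These sizes give
  stable statistics while keeping the whole validation suite and the
  reproduction script in the minutes range on one CPU.

# Known limitations

* The midline seam reconciliation (side-of-line assignment plus one
  dilation pass) is a documented choice; hemisphere warps that disagree
  wildly at the seam will show a visible discontinuity rather than being
  blended.
* Piecewise-affine extrapolation outside the control-point hull extends
  the nearest triangle's affine; far outside the hull this is only a
  continuation, not an estimate.
* The convNMF penalty term implements the cross-orthogonality form; other
  regularizations (sparsity on H, events-based penalties) are not
  included.
* MAT-file support covers exactly the subset needed for ROI masks
  (uncompressed 2D uint8/int32/double arrays).
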