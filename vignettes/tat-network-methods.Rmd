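---
title: "Methods: quantifying transverse-axial tubule networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying transverse-axial tubule networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tatnet)
```

# The measurement problem

Atrial myocytes contain a sparse intracellular membrane network — the
transverse-axial tubule (TAT) system — dominated by axial tubules (ATs)
running along the cell's long axis, with oblique (~45°) and transverse
(~90°) minorities. Three families of quantities characterize it:

* **network metrics**: skeleton length per unit cell area (µm/µm²),
  branch-point (junction) density (1/µm²), and mean branch length (µm);
* **component composition**: the fraction of skeleton length oriented
  near 0°, 45° and 90° relative to the cell axis, both relative and as
  absolute densities;
* **tubule dimensions**: cross-sectional FWHM of single tubules
  (150–500 nm) and of membrane nanodomains (~90 nm), measured by Gaussian
  fitting of intensity profiles.

Alongside the imaging chain, two trace analyses quantify function: the
partition of cytosolic Ca²⁺ extrusion into SERCA and non-SERCA fluxes from
mono-exponential decay rates, and amplitude/onset/slope metrics of optical
action potentials (APs) recorded with a voltage dye.

# Image chain

## Preprocessing (`preprocess`)

The chain is background subtraction → smoothing → threshold → region
restriction. Background is estimated as a grayscale opening with a disc
(the rolling-ball construction); the default radius of 2500 nm is roughly
ten tubule widths, so tubules are far too thin to survive the opening and
are preserved intact by the subtraction. Smoothing is Gaussian with
`smooth_sigma` = 16.23 nm (one STED pixel) by default. The operator choice
is a decision of this package: generic "smoothing" could equally be a mean
filter; Gaussian is used because it is separable, parameterized in
physical units, and does not privilege the pixel grid.

The threshold default is Otsu's method computed **within the analysis
region only** (background pixels outside the cell would otherwise dominate
the histogram); a fixed, predefined threshold is available via
`threshold_mode = "fixed"` for reproducing a fixed-threshold protocol. A
fixed threshold outside the image's dynamic range, or Otsu on a constant
region, is an error, never a silent empty mask.

The analysis region is the cell ROI minus nuclei minus a border strip of
`exclude_margin` (default 1 µm, implemented as erosion of the ROI by a
disc), which removes the surface sarcolemma whose bright signal is not
TAT membrane. All parameters are physical (nm/µm) and divided by the pixel
size, so one parameter set serves both STED (16.23 nm) and confocal
(114 nm) data.

## Skeletonization (`skeletonize`)

Zhang–Suen thinning with a final cleanup pass that deletes simple pixels
(crossing number 1) still completing a fully occupied 2×2 block, so the
output is strictly one pixel thin and topology is preserved. The thinning
also records the Euclidean distance transform of the input mask, which the
graph stage may use for tip-erosion compensation.

## Branch/junction graph (`build_graph`)

Definitions are chosen to be order-independent so results cannot depend on
traversal order:

* The step graph contains every 8-adjacency between skeleton pixels,
  **except** diagonal steps whose two pixels share an occupied orthogonal
  neighbour. Such diagonals are redundant — the path already runs through
  the shared neighbour — and keeping them would make every staircase
  corner of a thinned diagonal line a spurious 3-neighbour "junction" and
  double-count its length.
* A junction pixel has ≥ 3 step-graph neighbours; 8-connected junction
  pixels merge into one junction node. Endpoints have one neighbour;
  isolated pixels are degenerate nodes.
* Non-junction pixels have degree ≤ 2, so their connected components are
  simple paths or cycles. Each component, plus its steps into adjacent
  junction clusters, is one branch; branch length is the sum of its steps
  (1 or √2 pixels). Steps internal to a junction cluster carry no length.
  Total skeleton length is the sum of branch lengths.

Two measurement corrections are available and used by the pipeline:

* **Spur pruning** removes endpoint-terminated branches shorter than a
  threshold. The package default is the conventional 2 px; the pipeline
  (`analyze_network`) uses a physical scale of 0.3 µm, since thinning
  artifacts scale with the tubule half-width, not with the pixel.
* **Tip extension** (`tip_extension = TRUE`): thinning retracts every free
  end by roughly the local mask half-width, a systematic negative bias on
  physical length. Each endpoint adds back (distance-to-background − ½)
  pixels. The default is off, so that plain `build_graph` output matches
  step-counting skeleton tools exactly (and the brute-force enumeration
  oracle in the tests); the image pipeline turns it on because it
  estimates *physical* tubule length from ribbons of finite width.
* **Junction consolidation** (`junction_merge_um`, pipeline default
  0.25 µm): a four-way crossing of wide tubules often thins into two
  nearby 3-junctions; within a tubule width these are one biological
  branch point, so junction *counting* merges nodes within that radius.
  Branch decomposition is unaffected.

## Orientation and components (`orientation_histogram`, `classify_components`)

Local orientation is estimated per skeleton pixel from the structure
tensor of the (lightly smoothed) skeleton image with a Gaussian window of
σ = 5 px; the tubule direction is the minor-eigenvector orientation. Each
pixel enters the histogram with its length contribution (half of each
incident counted step), normalized so bin masses sum to the graph's total
length; bins are 5° wide over (−90°, 90°] relative to the cell's major
axis (estimated from the second central moments of the ROI mask unless
supplied).

For classification, orientations are folded to [0°, 90°] and each bin is
assigned to the nearest canonical orientation (AT 0°, OT 45°, TT 90°)
within a window. The default window of ±22.5° is exhaustive — every bin
classified, fractions summing to 100 % — which matches reading published
component fractions that total 100 %. A strict ±5° window is available via
`window = 5` and reports the remainder as unclassified; the package
supports both readings of "binning ± 5°" rather than asserting one as
intent. The tie at exactly 22.5° goes to the lower canonical angle.

## Tubule and nanodomain sizing (`extract_profile`, `fit_gaussian`, `tubule_width`)

Profiles are sampled on a rotated 50 × 30 px frame (bilinear
interpolation): 50 px across the tubule, averaged over 30 px along it.
Fits are Levenberg–Marquardt least squares of one or two Gaussians plus a
shared baseline. Initialization is data driven: prominent local maxima
(≥ 20 % of the excursion above the floor) of a σ = 1 px smoothed copy,
ties broken leftmost; if a two-peak fit finds only one maximum — a
flat-topped profile, typical of a solid tubule wider than the PSF — the
two peaks are seeded at the edges of the 60 %-of-max plateau. Fits that do
not converge, or whose σ collapses below a quarter pixel, are flagged
failures; no width is ever returned silently from a bad fit.

Width definitions: single peak, FWHM = 2√(2 ln 2)·σ; two peaks, the
distance between the outermost half-maximum crossings of the fitted
two-peak-plus-baseline model (numeric root finding on the fitted curve),
i.e. the dashed-line wall-to-wall reading; the peak-to-peak separation is
also reported. The half-max level is taken above the fitted baseline, so
widths are invariant to affine intensity transforms. For the ~90 nm
membrane nanodomain the 1D single-peak profile fit is implemented; a full
2D Gaussian fit of the spot is a possible alternative the package does not
currently provide.

# Trace analyses

`fit_monoexp` fits A·exp(−k(t−t_start)) + C from the transient peak to the
end of the trace (start at the peak sample by default; `window_start =
"p90"` starts at 90 % of peak for noise robustness — the fit-window
convention is a package decision). The offset C is free. k is invariant to
time-origin shifts and affine intensity transforms, so F, ΔF/F₀ or
calibrated traces all give the same rate. `partition_fluxes` enforces
k_syst ≥ k_caff (the caffeine transient lacks the SERCA component, so a
faster caffeine decay violates the model and errors) and asserts
frac_SERCA + frac_nonSERCA = 1 on every output. `current_density`
normalizes the windowed extremum (pA/pF) and trapezoidal charge integral
(pC/pF) by membrane capacitance; the caffeine-window integral doubles as
the SR-content proxy.

`ap_metrics` uses the mean pre-stimulus ΔF/F as baseline; amplitude is the
post-stimulus maximum minus baseline (the unsubtracted peak is also
reported, covering the per-site fractional-fluorescence reading); onset is
the first linear-interpolated crossing of baseline + 4 % ΔF/F after the
stimulus end, NA (flagged) if never crossed; maximum slope is the largest
first difference of a Savitzky–Golay smoothed copy (window 5 samples,
order 2) between stimulus end and the peak — the window starts at the
stimulus, not at the threshold crossing, because the steepest point of the
upstroke precedes the crossing. A window below 3 samples disables
smoothing, which matters when checking the analytic slope limit
amplitude/τ on fine noiseless traces.

# The synthetic-data generator

The generator defines the study conditions. Defaults: a 60 × 12 µm cell;
component fractions 0.62/0.23/0.15 (AT-dominated atrial composition);
target density 0.368 µm/µm² (the atrial tissue regime); segment length
2.3 ± 0.8 µm (the scale of reported mean branch length); angular jitter
6°; tubule widths 250 nm (AT) and 200 nm (TT), ATs wider than TTs;
junction rate 0.023/µm². Imaging defaults follow the two published pixel
sizes (16.23 nm STED, 114 nm confocal selectable) with a Gaussian PSF
given by FWHM, Poisson shot noise, then Gaussian read noise, then
quantization.

Generator design choices worth knowing:

* **Quota component assignment**: each new segment takes the component
  whose realized length share trails its target most. Realized fractions
  then track the spec tightly even at 20–30 segments per cell; a plain
  multinomial draw leaves per-cell composition noise of several percent,
  which would dominate small-cell recovery experiments.
* **Volume exclusion**: a candidate running within one tubule width of an
  existing near-parallel (< 25°) segment is redrawn. Real tubules are
  distinct membrane structures; without this the renderer fuses parallel
  tubules into single ribbons and part of the geometric length is
  irrecoverable from any image.
* **Resolvable seeded junctions**: T-junction branches attach ≥ 0.4 µm
  from the parent's ends, leave at ≥ 40° to the parent, and are ≥ 0.6 µm
  long. A "junction" closer to an end, at a shallower angle, or with a
  shorter stub is optically indistinguishable from a corner or a bump and
  would be counted in the truth but invisible in any image.
* **Oblique sign**: OTs are drawn at +45° or −45° with equal probability;
  both fold to 45°.
* **Exact rendering**: a finite ribbon convolved with an isotropic
  Gaussian factorizes in the ribbon frame into a product of error-function
  differences, evaluated per pixel — the forward model is exact, not a
  discretized convolution. Intensity is scaled so a representative
  (median-width) tubule ridge reaches `tubule_peak_signal`; overlaps may
  exceed it, as in real data.
* **Truth bookkeeping**: the truth block stores per-component lengths,
  density, and junction count (seeded + enumerated pairwise crossings)
  over the whole cell; `segment_truth_in_mask` restates the truth within
  any pixel region. The latter matters because the analysis region
  excludes a border margin, and a hard-core placement process is slightly
  denser near the boundary (less competition), so whole-cell and in-region
  densities differ by several percent in small cells.

What the generator does **not** emulate: curved tubules, 3D geometry and
projection effects, photobleaching, motion, uneven illumination,
membrane-wall (two-line) tubule cross-sections, and spatially correlated
noise. Passing recovery tests therefore demonstrates that the estimators
are unbiased under the stated forward model, not that real micrographs are
free of these further effects.

# Verification design and problem sizes

The test suite pairs every estimator with an independent oracle: the graph
decomposition against a plain-loop exhaustive enumeration (flood fill,
per-pixel neighbour counts) on hand-built fixtures and random blob masks
up to 32 × 32 px; the renderer and the width estimator against dense-grid
(1 nm) numerical convolution; the trace analyses against closed forms.
Recovery experiments use 15 × 8 µm or 20 × 10 µm cells imaged at 32.46 nm
pixels with a 60 nm PSF — small enough that a full
generate-render-analyze cycle takes about a second, large enough to hold
30–80 µm of network — with 3–20 seeds per condition; density recovery is
evaluated at 0.2–0.6 µm/µm², spanning the atrial regime, and junction
recovery is pooled across the sweep because a single small cell holds only
a handful of junctions. Flux recovery uses 100 seeds per rate at
signal-to-noise 20; AP onset uses 50 seeds at 1 % ΔF/F noise and 0.1 ms
sampling.

# Known limitations

* Network length from a skeleton is bias-corrected at tips but not at
  crossings: where two tubules cross, the overlap region is traversed
  once, an irreducible undercount that grows with density and PSF width.
  At confocal resolution (250 nm PSF) this cost several percent of length
  in dense networks; at STED-like resolution it is negligible.
* Junction counts in a single small cell are Poisson-sparse; compare
  junction densities on pooled counts, not per cell.
* The two-peak width model assumes a solid (filled-lumen) tubule profile;
  membrane-stained tubules resolved into two walls fit naturally, but a
  wall-model renderer is not provided for synthetic validation of that
  regime.
* The orientation estimator reports the structure-tensor orientation
  density; a Fourier-spectrum estimator would weight differently near
  junctions. The choice is recorded in the histogram's `method` field.
* Otsu thresholding assumes a bimodal region histogram; very sparse or
  empty cells should use a fixed threshold.
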