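# tatnet

Quantitative analysis of the **transverse-axial tubule (TAT) system** of
cardiomyocytes from 2D fluorescence micrographs, with companion analyses
for Ca²⁺ transient flux partitioning and optical action-potential (AP)
recordings.

Atrial myocytes carry a membrane tubule network dominated by **axial
tubules (ATs)** running parallel to the cell's long axis, with **oblique
(OT, ~45°)** and **transverse (TT, ~90°)** minorities. Characterizing this
network — how much tubule length a cell contains, how branched it is, how
its components are oriented, and how wide individual tubules are — links
membrane architecture to Ca²⁺ signalling: the systolic Ca²⁺ decay rate
k_syst reflects SERCA reuptake plus sarcolemmal extrusion, the
caffeine-evoked decay rate k_caff isolates extrusion, and their difference
k_SERCA = k_syst − k_caff partitions cytosolic Ca²⁺ removal into SERCA and
non-SERCA (NCX/PMCA/mitochondrial) fractions:

    frac_SERCA = (k_syst − k_caff) / k_syst,   frac_nonSERCA = k_caff / k_syst

The package implements the full image chain

1. **preprocess** — rolling-ball background subtraction, Gaussian
   smoothing, Otsu or fixed thresholding, ROI/nucleus/surface-membrane
   exclusion (all parameters in nm/µm, converted by pixel size);
2. **skeletonize** — Zhang–Suen thinning to a one-pixel skeleton;
3. **build_graph** — branch/junction decomposition (junction pixels have
   ≥ 3 skeleton neighbours; branch length counts each 1 or √2 pixel step
   once), with spur pruning and optional tip-erosion compensation;
4. **network_metrics** — network density (µm/µm²), junction density
   (1/µm²), mean branch length (µm);
5. **orientation_histogram / classify_components** — structure-tensor
   local orientation, length-weighted into 5° bins relative to the cell
   axis, folded to [0°, 90°] and assigned to AT/OT/TT;
6. **extract_profile / fit_gaussian / tubule_width** — cross-tubule
   intensity profiles (50 × 30 px) fitted with one- or two-peak Gaussians;
   FWHM = 2√(2 ln 2)·σ for a single peak, outer half-maximum envelope
   width for two peaks;
7. **fit_monoexp / partition_fluxes / current_density** — mono-exponential
   decay fits A·exp(−k(t−t_peak)) + C, SERCA/NCX flux partition, and
   capacitance-normalized current densities (pA/pF, pC/pF);
8. **ap_metrics** — AP amplitude (ΔF/F), onset (first crossing of
   baseline + 4 % ΔF/F after the stimulus, linearly interpolated), and
   maximum upstroke slope.

A ground-truthed **synthetic-data generator** (`generate_network_geometry`,
`render_image`, `generate_transients`, `generate_ap_trace`) simulates the
whole study — sparse anisotropic tubule networks rendered through a
Gaussian PSF with Poisson + read noise, mono-exponential Ca²⁺ transients,
stimulus-locked AP upstrokes — so every stage is testable end to end
without any external data.

## Worked example

Simulate a 20 × 10 µm atrial myocyte at the atrial density regime, image
it with a 60 nm PSF at 32.46 nm pixels, and run the network analysis:

```r
library(tatnet)

spec <- network_spec(cell_length = 20, cell_width = 10)
segs <- generate_network_geometry(spec, seed = 4)
print(segs)
#> Synthetic TAT network geometry
#>   cell: 20.0 x 10.0 um (axis 0.0 deg), area 200.0 um2
#>   segments: 32 (total 71.6 um, density 0.358 um/um2)
#>   length fractions: AT 0.61 / OT 0.23 / TT 0.15
#>   expected junctions: 6 (0.030 per um2)

im  <- render_image(segs, imaging_spec(pixel_size = 32.46, psf_fwhm = 60,
                                       seed = 5))
roi <- cell_roi(cell_mask_from_image(im))
na  <- analyze_network(im$image, roi, pixel_size = 32.46)
print(na$metrics)
#> TAT network metrics
#>   density           0.3883 um/um2
#>   junction density  0.0344 /um2
#>   mean branch       1.823 um (31 branches)
#>   total length      56.52 um in 145.5 um2
print(na$components)
#> TAT component summary (window +/-22.5 deg)
#>   AT:  62.1% of classified length, 0.2413 um/um2
#>   OT:  25.1% of classified length, 0.0974 um/um2
#>   TT:  12.8% of classified length, 0.0496 um/um2
#>   unclassified: 0.0%
```

The recovered density (0.388 µm/µm²) and component fractions (62/25/13 %)
track the generator's realized geometry (0.358 µm/µm² over the whole
cell, fractions 61/23/15 %); the analysis region excludes a 1 µm border
strip, so it is compared against the truth restricted to that region
(`segment_truth_in_mask`). Ca²⁺ flux partitioning works the same way:

```r
tr <- generate_transients(transient_spec(k_syst = 2, k_caff = 0.68,
                                         noise_sd = 0.075, seed = 3))
fp <- partition_fluxes(fit_monoexp(tr$systolic), fit_monoexp(tr$caffeine))
print(fp)
#> Ca2+ extrusion flux partition
#>   k_syst  2.012 1/s
#>   k_caff  0.6991 1/s
#>   k_SERCA 1.313 1/s
#>   SERCA fraction 65.2%, non-SERCA (NCX/PMCA/mito) 34.8%
```

The whole chain — image, widths, fluxes, AP metrics — can be run as one
deterministic pipeline from a YAML config
(`run_pipeline(system.file("extdata", "demo_pipeline.yaml", package =
"tatnet"))`), or from the shell via the thin CLI at `inst/cli/tatnet.R`
(subcommands `simulate-image`, `analyze-network`, `flux-partition`,
`ap-metrics`, `run`, …).

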