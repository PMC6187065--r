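Package: tatnet
Title: Quantitative Analysis of Transverse-Axial Tubule Networks in Atrial Myocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Skeleton-based quantification of the transverse-axial tubule (TAT)
    membrane network of cardiomyocytes from 2D fluorescence micrographs:
    preprocessing and binarization, topology-preserving skeletonization,
    branch/junction graph metrics (network density, junction density, branch
    length), structure-tensor orientation histograms with axial/oblique/
    transverse component classification, and tubule/nanodomain sizing by one-
    and two-peak Gaussian profile fitting (FWHM).  Companion trace analyses
    cover mono-exponential decay fitting of systolic and caffeine-evoked
    calcium transients with SERCA/NCX flux partitioning, capacitance-normalized
    current densities, and optical action-potential metrics (amplitude, onset,
    maximum slope).  A ground-truthed synthetic-data generator (segment
    geometry, Gaussian-PSF rendering with Poisson and read noise, transient and
    action-potential traces) makes the full pipeline testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    igraph,
    jsonlite,
    minpack.lm,
    pracma,
    signal,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
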