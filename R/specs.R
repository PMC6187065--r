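#' Specification of a synthetic TAT network geometry
#'
#' Describes the cell and the statistical structure of the tubule network to
#' simulate: an elongated cell whose transverse-axial tubule (TAT) system is
#' a sparse curvilinear network dominated by axial tubules (ATs, parallel to
#' the cell's long axis), with oblique (OT, ~45 deg) and transverse (TT,
#' ~90 deg) minorities.  Defaults emulate the atrial-myocyte regime: an
#' AT-dominated composition of roughly (0.62, 0.23, 0.15), a network density
#' of ~0.37 um tubule length per um2 of cell area, mean branch length
#' ~2.3 um, and AT tubules wider than TTs (250 vs 200 nm).
#'
#' @param cell_length,cell_width cell dimensions in micrometers.
#' @param axis_angle orientation of the cell's major axis in degrees,
#'   counterclockwise from the image row direction, in (-90, 90].
#' @param frac_at,frac_ot,frac_tt target length fractions of axial, oblique
#'   and transverse components; must sum to 1.
#' @param target_density target tubule length per unit cell area (um/um2).
#' @param segment_length_mean,segment_length_sd segment length distribution
#'   (um); lengths are drawn from a truncated normal.
#' @param angle_jitter_sd angular jitter (degrees, SD) about each component's
#'   canonical orientation.
#' @param tubule_width_at,tubule_width_tt true physical tubule widths in nm
#'   (oblique tubules take the mean of the two).
#' @param junction_rate expected density of explicitly seeded T-junctions
#'   (branch points) per um2.
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(cell_length = 60, cell_width = 12, axis_angle = 0,
                         frac_at = 0.62, frac_ot = 0.23, frac_tt = 0.15,
                         target_density = 0.368,
                         segment_length_mean = 2.3, segment_length_sd = 0.8,
                         angle_jitter_sd = 6,
                         tubule_width_at = 250, tubule_width_tt = 200,
                         junction_rate = 0.023) {
  check_scalar(cell_length, "cell_length", 0, strict_lower = TRUE)
  check_scalar(cell_width, "cell_width", 0, strict_lower = TRUE)
  check_scalar(axis_angle, "axis_angle", -90, 90)
  for (nm in c("frac_at", "frac_ot", "frac_tt"))
    check_scalar(get(nm), nm, 0, 1)
  if (abs(frac_at + frac_ot + frac_tt - 1) > 1e-8)
    stopf("component fractions must sum to 1 (got %g)",
          frac_at + frac_ot + frac_tt)
  check_scalar(target_density, "target_density", 0, strict_lower = TRUE)
  check_scalar(segment_length_mean, "segment_length_mean", 0,
               strict_lower = TRUE)
  check_scalar(segment_length_sd, "segment_length_sd", 0)
  check_scalar(angle_jitter_sd, "angle_jitter_sd", 0)
  check_scalar(tubule_width_at, "tubule_width_at", 0, strict_lower = TRUE)
  check_scalar(tubule_width_tt, "tubule_width_tt", 0, strict_lower = TRUE)
  check_scalar(junction_rate, "junction_rate", 0)
  structure(list(
    cell_length = cell_length, cell_width = cell_width,
    axis_angle = axis_angle,
    frac_at = frac_at, frac_ot = frac_ot, frac_tt = frac_tt,
    target_density = target_density,
    segment_length_mean = segment_length_mean,
    segment_length_sd = segment_length_sd,
    angle_jitter_sd = angle_jitter_sd,
    tubule_width_at = tubule_width_at, tubule_width_tt = tubule_width_tt,
    junction_rate = junction_rate
  ), class = "network_spec")
}

#' Specification of the imaging forward model
#'
#' Parameters of the synthetic microscope: pixel size (16.23 nm for the STED
#' configuration, 114 nm for confocal), an isotropic Gaussian PSF given by
#' its FWHM, signal and background levels in detector counts, Poisson shot
#' noise and additive Gaussian read noise, and quantization bit depth.
#'
#' @param pixel_size pixel size in nm (> 0).
#' @param psf_fwhm full width at half maximum of the Gaussian PSF, nm (>= 0;
#'   0 disables blurring).
#' @param background_level,tubule_peak_signal background and peak tubule
#'   signal in counts.
#' @param read_noise_sd SD of additive Gaussian read noise, counts.
#' @param shot_noise logical; apply Poisson noise?
#' @param bit_depth 8 or 16.
#' @param seed integer seed used when noise is applied.
#' @return an object of class `imaging_spec`.
#' @export
imaging_spec <- function(pixel_size = 16.23, psf_fwhm = 60,
                         background_level = 20, tubule_peak_signal = 200,
                         read_noise_sd = 2, shot_noise = TRUE,
                         bit_depth = 16, seed = 1L) {
  check_scalar(pixel_size, "pixel_size", 0, strict_lower = TRUE)
  check_scalar(psf_fwhm, "psf_fwhm", 0)
  check_scalar(background_level, "background_level", 0)
  check_scalar(tubule_peak_signal, "tubule_peak_signal", 0)
  check_scalar(read_noise_sd, "read_noise_sd", 0)
  if (!is.logical(shot_noise) || length(shot_noise) != 1L)
    stopf("'shot_noise' must be TRUE or FALSE")
  if (!bit_depth %in% c(8, 16)) stopf("'bit_depth' must be 8 or 16")
  structure(list(
    pixel_size = pixel_size, psf_fwhm = psf_fwhm,
    background_level = background_level,
    tubule_peak_signal = tubule_peak_signal,
    read_noise_sd = read_noise_sd, shot_noise = shot_noise,
    bit_depth = as.integer(bit_depth), seed = as.integer(seed)
  ), class = "imaging_spec")
}

#' Specification of synthetic Ca2+ transients
#'
#' A systolic transient decays with rate `k_syst` (SERCA reuptake plus
#' sarcolemmal extrusion) and a caffeine-evoked transient with the slower
#' `k_caff` (extrusion only, SERCA rendered futile by caffeine); the
#' generator enforces `k_syst >= k_caff >= 0`.  Decays are mono-exponential,
#' `A * exp(-k t) + C`, with additive Gaussian noise.
#'
#' @param k_syst,k_caff decay rate constants, 1/s.
#' @param amplitude transient amplitude in dF/F0 units.
#' @param baseline resting fluorescence F0.
#' @param sample_rate sampling rate, Hz (must exceed `2 * k_syst`).
#' @param duration trace duration, s.
#' @param noise_sd additive Gaussian noise SD, dF/F0 units.
#' @param seed integer seed.
#' @return an object of class `transient_spec`.
#' @export
transient_spec <- function(k_syst = 2.0, k_caff = 0.68, amplitude = 1.5,
                           baseline = 1.0, sample_rate = 100, duration = 8,
                           noise_sd = 0.05, seed = 1L) {
  check_scalar(k_syst, "k_syst", 0)
  check_scalar(k_caff, "k_caff", 0)
  if (k_syst < k_caff)
    stopf("model assumption violated: k_syst (%g) must be >= k_caff (%g)",
          k_syst, k_caff)
  check_scalar(amplitude, "amplitude", 0)
  check_scalar(baseline, "baseline")
  check_scalar(sample_rate, "sample_rate", 0, strict_lower = TRUE)
  if (sample_rate <= 2 * k_syst)
    stopf("sample_rate (%g Hz) must exceed 2 * k_syst (%g)", sample_rate,
          2 * k_syst)
  check_scalar(duration, "duration", 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", 0)
  structure(list(
    k_syst = k_syst, k_caff = k_caff, amplitude = amplitude,
    baseline = baseline, sample_rate = sample_rate, duration = duration,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "transient_spec")
}

#' Specification of a synthetic optical action-potential trace
#'
#' Emulates a voltage-dye recording during field stimulation: flat baseline
#' until `stim_end_time + true_onset_delay`, then a saturating-exponential
#' upstroke `amplitude * (1 - exp(-(t - t_on)/upstroke_tau))`.
#'
#' @param stim_end_time end of the stimulus artifact, ms.
#' @param true_onset_delay delay from stimulus end to fluorescence rise, ms.
#' @param upstroke_tau upstroke time constant, ms.
#' @param amplitude plateau amplitude, dF/F.
#' @param sample_interval sampling interval, ms (0.5-1.5 ms in the
#'   random-access multiphoton regime; finer values supported).
#' @param duration trace duration, ms.
#' @param noise_sd additive Gaussian noise SD, dF/F.
#' @param seed integer seed.
#' @return an object of class `ap_trace_spec`.
#' @export
ap_trace_spec <- function(stim_end_time = 10, true_onset_delay = 2,
                          upstroke_tau = 0.5, amplitude = 0.25,
                          sample_interval = 0.5, duration = 60,
                          noise_sd = 0.005, seed = 1L) {
  check_scalar(stim_end_time, "stim_end_time", 0)
  check_scalar(true_onset_delay, "true_onset_delay", 0)
  check_scalar(upstroke_tau, "upstroke_tau", 0, strict_lower = TRUE)
  check_scalar(amplitude, "amplitude", 0)
  check_scalar(sample_interval, "sample_interval", 0, strict_lower = TRUE)
  check_scalar(duration, "duration", 0, strict_lower = TRUE)
  if (duration <= stim_end_time + true_onset_delay)
    stopf("duration must extend beyond stimulus end + onset delay")
  check_scalar(noise_sd, "noise_sd", 0)
  structure(list(
    stim_end_time = stim_end_time, true_onset_delay = true_onset_delay,
    upstroke_tau = upstroke_tau, amplitude = amplitude,
    sample_interval = sample_interval, duration = duration,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "ap_trace_spec")
}

#' Preprocessing parameters for micrograph binarization
#'
#' Physical-unit parameters of the raw-image-to-mask chain: rolling-ball
#' style background subtraction (grayscale opening with a disc), Gaussian
#' smoothing, thresholding (Otsu within the ROI by default, or a fixed
#' predefined threshold), and exclusion of a strip at the cell border so the
#' surface sarcolemma does not contaminate the interior TAT analysis.
#'
#' @param smooth_sigma Gaussian smoothing SD in nm (0 disables smoothing).
#' @param background_radius rolling-ball radius in nm; must exceed
#'   `smooth_sigma`.  Default 2500 nm, i.e. ~10x a typical tubule width.
#' @param threshold_mode `"otsu"` (computed within the ROI) or `"fixed"`.
#' @param fixed_threshold threshold in counts for `threshold_mode = "fixed"`.
#' @param exclude_margin width (um) of the border strip removed from the ROI.
#' @return an object of class `preprocess_params`.
#' @export
preprocess_params <- function(smooth_sigma = 16.23, background_radius = 2500,
                              threshold_mode = c("otsu", "fixed"),
                              fixed_threshold = NULL, exclude_margin = 1) {
  threshold_mode <- match.arg(threshold_mode)
  check_scalar(smooth_sigma, "smooth_sigma", 0)
  check_scalar(background_radius, "background_radius", 0,
               strict_lower = TRUE)
  if (background_radius <= smooth_sigma)
    stopf("background_radius (%g nm) must exceed smooth_sigma (%g nm)",
          background_radius, smooth_sigma)
  if (threshold_mode == "fixed") {
    if (is.null(fixed_threshold))
      stopf("fixed_threshold required when threshold_mode = 'fixed'")
    check_scalar(fixed_threshold, "fixed_threshold")
  }
  check_scalar(exclude_margin, "exclude_margin", 0)
  structure(list(
    smooth_sigma = smooth_sigma, background_radius = background_radius,
    threshold_mode = threshold_mode, fixed_threshold = fixed_threshold,
    exclude_margin = exclude_margin
  ), class = "preprocess_params")
}

#' Cell region of interest
#'
#' @param mask logical matrix marking cell-interior pixels.
#' @param nucleus_masks list of logical matrices (same shape) marking nuclei;
#'   every nucleus pixel must lie inside `mask`.
#' @param major_axis_angle optional known major-axis angle in degrees; when
#'   `NULL` it is estimated from the mask on demand.
#' @return an object of class `cell_roi`.
#' @export
cell_roi <- function(mask, nucleus_masks = list(), major_axis_angle = NULL) {
  if (!is.matrix(mask)) stopf("'mask' must be a matrix")
  mask <- mask > 0
  nucleus_masks <- lapply(nucleus_masks, function(n) {
    if (!all(dim(n) == dim(mask)))
      stopf("nucleus mask shape differs from the cell mask")
    n <- n > 0
    if (any(n & !mask)) stopf("nucleus masks must lie inside the cell mask")
    n
  })
  if (!is.null(major_axis_angle)) {
    check_scalar(major_axis_angle, "major_axis_angle")
    if (major_axis_angle <= -90 || major_axis_angle > 90)
      stopf("major_axis_angle must lie in (-90, 90]")
  }
  structure(list(mask = mask, nucleus_masks = nucleus_masks,
                 major_axis_angle = major_axis_angle),
            class = "cell_roi")
}
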