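#' Generate synthetic systolic and caffeine-evoked Ca2+ transients
#'
#' Both transients share the model: baseline fluorescence, a brief linear
#' upstroke to `baseline + amplitude`, then a mono-exponential decay
#' `amplitude * exp(-k (t - t_peak)) + baseline` with `k = k_syst` for the
#' systolic transient (SERCA + sarcolemmal extrusion) and `k = k_caff` for
#' the caffeine transient (extrusion only).  Additive Gaussian noise is
#' applied to both.
#'
#' @param spec a [transient_spec()].
#' @return list with `systolic` and `caffeine` (data.frames `time_s`,
#'   `value`) and a `truth` block (`k_syst`, `k_caff`, `t_peak`, `amplitude`,
#'   `baseline`, and `window_too_short` — TRUE when the trace does not cover
#'   three caffeine decay time constants past the peak).
#' @export
generate_transients <- function(spec) {
  stopifnot(inherits(spec, "transient_spec"))
  t <- seq(0, spec$duration, by = 1 / spec$sample_rate)
  t_up <- 0.5                 # upstroke start, s
  rise <- 0.05                # linear rise time, s
  t_peak <- t_up + rise
  shape <- function(k) {
    y <- rep(spec$baseline, length(t))
    ramp <- t > t_up & t < t_peak
    y[ramp] <- spec$baseline + spec$amplitude * (t[ramp] - t_up) / rise
    dec <- t >= t_peak
    y[dec] <- spec$baseline + spec$amplitude * exp(-k * (t[dec] - t_peak))
    y
  }
  out <- with_seed(spec$seed, {
    list(
      systolic = shape(spec$k_syst) +
        stats::rnorm(length(t), 0, spec$noise_sd),
      caffeine = shape(spec$k_caff) +
        stats::rnorm(length(t), 0, spec$noise_sd)
    )
  })
  window_too_short <- spec$k_caff > 0 &&
    (spec$duration - t_peak) < 3 / spec$k_caff
  list(
    systolic = data.frame(time_s = t, value = out$systolic),
    caffeine = data.frame(time_s = t, value = out$caffeine),
    truth = list(k_syst = spec$k_syst, k_caff = spec$k_caff,
                 t_peak = t_peak, amplitude = spec$amplitude,
                 baseline = spec$baseline,
                 window_too_short = window_too_short)
  )
}

#' Generate a synthetic optical action-potential trace
#'
#' Flat zero baseline until `stim_end_time + true_onset_delay`, then a
#' saturating-exponential upstroke
#' `amplitude * (1 - exp(-(t - t_on)/upstroke_tau))`; the analytic maximum
#' slope, attained at onset, is `amplitude / upstroke_tau`.
#'
#' @param spec an [ap_trace_spec()].
#' @param threshold onset threshold in dF/F used to precompute the analytic
#'   crossing time in the truth block (default 0.04, i.e. 4% dF/F).
#' @return list with `trace` (data.frame `time_ms`, `dff`), `stim_end` (ms)
#'   and `truth` (`onset_delay`, `onset_time`, `max_slope`,
#'   `threshold_cross_time` or NA, and `no_ap` flag).
#' @export
generate_ap_trace <- function(spec, threshold = 0.04) {
  stopifnot(inherits(spec, "ap_trace_spec"))
  t <- seq(0, spec$duration, by = spec$sample_interval)
  t_on <- spec$stim_end_time + spec$true_onset_delay
  y <- ifelse(t <= t_on, 0,
              spec$amplitude * (1 - exp(-(t - t_on) / spec$upstroke_tau)))
  y <- with_seed(spec$seed, y + stats::rnorm(length(t), 0, spec$noise_sd))
  no_ap <- spec$amplitude <= threshold
  t_cross <- if (no_ap) NA_real_ else
    t_on - spec$upstroke_tau * log(1 - threshold / spec$amplitude)
  list(
    trace = data.frame(time_ms = t, dff = y),
    stim_end = spec$stim_end_time,
    truth = list(onset_delay = spec$true_onset_delay, onset_time = t_on,
                 max_slope = spec$amplitude / spec$upstroke_tau,
                 threshold_cross_time = t_cross, no_ap = no_ap)
  )
}
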