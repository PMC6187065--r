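#' Construct a time-series trace
#'
#' @param time time base, s (strictly increasing).
#' @param value fluorescence (F or dF/F0) or current (pA).
#' @param kind one of `"systolic"`, `"caffeine"`, `"current"`.
#' @param capacitance membrane capacitance in pF (required for currents).
#' @return an object of class `tat_trace`.
#' @export
tat_trace <- function(time, value, kind = c("systolic", "caffeine",
                                            "current"),
                      capacitance = NULL) {
  kind <- match.arg(kind)
  if (length(time) != length(value) || length(time) < 10L)
    stopf("trace needs >= 10 aligned samples")
  if (any(diff(time) <= 0)) stopf("time must be strictly increasing")
  if (kind == "current") {
    if (is.null(capacitance)) stopf("current traces require a capacitance")
    check_scalar(capacitance, "capacitance", 0, strict_lower = TRUE)
  }
  structure(list(time = time, value = value, kind = kind,
                 capacitance = capacitance), class = "tat_trace")
}

#' Fit a mono-exponential decay to a transient
#'
#' Least-squares fit of `A exp(-k (t - t_peak)) + C` to the decay phase,
#' from the transient peak (or the first sample below 90% of peak, with
#' `window_start = "p90"`) to the end of the trace.  The rate constant `k`
#' is invariant to time-origin shifts and to affine transforms of the
#' intensity scale, so traces may be F, dF/F0 or calibrated Ca2+.
#'
#' @param trace a `tat_trace` (or data.frame with `time_s`/`time` and
#'   `value`), fluorescence kind.
#' @param window_start `"peak"` (default) or `"p90"`.
#' @return an object of class `monoexp_fit`: `ok`, `k` (1/s), `A`, `C`,
#'   `fit_window` (s), `residual_rms`.
#' @export
fit_monoexp <- function(trace, window_start = c("peak", "p90")) {
  window_start <- match.arg(window_start)
  tv <- as_trace_df(trace)
  t <- tv$time; y <- tv$value
  failed <- function(msg) structure(
    list(ok = FALSE, message = msg, k = NA_real_, A = NA_real_,
         C = NA_real_, fit_window = c(NA_real_, NA_real_),
         residual_rms = NA_real_), class = "monoexp_fit")
  ip <- which.max(y)
  if (ip > length(y) - 10L)
    return(failed("no decay phase: peak too close to the end of the trace"))
  if (diff(range(y)) <= 0) return(failed("constant trace: nothing to fit"))
  i0 <- ip
  if (window_start == "p90") {
    tail_min <- min(y[ip:length(y)])
    lvl <- tail_min + 0.9 * (y[ip] - tail_min)
    below <- which(y[ip:length(y)] <= lvl)
    if (length(below)) i0 <- ip + below[1] - 1L
  }
  td <- t[i0:length(t)] - t[i0]
  yd <- y[i0:length(y)]
  C0 <- min(yd); A0 <- max(yd[1] - C0, 1e-9)
  k0 <- 1 / max(td[length(td)] / 3, 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(yd ~ C + A * exp(-k * td),
                      start = list(C = C0, A = A0, k = k0),
                      lower = c(-Inf, 0, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed("nonlinear fit did not converge"))
  cf <- stats::coef(fit)
  if (cf[["k"]] <= 0) return(failed("non-decaying trace: fitted k <= 0"))
  structure(list(
    ok = TRUE, message = "converged",
    k = unname(cf[["k"]]), A = unname(cf[["A"]]), C = unname(cf[["C"]]),
    fit_window = c(t[i0], t[length(t)]),
    residual_rms = sqrt(mean(stats::resid(fit)^2))
  ), class = "monoexp_fit")
}

as_trace_df <- function(trace) {
  if (inherits(trace, "tat_trace"))
    return(list(time = trace$time, value = trace$value))
  if (is.data.frame(trace)) {
    tcol <- intersect(c("time_s", "time"), names(trace))[1]
    if (is.na(tcol) || !"value" %in% names(trace))
      stopf("trace data.frame needs a time column and 'value'")
    return(list(time = trace[[tcol]], value = trace$value))
  }
  stopf("unsupported trace object")
}

#' @export
print.monoexp_fit <- function(x, ...) {
  if (!isTRUE(x$ok)) {
    cat(sprintf("Mono-exponential fit FAILED: %s\n", x$message))
  } else {
    cat(sprintf(
      "Mono-exponential decay: k = %.4g 1/s (A = %.3g, C = %.3g, RMS %.3g)\n",
      x$k, x$A, x$C, x$residual_rms))
  }
  invisible(x)
}

#' Partition Ca2+ extrusion into SERCA and non-SERCA fluxes
#'
#' The systolic decay rate reflects SERCA reuptake plus sarcolemmal
#' extrusion (predominantly NCX); the caffeine-evoked decay, with the SR
#' rendered leaky, reflects extrusion alone.  Hence
#' `k_serca = k_syst - k_caff`, the SERCA fraction is `k_serca / k_syst`,
#' and the non-SERCA fraction (NCX, PMCA, mitochondria) is its complement.
#'
#' @param fit_syst,fit_caff converged `monoexp_fit` objects (or bare rate
#'   constants in 1/s).
#' @return an object of class `flux_partition`: `k_syst`, `k_caff`,
#'   `k_serca` (1/s), `frac_serca`, `frac_non_serca`.
#' @export
partition_fluxes <- function(fit_syst, fit_caff) {
  k_s <- if (inherits(fit_syst, "monoexp_fit")) fit_syst$k else fit_syst
  k_c <- if (inherits(fit_caff, "monoexp_fit")) fit_caff$k else fit_caff
  check_scalar(k_s, "k_syst", 0)
  check_scalar(k_c, "k_caff", 0, strict_lower = TRUE)
  if (k_s < k_c)
    stopf(paste("model assumption violated: k_syst (%.4g) < k_caff (%.4g);",
                "the caffeine decay cannot be faster than the systolic one"),
          k_s, k_c)
  out <- structure(list(
    k_syst = k_s, k_caff = k_c, k_serca = k_s - k_c,
    frac_serca = (k_s - k_c) / k_s,
    frac_non_serca = k_c / k_s
  ), class = "flux_partition")
  stopifnot(abs(out$frac_serca + out$frac_non_serca - 1) < 1e-12,
            out$k_serca >= 0)
  out
}

#' @export
print.flux_partition <- function(x, ...) {
  cat("Ca2+ extrusion flux partition\n")
  cat(sprintf("  k_syst  %.4g 1/s\n  k_caff  %.4g 1/s\n  k_SERCA %.4g 1/s\n",
              x$k_syst, x$k_caff, x$k_serca))
  cat(sprintf("  SERCA fraction %.1f%%, non-SERCA (NCX/PMCA/mito) %.1f%%\n",
              100 * x$frac_serca, 100 * x$frac_non_serca))
  invisible(x)
}

#' Capacitance-normalized current density
#'
#' Peak current and trapezoidal charge integral within a window, both
#' normalized to the membrane capacitance (a proxy of cell surface area).
#' For a caffeine-evoked inward NCX current, the integral serves as the
#' SR-content proxy.
#'
#' @param trace a `tat_trace` of kind `"current"` (pA) with capacitance
#'   (pF).
#' @param window `c(t_start, t_end)` in s; must lie within the trace.
#' @param caffeine logical: report the integral also as `sr_content_proxy`.
#' @return an object of class `current_density`: `peak_density` (pA/pF),
#'   `integral_density` (pC/pF), `sr_content_proxy` (pC/pF or NA),
#'   `window`.
#' @export
current_density <- function(trace, window = range(trace$time),
                            caffeine = FALSE) {
  stopifnot(inherits(trace, "tat_trace"))
  if (trace$kind != "current" || is.null(trace$capacitance))
    stopf("current_density needs a current trace with capacitance")
  if (window[1] < min(trace$time) || window[2] > max(trace$time) ||
      window[1] >= window[2])
    stopf("integration window outside the trace")
  sel <- trace$time >= window[1] & trace$time <= window[2]
  tt <- trace$time[sel]; y <- trace$value[sel]
  peak <- y[which.max(abs(y))]
  q <- pracma::trapz(tt, y)  # pA * s = pC
  structure(list(
    peak_density = peak / trace$capacitance,
    integral_density = q / trace$capacitance,
    sr_content_proxy = if (caffeine) q / trace$capacitance else NA_real_,
    window = window, capacitance = trace$capacitance
  ), class = "current_density")
}

#' @export
print.current_density <- function(x, ...) {
  cat(sprintf(
    "Current density: peak %.3g pA/pF, integral %.3g pC/pF (Cm %.4g pF)\n",
    x$peak_density, x$integral_density, x$capacitance))
  if (is.finite(x$sr_content_proxy))
    cat(sprintf("  SR content proxy %.3g pC/pF\n", x$sr_content_proxy))
  invisible(x)
}
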