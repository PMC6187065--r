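## Pipeline configuration and the end-to-end runner.

## allowed configuration schema: names are validated recursively and any
## unknown key raises an error naming it
config_schema <- function() list(
  seed = NA,
  out_dir = NA,
  simulate = list(
    network = as.list(formals(network_spec)),
    imaging = as.list(formals(imaging_spec)),
    transients = as.list(formals(transient_spec)),
    ap = as.list(formals(ap_trace_spec))
  ),
  inputs = list(
    image = NA, roi_mask = NA, pixel_size = NA,
    systolic_trace = NA, caffeine_trace = NA,
    ap_trace = NA, ap_stim_end = NA
  ),
  params = list(
    preprocess = as.list(formals(preprocess_params)),
    graph = list(prune_spurs_px = NA),
    orientation = list(bin_width = NA, tensor_sigma = NA, window = NA),
    width = list(n_peaks = NA, length_px = NA, width_px = NA),
    ap = list(threshold = NA, smooth_window = NA)
  )
)

validate_config_keys <- function(cfg, schema, path = "") {
  if (!is.list(cfg)) return(invisible(TRUE))
  bad <- setdiff(names(cfg), names(schema))
  if (length(bad))
    stopf("unknown configuration key: '%s%s'", path, bad[1])
  for (nm in names(cfg)) {
    if (is.list(schema[[nm]]) && !is.null(names(schema[[nm]])))
      validate_config_keys(cfg[[nm]], schema[[nm]],
                           paste0(path, nm, "."))
  }
  invisible(TRUE)
}

#' Load and validate a pipeline configuration
#'
#' @param config a named list, or the path of a YAML file.
#' @return the validated configuration list (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("configuration must be a list or YAML path")
  validate_config_keys(config, config_schema())
  if (is.null(config$seed)) config$seed <- 1L
  structure(config, class = "pipeline_config")
}

merged_args <- function(fun, overrides) {
  overrides <- as.list(overrides)
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  do.call(fun, overrides)
}

#' Run the full TAT analysis pipeline
#'
#' Binds all stages: input acquisition (bundled synthetic generation, or
#' image/trace files named in the config), preprocessing and binarization,
#' skeletonization, graph metrics, orientation-resolved component
#' classification, tubule width measurement, Ca2+ flux partitioning, and
#' optical AP metrics.  Emits a single report (returned; also written as
#' JSON plus CSV tables into `out_dir` when set, together with the resolved
#' configuration).  No timestamps enter the report, so identical config and
#' seed give byte-identical outputs.
#'
#' @param config a [pipeline_config()] (or list / YAML path accepted by it).
#' @return an object of class `tat_report` (a nested list of results).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  seed <- as.integer(config$seed)
  p <- config$params
  report <- list(
    package = "tatnet",
    version = as.character(utils::packageVersion("tatnet")),
    seed = seed,
    stages = list()
  )

  ## ---- acquire image + ROI ----
  img <- NULL; roi <- NULL; pixel_size <- NULL; segs <- NULL
  if (!is.null(config$simulate$network)) {
    nspec <- merged_args(network_spec, config$simulate$network)
    ispec_over <- config$simulate$imaging
    if (is.null(ispec_over$seed)) ispec_over$seed <- seed + 1L
    ispec <- merged_args(imaging_spec, ispec_over)
    segs <- generate_network_geometry(nspec, seed = seed)
    rendered <- render_image(segs, ispec)
    img <- rendered$image
    pixel_size <- rendered$pixel_size
    roi <- cell_roi(cell_mask_from_image(rendered))
    report$stages$simulate <- list(
      truth = segs$truth[c("total_length", "density", "junction_density",
                           "junction_count", "n_segments")],
      truth_fractions = as.list(segs$truth$length_fractions),
      pixel_size = pixel_size)
  } else if (!is.null(config$inputs$image)) {
    if (!file.exists(config$inputs$image))
      stopf("input image not found: %s", config$inputs$image)
    img <- read_image_tiff(config$inputs$image)
    pixel_size <- config$inputs$pixel_size
    if (is.null(pixel_size))
      stopf("inputs.pixel_size (nm) is required with an input image")
    if (!is.null(config$inputs$roi_mask)) {
      if (!file.exists(config$inputs$roi_mask))
        stopf("ROI mask not found: %s", config$inputs$roi_mask)
      roi <- cell_roi(read_image_tiff(config$inputs$roi_mask) > 0)
    } else {
      roi <- cell_roi(matrix(TRUE, nrow(img), ncol(img)))
    }
  }

  ## ---- network analysis ----
  if (!is.null(img)) {
    pp <- merged_args(preprocess_params, p$preprocess)
    na <- analyze_network(
      img, roi, pixel_size, params = pp,
      spur_um = if (!is.null(p$graph$prune_spurs_px))
        p$graph$prune_spurs_px * pixel_size / 1000 else 0.3,
      bin_width = p$orientation$bin_width %||% 5,
      tensor_sigma = p$orientation$tensor_sigma %||% 5,
      window = p$orientation$window %||% 22.5)
    report$stages$network <- list(
      threshold = attr(na$mask, "threshold"),
      major_axis_deg = na$major_axis_deg,
      roi_area_um2 = na$roi_area_um2,
      metrics = unclass(na$metrics),
      components = na$components$components,
      unclassified_fraction = na$components$unclassified_fraction,
      orientation_histogram = na$histogram$bins)
  }

  ## ---- tubule widths (on simulated tubules: one AT, one TT profile) ----
  if (!is.null(segs)) {
    widths <- list()
    origin <- rendered$origin
    for (comp in c("AT", "TT")) {
      s <- segs$segments[segs$segments$component == comp &
                         segs$segments$length_um > 1, ]
      if (!nrow(s)) next
      s <- s[which.max(s$length_um), ]
      mid <- c((s$y0 + s$y1) / 2, (s$x0 + s$x1) / 2)  # (y, x) um
      ctr <- (mid - rev(origin)) / (pixel_size / 1000) + 0.5
      ang <- atan2(s$y1 - s$y0, s$x1 - s$x0) * 180 / pi
      prof <- tryCatch(
        extract_profile(img, ctr, ang,
                        length_px = p$width$length_px %||% 50,
                        width_px = p$width$width_px %||% 30,
                        pixel_size = pixel_size),
        error = function(e) NULL)
      if (is.null(prof)) next
      fit <- fit_gaussian(prof, n_peaks = p$width$n_peaks %||% 1)
      widths[[comp]] <- list(
        ok = fit$ok,
        width_nm = if (fit$ok) tubule_width(fit) else NA_real_,
        true_width_nm = s$width_nm)
    }
    report$stages$widths <- widths
  }

  ## ---- Ca2+ flux partition ----
  tr <- NULL
  if (!is.null(config$simulate$transients)) {
    tspec_over <- config$simulate$transients
    if (is.null(tspec_over$seed)) tspec_over$seed <- seed + 2L
    tspec <- merged_args(transient_spec, tspec_over)
    tr <- generate_transients(tspec)
  } else if (!is.null(config$inputs$systolic_trace)) {
    for (f in c(config$inputs$systolic_trace, config$inputs$caffeine_trace))
      if (is.null(f) || !file.exists(f))
        stopf("transient trace file missing: %s", f %||% "(unset)")
    tr <- list(systolic = read_trace_csv(config$inputs$systolic_trace),
               caffeine = read_trace_csv(config$inputs$caffeine_trace))
  }
  if (!is.null(tr)) {
    fs <- fit_monoexp(tr$systolic)
    fc <- fit_monoexp(tr$caffeine)
    flux <- if (fs$ok && fc$ok && fs$k >= fc$k)
      unclass(partition_fluxes(fs, fc)) else
        list(failed = TRUE, k_syst = fs$k, k_caff = fc$k)
    report$stages$flux <- c(flux, list(
      fit_ok = fs$ok && fc$ok,
      truth = if (!is.null(tr$truth))
        tr$truth[c("k_syst", "k_caff")] else NULL))
  }

  ## ---- AP metrics ----
  ap <- NULL
  if (!is.null(config$simulate$ap)) {
    aspec_over <- config$simulate$ap
    if (is.null(aspec_over$seed)) aspec_over$seed <- seed + 3L
    aspec <- merged_args(ap_trace_spec, aspec_over)
    gen <- generate_ap_trace(aspec)
    ap <- list(trace = gen$trace, stim_end = gen$stim_end,
               truth = gen$truth)
  } else if (!is.null(config$inputs$ap_trace)) {
    if (!file.exists(config$inputs$ap_trace))
      stopf("AP trace not found: %s", config$inputs$ap_trace)
    ap <- list(trace = read_trace_csv(config$inputs$ap_trace),
               stim_end = config$inputs$ap_stim_end %||%
                 stopf("inputs.ap_stim_end required with an AP trace"))
  }
  if (!is.null(ap)) {
    m <- ap_metrics(ap$trace$time_ms, ap$trace$dff, ap$stim_end,
                    threshold = p$ap$threshold %||% 0.04,
                    smooth_window = p$ap$smooth_window %||% 5)
    report$stages$ap <- c(unclass(m)["site_label" != names(unclass(m))],
                          list(truth = ap$truth["onset_delay"]))
  }

  ## echo the analysis configuration (not the output location, so reports
  ## from different directories stay byte-identical)
  cfg_echo <- unclass(config)
  cfg_echo$out_dir <- NULL
  report$config <- cfg_echo
  class(report) <- "tat_report"

  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_truth_json(strip_class(report),
                     file.path(out_dir, "report.json"))
    yaml::write_yaml(unclass(config),
                     file.path(out_dir, "config_resolved.yaml"))
    if (!is.null(report$stages$network)) {
      utils::write.csv(report$stages$network$orientation_histogram,
                       file.path(out_dir, "orientation_histogram.csv"),
                       row.names = FALSE)
      utils::write.csv(
        as.data.frame(report$stages$network$metrics[
          c("density", "junction_density", "mean_branch_length",
            "n_branches", "n_junctions", "total_length", "roi_area")]),
        file.path(out_dir, "network_metrics.csv"), row.names = FALSE)
    }
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## drop classes recursively so jsonlite serializes plainly
strip_class <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_class)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' @export
print.tat_report <- function(x, ...) {
  cat(sprintf("tatnet pipeline report (seed %d)\n", x$seed))
  st <- x$stages
  if (!is.null(st$network)) {
    m <- st$network$metrics
    cat(sprintf(
      "  network: density %.3f um/um2, %.4f junctions/um2, branch %.2f um\n",
      m$density, m$junction_density, m$mean_branch_length))
    cmp <- st$network$components
    cat(sprintf("  components: AT %.0f%% / OT %.0f%% / TT %.0f%%\n",
                100 * cmp$relative_fraction[1],
                100 * cmp$relative_fraction[2],
                100 * cmp$relative_fraction[3]))
  }
  if (!is.null(st$widths) && length(st$widths))
    for (nm in names(st$widths))
      cat(sprintf("  width[%s]: %.0f nm (true %.0f nm)\n", nm,
                  st$widths[[nm]]$width_nm, st$widths[[nm]]$true_width_nm))
  if (!is.null(st$flux) && is.null(st$flux$failed))
    cat(sprintf("  flux: k_syst %.3g, k_caff %.3g, SERCA fraction %.0f%%\n",
                st$flux$k_syst, st$flux$k_caff, 100 * st$flux$frac_serca))
  if (!is.null(st$ap))
    cat(sprintf("  AP: amplitude %.3g dF/F, onset %.3g ms, slope %.3g /ms\n",
                st$ap$amplitude, st$ap$onset, st$ap$max_slope))
  invisible(x)
}
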