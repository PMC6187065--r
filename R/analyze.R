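#' One-call TAT network analysis of a micrograph
#'
#' Convenience wrapper binding the network stages: [preprocess()] ->
#' [skeletonize()] -> [build_graph()] -> [network_metrics()] ->
#' [orientation_histogram()] -> [classify_components()].  Analysis defaults
#' are physical: spur branches shorter than `spur_um` (the scale of
#' thinning artifacts, about one tubule width) are pruned, tip erosion is
#' compensated, and junction nodes within `junction_merge_um` are counted
#' as one branch point.
#'
#' @param image numeric matrix of counts.
#' @param roi a [cell_roi()]; its major axis is estimated from the mask
#'   unless `roi$major_axis_angle` is set.
#' @param pixel_size pixel size in nm.
#' @param params a [preprocess_params()].
#' @param spur_um spur-pruning scale in um (default 0.3).
#' @param junction_merge_um junction consolidation radius in um.
#' @param bin_width,tensor_sigma,window orientation analysis settings, see
#'   [orientation_histogram()] and [classify_components()].
#' @return list with `mask`, `graph`, `metrics` (a `network_metrics`),
#'   `histogram` (a `tat_orientation`), `components`
#'   (a `component_summary`), `major_axis_deg`, `roi_area_um2`,
#'   `analysis_mask`.
#' @export
analyze_network <- function(image, roi, pixel_size,
                            params = preprocess_params(),
                            spur_um = 0.3, junction_merge_um = 0.25,
                            bin_width = 5, tensor_sigma = 5,
                            window = 22.5) {
  mask <- preprocess(image, roi, params, pixel_size = pixel_size)
  axis_deg <- if (!is.null(roi$major_axis_angle)) roi$major_axis_angle
              else estimate_major_axis(roi$mask)
  am <- attr(mask, "analysis_mask")
  area <- sum(am) * (pixel_size / 1000)^2
  skel <- skeletonize(mask, pixel_size = pixel_size)
  graph <- build_graph(skel,
                       prune_spurs_px = spur_um * 1000 / pixel_size,
                       tip_extension = TRUE,
                       junction_merge_um = junction_merge_um)
  metrics <- network_metrics(graph, area)
  hist <- orientation_histogram(graph, reference_angle = axis_deg,
                                bin_width = bin_width,
                                tensor_sigma = tensor_sigma)
  comps <- classify_components(hist, area, window = window)
  list(mask = mask, graph = graph, metrics = metrics, histogram = hist,
       components = comps, major_axis_deg = axis_deg,
       roi_area_um2 = area, analysis_mask = am)
}
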