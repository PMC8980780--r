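#' Measurement configuration
#'
#' Collects every tunable threshold of the measurement pipeline in one place,
#' so nothing is hard-coded and a run is fully described by its configuration.
#' All lengths are in pixels; the package deliberately reports calibers in
#' pixel units (magnification of an arbitrary fundus camera is unknown, so a
#' micron conversion would be spurious precision).
#'
#' @param min_segment_len Minimum centerline point count for a vessel segment;
#'   shorter segments are excluded from analysis. Default 10.
#' @param target_side Side length of the square analysis frame the masks are
#'   resized to after field-of-view cropping. Default 512.
#' @param zone_inner_dd,zone_outer_dd Inner/outer limit of the standard
#'   measurement zone, in disc diameters outward from the disc margin.
#'   Defaults 0.5 and 1.0 (radii `2r` to `3r` from the disc center for disc
#'   radius `r`).
#' @param n_equiv_vessels Number of largest vessels per class combined into
#'   the central retinal equivalents. Default 6.
#' @param knudtson_c_artery,knudtson_c_vein Pairwise combination constants of
#'   the revised Knudtson-Parr-Hubbard formula. Defaults 0.88 and 0.95.
#' @param qc_min_zone_vessels Minimum count of distinct arteries and of veins
#'   in the standard zone for an image to pass quality control. Default 6.
#' @param qc_min_fundus_vessels Minimum count of distinct arteries and of
#'   veins anywhere in the fundus for an image to pass quality control.
#'   Default 2.
#' @param junction_exclude_px Centerline points within this many path steps of
#'   a junction cluster are excluded from diameter profiles (thinning emits
#'   junction blobs that inflate the distance transform). Default 2.
#' @param tangent_window Number of centerline points used to estimate a
#'   segment's tangent direction at a node (principal direction of the points
#'   just past the junction-exclusion zone). Default 15: shorter windows
#'   carry several degrees of digital-line quantization error.
#' @param node_caliber_window Number of valid profile points nearest a node
#'   averaged into the local calibers d0, d1, d2 at a bifurcation. Default
#'   12 (roughly one to two vessel diameters): short windows leave the
#'   Murray-law residual dominated by per-point caliber noise.
#' @param ba_edge_reach Length of vessel wall (pixels from the node) used for
#'   the edge-based branching angle. Default 10.
#' @param root_radius_factor Segments with an endpoint within
#'   `root_radius_factor * disc_radius` of the disc center seed the vessel
#'   ordering. Default 1.1.
#'
#' @return A list of class `vessel_config`.
#' @export
#' @examples
#' cfg <- vessel_config(min_segment_len = 5)
#' cfg$min_segment_len
vessel_config <- function(min_segment_len = 10L,
                          target_side = 512L,
                          zone_inner_dd = 0.5,
                          zone_outer_dd = 1.0,
                          n_equiv_vessels = 6L,
                          knudtson_c_artery = 0.88,
                          knudtson_c_vein = 0.95,
                          qc_min_zone_vessels = 6L,
                          qc_min_fundus_vessels = 2L,
                          junction_exclude_px = 2L,
                          tangent_window = 15L,
                          node_caliber_window = 12L,
                          ba_edge_reach = 10,
                          root_radius_factor = 1.1) {
  stopifnot(min_segment_len >= 1, target_side >= 32,
            zone_outer_dd > zone_inner_dd, zone_inner_dd >= 0,
            n_equiv_vessels >= 1, knudtson_c_artery > 0, knudtson_c_vein > 0,
            junction_exclude_px >= 0, tangent_window >= 3)
  structure(list(
    min_segment_len = as.integer(min_segment_len),
    target_side = as.integer(target_side),
    zone_inner_dd = zone_inner_dd,
    zone_outer_dd = zone_outer_dd,
    n_equiv_vessels = as.integer(n_equiv_vessels),
    knudtson_c_artery = knudtson_c_artery,
    knudtson_c_vein = knudtson_c_vein,
    qc_min_zone_vessels = as.integer(qc_min_zone_vessels),
    qc_min_fundus_vessels = as.integer(qc_min_fundus_vessels),
    junction_exclude_px = as.integer(junction_exclude_px),
    tangent_window = as.integer(tangent_window),
    node_caliber_window = as.integer(node_caliber_window),
    ba_edge_reach = ba_edge_reach,
    root_radius_factor = root_radius_factor
  ), class = "vessel_config")
}

#' @export
print.vessel_config <- function(x, ...) {
  cat("<vessel_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
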