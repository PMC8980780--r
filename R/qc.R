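#' Second-pass quality control of a measured image
#'
#' An image is excluded when any of the following holds: no detectable optic
#' disc; fewer than 6 distinct arteries or fewer than 6 distinct veins in
#' the standard zone; fewer than 2 arteries or 2 veins in the whole fundus.
#' Counts are of distinct vessels (crossing continuations merged). All
#' triggered reasons are listed; excluded images keep whatever measurements
#' were computable.
#'
#' @param disc A `disc_geometry`.
#' @param zone_counts Named vector/list with `artery` and `vein` counts in
#'   the standard zone.
#' @param fundus_counts Named vector/list with whole-fundus `artery` and
#'   `vein` counts.
#' @param quality_grade Optional photographic grade passed through.
#' @param config A [vessel_config] (thresholds).
#' @return List of class `qc_report`: `status` ("pass"/"excluded"),
#'   `reasons`, `counts`, `quality_grade`.
#' @export
#' @examples
#' d <- structure(list(present = FALSE), class = "disc_geometry")
#' apply_qc(d, c(artery = 6, vein = 6), c(artery = 3, vein = 3))$reasons
apply_qc <- function(disc, zone_counts, fundus_counts,
                     quality_grade = "unknown", config = vessel_config()) {
  za <- as.integer(zone_counts[["artery"]]); zv <- as.integer(zone_counts[["vein"]])
  fa <- as.integer(fundus_counts[["artery"]]); fv <- as.integer(fundus_counts[["vein"]])
  reasons <- character(0)
  if (!isTRUE(disc$present)) reasons <- c(reasons, "no_disc")
  if (za < config$qc_min_zone_vessels || zv < config$qc_min_zone_vessels) {
    reasons <- c(reasons, "insufficient_zone_vessels")
  }
  if (fa < config$qc_min_fundus_vessels || fv < config$qc_min_fundus_vessels) {
    reasons <- c(reasons, "insufficient_fundus_vessels")
  }
  structure(list(
    status = if (length(reasons)) "excluded" else "pass",
    reasons = reasons,
    counts = c(n_arteries_zone = za, n_veins_zone = zv,
               n_arteries_fundus = fa, n_veins_fundus = fv),
    quality_grade = quality_grade
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s%s\n", x$status,
              if (length(x$reasons)) paste0(" [", paste(x$reasons, collapse = ", "), "]")
              else ""))
  print(x$counts)
  invisible(x)
}

#' Partition measurement records by quality-control status
#'
#' Splits records into passed and excluded sets. Excluded records keep all
#' computable measurements; their summary rows carry the exclusion reasons,
#' ready to be written to a separate file.
#'
#' @param records List of `fundus_record` objects from [measure_fundus()].
#' @return List with `passed` and `excluded` summary tibbles (see
#'   [glance.fundus_record()]) and the corresponding record lists
#'   `passed_records`, `excluded_records`.
#' @export
partition_results <- function(records) {
  if (inherits(records, "fundus_record")) records <- list(records)
  gl <- dplyr::bind_rows(lapply(records, glance))
  ok <- gl$qc_status == "pass"
  list(passed = gl[ok, , drop = FALSE],
       excluded = gl[!ok, , drop = FALSE],
       passed_records = records[ok],
       excluded_records = records[!ok])
}
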