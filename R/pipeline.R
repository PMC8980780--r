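#' Measure one fundus image from its segmentation maps
#'
#' Runs the full measurement chain on one [seg_maps] object: vessel graph
#' extraction, per-segment and per-bifurcation measurements, disc geometry,
#' standard-zone CRAE/CRVE/AVRe, whole-fundus summaries, fractal dimension
#' and the quality-control gate. Per-stage wall times are recorded.
#'
#' @param maps A [seg_maps] object (already in the analysis frame; use
#'   [preprocess_maps()] first for raw-sized masks).
#' @param config A [vessel_config].
#' @return Object of class `fundus_record`; see [tidy.fundus_record()] and
#'   [glance.fundus_record()].
#' @export
#' @examples
#' g <- generate_tree(synth_tree_spec(image_side = 256, disc_radius = 22,
#'                                    root_width = 7, n_levels = 3, seed = 2))
#' rec <- measure_fundus(g$maps)
#' glance(rec)$crae
measure_fundus <- function(maps, config = vessel_config()) {
  stopifnot(inherits(maps, "seg_maps"))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  graph <- build_vessel_graph(maps, config)
  timings["graph"] <- tic() - t0

  t0 <- tic()
  segments <- measure_segments(graph, maps)
  timings["segments"] <- tic() - t0

  t0 <- tic()
  bifs <- measure_bifurcations(graph, maps, segments)
  timings["bifurcations"] <- tic() - t0

  t0 <- tic()
  disc <- graph$disc
  zone_res <- list(crae = NA_real_, crve = NA_real_, avre = NA_real_,
                   artery_widths = numeric(0), vein_widths = numeric(0),
                   n_arteries_zone = 0L, n_veins_zone = 0L)
  if (isTRUE(disc$present)) {
    zone <- standard_zone(disc, dim(maps$artery),
                          config$zone_inner_dd, config$zone_outer_dd)
    za <- zone_vessel_widths(graph, segments, zone, "artery",
                             config$n_equiv_vessels)
    zv <- zone_vessel_widths(graph, segments, zone, "vein",
                             config$n_equiv_vessels)
    crae <- if (length(za$widths)) {
      knudtson_equivalent(za$widths, const = config$knudtson_c_artery)
    } else NA_real_
    crve <- if (length(zv$widths)) {
      knudtson_equivalent(zv$widths, const = config$knudtson_c_vein)
    } else NA_real_
    ratio <- if (!is.na(crae) && !is.na(crve) && crve > 0) crae / crve else NA_real_
    zone_res <- list(crae = crae, crve = crve, avre = ratio,
                     artery_widths = za$widths, vein_widths = zv$widths,
                     n_arteries_zone = za$count, n_veins_zone = zv$count)
  }
  timings["zone"] <- tic() - t0

  t0 <- tic()
  glob <- global_summary(segments)
  fd <- fractal_dimension(graph$skeleton)
  # whole-fundus distinct-vessel counts (continuations merged)
  n_fund <- function(cl) {
    m <- segments[segments$vessel_class == cl, ]
    length(unique(m$path_id[!is.na(m$path_id)])) + sum(is.na(m$path_id))
  }
  qc <- apply_qc(disc,
                 c(artery = zone_res$n_arteries_zone, vein = zone_res$n_veins_zone),
                 c(artery = n_fund("artery"), vein = n_fund("vein")),
                 quality_grade = maps$quality_grade, config = config)
  timings["summary_qc"] <- tic() - t0

  structure(list(source_id = maps$source_id,
                 quality_grade = maps$quality_grade,
                 disc = disc, zone = zone_res, segments = segments,
                 bifurcations = bifs, global = glob,
                 fractal_dimension = fd, qc = qc, graph = graph,
                 timings = timings, config = config),
            class = "fundus_record")
}

#' @export
print.fundus_record <- function(x, ...) {
  cat(sprintf("<fundus_record> %s  QC: %s\n", x$source_id, x$qc$status))
  cat(sprintf("  CRAE %.2f px | CRVE %.2f px | AVRe %.3f\n",
              x$zone$crae, x$zone$crve, x$zone$avre))
  cat(sprintf("  %d segments, %d bifurcations, fractal dim %.3f\n",
              nrow(x$segments), nrow(x$bifurcations), x$fractal_dimension))
  invisible(x)
}

#' Tidy tables of a measured fundus image
#'
#' @param x A `fundus_record`.
#' @param table Which table: per-`"segments"`, per-`"bifurcations"` or
#'   per-class `"global"` summaries.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fundus_record <- function(x, table = c("segments", "bifurcations", "global"),
                               ...) {
  table <- match.arg(table)
  switch(table,
    segments = dplyr::select(x$segments, -dplyr::any_of(c("diameters", "diam_valid"))),
    bifurcations = x$bifurcations,
    global = x$global)
}

#' One-row summary of a measured fundus image
#'
#' @param x A `fundus_record`.
#' @param ... Unused.
#' @return One-row tibble with QC status, zone equivalents, counts and
#'   whole-fundus means.
#' @export
glance.fundus_record <- function(x, ...) {
  ga <- x$global[x$global$vessel_class == "artery", ]
  gv <- x$global[x$global$vessel_class == "vein", ]
  tibble::tibble(
    source_id = x$source_id,
    quality_grade = x$quality_grade,
    qc_status = x$qc$status,
    qc_reasons = paste(x$qc$reasons, collapse = ";"),
    crae = x$zone$crae, crve = x$zone$crve, avre = x$zone$avre,
    n_arteries_zone = x$zone$n_arteries_zone,
    n_veins_zone = x$zone$n_veins_zone,
    n_arteries_fundus = unname(x$qc$counts["n_arteries_fundus"]),
    n_veins_fundus = unname(x$qc$counts["n_veins_fundus"]),
    n_segments = nrow(x$segments), n_bifurcations = nrow(x$bifurcations),
    artery_mean_diameter = ga$mean_diameter, vein_mean_diameter = gv$mean_diameter,
    artery_weighted_diameter = ga$weighted_diameter,
    vein_weighted_diameter = gv$weighted_diameter,
    artery_mean_arc = ga$mean_arc, vein_mean_arc = gv$mean_arc,
    artery_mean_ldr = ga$mean_ldr, vein_mean_ldr = gv$mean_ldr,
    fractal_dimension = x$fractal_dimension)
}

record_to_json <- function(record, path) {
  obj <- list(
    source_id = record$source_id,
    quality_grade = record$quality_grade,
    qc = list(status = record$qc$status, reasons = record$qc$reasons,
              counts = as.list(record$qc$counts)),
    disc = if (record$disc$present) {
      list(center = record$disc$center, radius = record$disc$radius)
    } else NULL,
    zone = record$zone,
    global = record$global,
    fractal_dimension = record$fractal_dimension,
    segments = tidy(record, "segments"),
    bifurcations = tidy(record, "bifurcations"),
    timings = as.list(record$timings))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Batch measurement pipeline
#'
#' Processes a directory of mask sets named `<id>_artery.png`,
#' `<id>_vein.png`, `<id>_disc.png` (optionally `<id>_fundus.png` for the
#' field of view): preprocesses each to the analysis frame, measures it,
#' applies quality control, and writes per-image JSON records, aggregated
#' `measurements.csv` (QC-passed) and `excluded.csv` (with reasons), a
#' per-segment and per-bifurcation CSV, and a run log with per-stage
#' timings. The pipeline is deterministic: identical inputs and
#' configuration give byte-identical CSVs.
#'
#' @param input_dir Directory of mask PNGs.
#' @param output_dir Output directory (created if needed).
#' @param config A [vessel_config].
#' @param preprocess Whether to FOV-crop and resize inputs to
#'   `config$target_side` first (default TRUE).
#' @return Invisibly, the list of `fundus_record` objects; unreadable inputs
#'   are logged and skipped.
#' @export
run_pipeline <- function(input_dir, output_dir, config = vessel_config(),
                         preprocess = TRUE) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  arts <- sort(list.files(input_dir, pattern = "_artery\\.(png|tif|tiff)$",
                          full.names = TRUE))
  ids <- sub("_artery\\.[a-z]+$", "", basename(arts))
  log_lines <- character(0)
  records <- list()
  failed <- character(0)
  for (i in seq_along(ids)) {
    id <- ids[i]
    ext <- tools::file_ext(arts[i])
    p <- function(cl) file.path(input_dir, paste0(id, "_", cl, ".", ext))
    fundus <- file.path(input_dir, paste0(id, "_fundus.png"))
    rec <- tryCatch({
      maps <- load_segmentation_maps(
        artery = p("artery"), vein = p("vein"), disc = p("disc"),
        fundus = if (file.exists(fundus)) fundus else NULL, source_id = id)
      if (preprocess) maps <- preprocess_maps(maps, config$target_side)
      measure_fundus(maps, config)
    }, error = function(e) {
      log_lines <<- c(log_lines, sprintf("SKIP %s: %s", id, conditionMessage(e)))
      failed <<- c(failed, id)
      NULL
    })
    if (is.null(rec)) next
    records[[id]] <- rec
    record_to_json(rec, file.path(output_dir, paste0(id, "_record.json")))
    log_lines <- c(log_lines, sprintf(
      "OK %s: qc=%s stages[s]: %s", id, rec$qc$status,
      paste(sprintf("%s=%.3f", names(rec$timings), rec$timings), collapse = " ")))
  }
  parts <- partition_results(unname(records))
  utils::write.csv(parts$passed, file.path(output_dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(parts$excluded, file.path(output_dir, "excluded.csv"),
                   row.names = FALSE)
  seg_all <- dplyr::bind_rows(lapply(records, function(r) {
    dplyr::mutate(tidy(r, "segments"), source_id = r$source_id, .before = 1)
  }))
  bif_all <- dplyr::bind_rows(lapply(records, function(r) {
    dplyr::mutate(tidy(r, "bifurcations"), source_id = r$source_id, .before = 1)
  }))
  utils::write.csv(seg_all, file.path(output_dir, "segments.csv"), row.names = FALSE)
  utils::write.csv(bif_all, file.path(output_dir, "bifurcations.csv"), row.names = FALSE)
  writeLines(log_lines, file.path(output_dir, "run.log"))
  if (length(failed)) {
    rlang::warn(sprintf("%d input(s) skipped: %s", length(failed),
                        paste(failed, collapse = ", ")))
  }
  invisible(records)
}

#' Mean per-stage timings over measurement records
#'
#' @param records List of `fundus_record` objects (or one record).
#' @return Tibble of stage names and mean elapsed seconds.
#' @export
report_timing <- function(records) {
  if (inherits(records, "fundus_record")) records <- list(records)
  tm <- do.call(rbind, lapply(records, function(r) r$timings))
  tibble::tibble(stage = colnames(tm), mean_seconds = colMeans(tm))
}
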