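#' Optic disc geometry from its mask
#'
#' Center is the centroid of the largest connected component; radius is the
#' equivalent-area circle radius `sqrt(area / pi)`. An empty mask yields
#' `present = FALSE` (a quality-control trigger downstream); multiple
#' components are flagged and the largest wins.
#'
#' @param disc_mask Binary optic-disc mask.
#' @return List of class `disc_geometry`: `center` (row, col), `radius`,
#'   `present`, `multi_component`.
#' @export
disc_geometry <- function(disc_mask) {
  m <- as_binary_matrix(disc_mask, "disc")
  if (sum(m) == 0L) {
    return(structure(list(center = c(NA_real_, NA_real_), radius = NA_real_,
                          present = FALSE, multi_component = FALSE),
                     class = "disc_geometry"))
  }
  lab <- EBImage::bwlabel(m * 1.0)
  tab <- tabulate(as.integer(lab[lab > 0]))
  keep <- which.max(tab)
  idx <- which(lab == keep, arr.ind = TRUE)
  structure(list(center = c(mean(idx[, 1]), mean(idx[, 2])),
                 radius = sqrt(nrow(idx) / pi),
                 present = TRUE,
                 multi_component = length(tab) > 1L),
            class = "disc_geometry")
}

#' @export
print.disc_geometry <- function(x, ...) {
  if (x$present) {
    cat(sprintf("<disc_geometry> center (%.1f, %.1f), radius %.1f px\n",
                x$center[1], x$center[2], x$radius))
  } else cat("<disc_geometry> absent\n")
  invisible(x)
}

#' Standard measurement zone
#'
#' The annulus from 0.5 to 1.0 disc diameters outward from the disc margin:
#' for disc radius `r` this is the band of radii `[2r, 3r]` (inclusive)
#' about the disc center, clipped to the image.
#'
#' @param disc A `disc_geometry` with `present = TRUE`.
#' @param shape Output dimensions `c(rows, cols)`.
#' @param inner_dd,outer_dd Zone limits in disc diameters from the margin.
#' @return Binary matrix of the annulus.
#' @export
standard_zone <- function(disc, shape, inner_dd = 0.5, outer_dd = 1.0) {
  if (!isTRUE(disc$present)) {
    rlang::abort("standard zone undefined: no detectable optic disc",
                 class = "vesselmetrics_qc_trigger")
  }
  r <- disc$radius
  rin <- r + inner_dd * 2 * r
  rout <- r + outer_dd * 2 * r
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  d <- sqrt((rows - disc$center[1])^2 + (cols - disc$center[2])^2)
  matrix(as.integer(d >= rin & d <= rout), shape[1], shape[2])
}

#' Widths of the distinct vessels crossing a zone
#'
#' Groups segments into distinct vessel paths (crossing continuations
#' merged, so one vessel crossing the zone twice counts once), takes each
#' path's width as the mean caliber of its centerline points inside the
#' zone, and returns up to the `n_top` largest widths in descending order
#' together with the count of distinct vessels for quality control.
#'
#' @param graph A `vessel_graph`.
#' @param measurements Output of [measure_segments()].
#' @param zone Binary zone mask (e.g. [standard_zone()]).
#' @param vessel_class `"artery"` or `"vein"`.
#' @param n_top Number of widths to return, default 6.
#' @return List: `widths` (descending, length <= `n_top`), `count` of
#'   distinct vessels intersecting the zone, `all_widths`.
#' @export
zone_vessel_widths <- function(graph, measurements, zone, vessel_class,
                               n_top = 6L) {
  m <- measurements[measurements$vessel_class == vessel_class, , drop = FALSE]
  s <- graph$segments
  if (!nrow(m)) return(list(widths = numeric(0), count = 0L, all_widths = numeric(0)))
  per_path <- list()
  for (i in seq_len(nrow(m))) {
    pts <- s$points[[match(m$segment_id[i], s$segment_id)]]
    inz <- zone[pts] == 1L
    if (!any(inz)) next
    d <- m$diameters[[i]]; v <- m$diam_valid[[i]]
    sel <- inz & v
    if (!any(sel)) sel <- inz
    key <- as.character(m$path_id[i])
    if (is.na(m$path_id[i])) key <- paste0("seg_", m$segment_id[i])
    per_path[[key]] <- c(per_path[[key]], d[sel])
  }
  if (!length(per_path)) return(list(widths = numeric(0), count = 0L,
                                     all_widths = numeric(0)))
  w <- sort(vapply(per_path, mean, double(1)), decreasing = TRUE)
  list(widths = unname(utils::head(w, n_top)), count = length(w),
       all_widths = unname(w))
}

#' Central retinal vessel equivalent (revised Knudtson-Parr-Hubbard)
#'
#' Iterative pairwise combination of up to six vessel calibers into a single
#' equivalent: at each round the calibers are sorted, the widest is paired
#' with the narrowest (then the second widest with the second narrowest,
#' and so on), each pair combining as `c * sqrt(w1^2 + w2^2)` with
#' `c = 0.88` for arteries (CRAE) and `c = 0.95` for veins (CRVE); with an
#' odd count the median caliber carries over unpaired. Rounds repeat until
#' a single value remains. A single input width is returned unchanged —
#' the combination constant applies only to pairs.
#'
#' @param widths Numeric vector of 1-6 positive calibers (pixels).
#' @param vessel_class `"artery"` or `"vein"` (selects the constant).
#' @param const Optional explicit combination constant overriding
#'   `vessel_class`.
#' @return The single equivalent caliber (pixels), or `NA` for empty input
#'   (flagged by quality control downstream).
#' @export
#' @examples
#' knudtson_equivalent(c(10, 10), "artery")          # 0.88 * sqrt(200)
#' knudtson_equivalent(rep(10, 6), "artery")         # ~ 17.484
#' knudtson_equivalent(rep(10, 6), "vein")           # ~ 21.376
knudtson_equivalent <- function(widths, vessel_class = c("artery", "vein"),
                                const = NULL) {
  if (is.null(const)) {
    vessel_class <- match.arg(vessel_class)
    const <- if (vessel_class == "artery") 0.88 else 0.95
  }
  w <- widths[!is.na(widths)]
  if (!length(w)) {
    rlang::warn("no widths supplied: equivalent undefined",
                class = "vesselmetrics_undefined_measure")
    return(NA_real_)
  }
  if (any(w <= 0)) {
    rlang::abort("vessel widths must be positive",
                 class = "vesselmetrics_contract_error")
  }
  while (length(w) > 1L) {
    w <- sort(w, decreasing = TRUE)
    n <- length(w)
    half <- n %/% 2L
    combined <- const * sqrt(w[seq_len(half)]^2 + w[n + 1L - seq_len(half)]^2)
    w <- if (n %% 2L == 1L) c(combined, w[half + 1L]) else combined
  }
  w
}

#' Arteriole-to-venule ratio from equivalents
#'
#' @param crae,crve Central retinal artery / vein equivalents (pixels).
#' @return `crae / crve`, or `NA` (with a warning) when `crve` is undefined
#'   or zero.
#' @export
avre <- function(crae, crve) {
  if (is.na(crae) || is.na(crve) || crve <= 0) {
    rlang::warn("AVRe undefined: missing or zero vein equivalent",
                class = "vesselmetrics_undefined_measure")
    return(NA_real_)
  }
  crae / crve
}

#' Whole-fundus summary per vessel class
#'
#' Unweighted means of arc, chord, length-diameter ratio and diameter over
#' segments, plus the length-weighted mean diameter
#' `sum(d_i * arc_i) / sum(arc_i)` and the segment count.
#'
#' @param measurements Output of [measure_segments()].
#' @return Tibble with one row per vessel class.
#' @export
global_summary <- function(measurements) {
  m <- measurements
  out <- lapply(c("artery", "vein"), function(cl) {
    g <- m[m$vessel_class == cl, , drop = FALSE]
    if (!nrow(g)) {
      return(tibble::tibble(vessel_class = cl, n_segments = 0L,
                            mean_arc = NA_real_, mean_chord = NA_real_,
                            mean_ldr = NA_real_, mean_diameter = NA_real_,
                            weighted_diameter = NA_real_))
    }
    tibble::tibble(
      vessel_class = cl, n_segments = nrow(g),
      mean_arc = mean(g$arc_length),
      mean_chord = mean(g$chord_length),
      mean_ldr = mean(g$ldr, na.rm = TRUE),
      mean_diameter = mean(g$mean_diameter),
      weighted_diameter = sum(g$mean_diameter * g$arc_length) / sum(g$arc_length))
  })
  dplyr::bind_rows(out)
}

#' Box-counting fractal dimension
#'
#' Least-squares slope of `log N(s)` against `log(1/s)` over box sizes
#' `s = 2, 4, 8, ..., side/4` with the box grid anchored at the origin
#' (deterministic; no randomized offsets). Roughly 1 for a line, 2 for a
#' filled region; retinal vasculature typically falls in between.
#'
#' @param skeleton Binary matrix (normally a vessel skeleton).
#' @return The fractal dimension, or `NA` if fewer than 3 box sizes fit.
#' @export
fractal_dimension <- function(skeleton) {
  pix <- which(skeleton == 1L, arr.ind = TRUE)
  if (nrow(pix) == 0L) return(NA_real_)
  side <- max(dim(skeleton))
  sizes <- 2^(1:floor(log2(side / 4)))
  if (length(sizes) < 3L) return(NA_real_)
  n_boxes <- vapply(sizes, function(s) {
    nrow(unique(cbind((pix[, 1] - 1L) %/% s, (pix[, 2] - 1L) %/% s)))
  }, double(1))
  stats::coef(stats::lm(log(n_boxes) ~ log(1 / sizes)))[[2]]
}
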