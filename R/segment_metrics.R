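#' Per-point vessel diameters along a centerline
#'
#' Caliber at each centerline point is estimated from the Euclidean distance
#' transform (EDT) of the class mask as `2 * EDT - 1`, with the EDT read as
#' the maximum over the point's 3x3 neighbourhood: a thinned skeleton tracks
#' the true medial axis only to within about one pixel, and the local EDT
#' maximum recovers the medial radius without the off-center negative bias.
#' The estimate is exact for odd-width straight strokes. Points within
#' `junction_exclude` path steps of a junction-attached end are marked
#' invalid: thinning produces junction blobs whose distance transform is
#' inflated.
#'
#' @param points Integer matrix of ordered `(row, col)` centerline points.
#' @param mask Binary class mask the centerline lies in (or its
#'   precomputed distance transform, passed as `edt`).
#' @param junction_exclude Integer vector of length 2: number of points to
#'   invalidate at the start and at the end of the centerline.
#' @param edt Optional precomputed `EBImage::distmap(mask)`.
#' @return A tibble with `diameter` and `valid` per centerline point.
#' @export
#' @examples
#' m <- matrix(0L, 11, 30); m[4:8, 2:29] <- 1L
#' pts <- cbind(row = rep(6L, 20), col = 6:25)
#' profile_diameters(pts, m)$diameter[1]  # 5, the stroke width
profile_diameters <- function(points, mask, junction_exclude = c(0L, 0L),
                              edt = NULL) {
  if (is.null(edt)) edt <- EBImage::distmap(mask)
  if (any(edt[points] <= 0)) {
    rlang::abort("centerline point falls outside the vessel mask",
                 class = "vesselmetrics_contract_error")
  }
  vals <- max3x3(edt)[points]
  n <- nrow(points)
  valid <- rep(TRUE, n)
  h <- junction_exclude[1]; t <- junction_exclude[2]
  if (h > 0) valid[seq_len(min(h, n))] <- FALSE
  if (t > 0) valid[seq(max(1L, n - t + 1L), n)] <- FALSE
  tibble::tibble(diameter = 2 * as.numeric(vals) - 1, valid = valid)
}

# 3x3 grayscale maximum filter (used to read the EDT at skeleton pixels)
max3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    sh <- matrix(0, nr, nc)
    ri <- max(1L, 1L - dr):min(nr, nr - dr)
    ci <- max(1L, 1L - dc):min(nc, nc - dc)
    sh[ri, ci] <- m[ri + dr, ci + dc]
    out <- pmax(out, sh)
  }
  out
}

#' Arc length of a centerline
#'
#' Sum of Euclidean steps between consecutive points (1 for axial moves,
#' sqrt(2) for diagonal moves on a pixel path). Works on any polyline,
#' including analytic (non-integer) ones.
#'
#' @param points Matrix of ordered `(row, col)` points.
#' @return Arc length in pixels.
#' @export
#' @examples
#' arc_length(cbind(1, 1:11))       # 10
#' arc_length(cbind(1:11, 1:11))    # 10 * sqrt(2)
arc_length <- function(points) {
  if (nrow(points) < 2L) return(0)
  d <- diff(points)
  sum(sqrt(rowSums(d^2)))
}

#' Chord length of a centerline
#'
#' Euclidean distance between the first and last points.
#'
#' @inheritParams arc_length
#' @return Chord length in pixels (0 for a closed/cyclic centerline).
#' @export
chord_length <- function(points) {
  if (nrow(points) < 2L) return(0)
  sqrt(sum((points[nrow(points), ] - points[1L, ])^2))
}

#' Simple tortuosity index
#'
#' Arc length divided by chord length; 1 for a perfectly straight segment.
#' Undefined (NA, with a warning) when the chord is zero, e.g. for a closed
#' loop.
#'
#' @inheritParams arc_length
#' @return Tortuosity (unitless, >= 1), or `NA` for zero chord.
#' @export
#' @examples
#' th <- seq(0, pi, length.out = 200)
#' semi <- cbind(50 * sin(th), 50 * cos(th))
#' tortuosity(semi)  # ~ pi / 2
tortuosity <- function(points) {
  ch <- chord_length(points)
  if (ch == 0) {
    rlang::warn("zero chord: tortuosity undefined",
                class = "vesselmetrics_undefined_measure")
    return(NA_real_)
  }
  arc_length(points) / ch
}

#' Length-diameter ratio
#'
#' @param arc Arc length(s), pixels.
#' @param mean_diameter Mean diameter(s), pixels, > 0.
#' @return `arc / mean_diameter`, unitless.
#' @export
ldr <- function(arc, mean_diameter) {
  ifelse(mean_diameter > 0, arc / mean_diameter, NA_real_)
}

#' Measure all segments of a vessel graph
#'
#' Computes the per-segment physical parameters: mean and SD of the diameter
#' profile (population SD over valid points), arc length, chord length,
#' length-diameter ratio and tortuosity, carrying the class and order labels
#' from the graph.
#'
#' @param graph A `vessel_graph` from [build_vessel_graph()].
#' @param maps The [seg_maps] the graph came from (class masks are needed for
#'   the diameter profiles).
#' @return A tibble with one row per segment and list-columns `diameters`
#'   (per-point) and `diam_valid` used downstream by the zone summary.
#' @export
measure_segments <- function(graph, maps) {
  stopifnot(inherits(graph, "vessel_graph"), inherits(maps, "seg_maps"))
  s <- graph$segments
  cfg <- graph$config
  edt <- list(artery = max3x3(EBImage::distmap(fill_small_holes(maps$artery))),
              vein = max3x3(EBImage::distmap(fill_small_holes(maps$vein))))
  edt_union <- EBImage::distmap(fill_small_holes((maps$artery | maps$vein) * 1L))
  junction_nodes <- graph$nodes$node_id[graph$nodes$kind != "endpoint"]
  # junction blobs inflate the distance transform over a reach that scales
  # with the local caliber: exclude at least junction_exclude_px points,
  # and at least the local half-width at the node
  node_reach <- function(node) {
    nd <- graph$nodes[match(node, graph$nodes$node_id), ]
    e <- edt_union[max(1L, min(nrow(edt_union), round(nd$row))),
                   max(1L, min(ncol(edt_union), round(nd$col)))]
    as.integer(max(cfg$junction_exclude_px, ceiling(e)))
  }
  n <- nrow(s)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    pts <- s$points[[i]]
    cls <- s$vessel_class[i]
    excl <- c(
      if (!is.na(s$node_a[i]) && s$node_a[i] %in% junction_nodes) node_reach(s$node_a[i]) else 0L,
      if (!is.na(s$node_b[i]) && s$node_b[i] %in% junction_nodes) node_reach(s$node_b[i]) else 0L
    )
    # points on the union skeleton can sit just outside their class mask at
    # crossings; profile on the class mask where covered, union elsewhere
    e <- edt[[cls]]
    vals <- e[pts]
    covered <- vals > 0
    prof_d <- 2 * as.numeric(vals) - 1
    if (any(!covered)) {
      eu <- pmax(edt$artery[pts], edt$vein[pts])
      prof_d[!covered] <- 2 * as.numeric(eu[!covered]) - 1
    }
    np <- nrow(pts)
    # extend each junction exclusion while the profile stays inflated
    # relative to the segment's own mid-run caliber: daughters of a
    # narrow-angle bifurcation merge with their sibling near the node, and
    # the merged run must not contribute to caliber or tangent estimates
    mid <- prof_d[max(1L, floor(np / 4)):min(np, ceiling(3 * np / 4))]
    med <- stats::median(mid)
    cap <- max(excl, floor(np / 3))
    if (excl[1] > 0) {
      while (excl[1] < cap && excl[1] < np && prof_d[excl[1] + 1L] > 1.2 * med) {
        excl[1] <- excl[1] + 1L
      }
    }
    if (excl[2] > 0) {
      while (excl[2] < cap && excl[2] < np && prof_d[np - excl[2]] > 1.2 * med) {
        excl[2] <- excl[2] + 1L
      }
    }
    valid <- rep(TRUE, np)
    if (excl[1] > 0) valid[seq_len(min(excl[1], np))] <- FALSE
    if (excl[2] > 0) valid[seq(max(1L, np - excl[2] + 1L), np)] <- FALSE
    valid <- valid & covered
    dv <- prof_d[valid]
    if (!length(dv)) dv <- prof_d
    arc <- arc_length(pts)
    ch <- if (s$cyclic[i]) 0 else chord_length(pts)
    tort <- if (ch > 0) arc / ch else NA_real_
    md <- mean(dv)
    out[[i]] <- tibble::tibble(
      segment_id = s$segment_id[i], vessel_class = cls,
      vessel_order = s$vessel_order[i] %||% NA_integer_,
      strahler_order = s$strahler_order[i] %||% NA_integer_,
      path_id = s$path_id[i] %||% NA_integer_,
      n_points = s$n_points[i], cyclic = s$cyclic[i],
      mean_diameter = md,
      sd_diameter = stats::sd(dv) * sqrt(max(0, (length(dv) - 1)) / max(1, length(dv))),
      arc_length = arc, chord_length = ch,
      ldr = ldr(arc, md), tortuosity = tort,
      excl_a = excl[1], excl_b = excl[2],
      diameters = list(prof_d), diam_valid = list(valid)
    )
  }
  if (!n) {
    return(tibble::tibble(segment_id = character(), vessel_class = character(),
                          vessel_order = integer(), strahler_order = integer(),
                          path_id = integer(), n_points = integer(),
                          cyclic = logical(), mean_diameter = double(),
                          sd_diameter = double(), arc_length = double(),
                          chord_length = double(), ldr = double(),
                          tortuosity = double(), excl_a = integer(),
                          excl_b = integer(), diameters = list(),
                          diam_valid = list()))
  }
  dplyr::bind_rows(out)
}
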