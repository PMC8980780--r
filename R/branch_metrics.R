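#' Branching coefficient
#'
#' `BC = (d1^2 + d2^2) / d0^2` for a bifurcation with trunk caliber `d0` and
#' daughter calibers `d1 >= d2`. Equals 2 for three equal calibers and
#' `2^(1/3)` for a Murray-optimal symmetric bifurcation.
#'
#' @param d0,d1,d2 Trunk and daughter diameters (pixels); vectorized.
#' @return Unitless coefficient.
#' @export
branching_coefficient <- function(d0, d1, d2) {
  ifelse(d0 > 0, (d1^2 + d2^2) / d0^2, NA_real_)
}

#' Asymmetry ratio
#'
#' `AR = (d2 / d1)^2` with `d1` the wider daughter; 1 for a symmetric
#' bifurcation. Arguments in either order are accepted.
#'
#' @param d1,d2 Daughter diameters (pixels); vectorized.
#' @return Unitless ratio in (0, 1].
#' @export
asymmetry_ratio <- function(d1, d2) {
  hi <- pmax(d1, d2); lo <- pmin(d1, d2)
  ifelse(hi > 0, (lo / hi)^2, NA_real_)
}

#' Angular asymmetry
#'
#' Absolute difference of the two daughters' deviation angles from the
#' extrapolated parent direction: 0 for a symmetric bifurcation.
#'
#' @param theta1,theta2 Unsigned daughter deviation angles, degrees.
#' @return Degrees.
#' @export
angular_asymmetry <- function(theta1, theta2) abs(theta1 - theta2)

#' Junctional exponent deviation
#'
#' Departure of a bifurcation from Murray's law `d0^3 = d1^3 + d2^3`,
#' expressed as `JED = ((d1^3 + d2^3)^(1/3) - d0) / d0`. Zero when the law
#' holds exactly; positive when the daughters are oversized relative to the
#' trunk. This closed form is preferred to solving `d0^x = d1^x + d2^x` for
#' the junctional exponent x, which has no root whenever
#' `d0 <= max(d1, d2)`; the deviation form is total and monotone in the
#' Murray residual.
#'
#' @param d0,d1,d2 Trunk and daughter diameters (pixels); vectorized.
#' @return Unitless deviation.
#' @export
#' @examples
#' junctional_exponent_deviation(10, 10 * 2^(-1/3), 10 * 2^(-1/3))  # ~ 0
junctional_exponent_deviation <- function(d0, d1, d2) {
  ifelse(d0 > 0, ((d1^3 + d2^3)^(1 / 3) - d0) / d0, NA_real_)
}

# mean caliber of the `k` valid profile points of segment `idx` nearest the
# given node; falls back to all points past the exclusion zone if fewer
local_diameter_at_node <- function(measurements, seg_row, node, k = 5L,
                                   skip_extra = 0L) {
  d <- measurements$diameters[[seg_row]]
  v <- measurements$diam_valid[[seg_row]]
  at_a <- !is.na(measurements$node_a_cache[seg_row]) &&
    measurements$node_a_cache[seg_row] == node
  ord <- if (at_a) seq_along(d) else rev(seq_along(d))
  if (skip_extra > 0L) {
    v2 <- v; v2[ord[seq_len(min(skip_extra, length(ord)))]] <- FALSE
    if (any(v2)) v <- v2
  }
  dv <- d[ord][v[ord]]
  if (!length(dv)) dv <- d[ord]
  mean(dv[seq_len(min(k, length(dv)))])
}

#' Detect bifurcations and measure their geometry
#'
#' A bifurcation is a branch node (degree 3) whose three incident segments
#' all share one vessel class; crossings are excluded. The parent is the
#' incident segment with the lowest vessel order (nearest the root); on ties
#' the widest segment is taken as parent and the row is flagged. Daughters
#' are ranked by caliber (`d1 >= d2`). Calibers `d0, d1, d2` are means of
#' the 5 valid profile points nearest the node. Angles:
#'
#' * `ba` — branching angle between the two daughter centerline tangents;
#' * `ba_edge` — same angle from total-least-squares fits to the daughters'
#'   two wall contours within `ba_edge_reach` pixels of the node;
#' * `theta1, theta2` — unsigned daughter deviations from the extrapolated
#'   parent direction; `aa = |theta1 - theta2|`.
#'
#' @param graph A `vessel_graph` with orders assigned.
#' @param maps The originating [seg_maps].
#' @param measurements Segment measurements from [measure_segments()]
#'   (computed on the fly if missing).
#' @return A tibble with one row per bifurcation: calibers, angles, `bc`,
#'   `aa`, `ar`, `jed` and flags.
#' @export
measure_bifurcations <- function(graph, maps, measurements = NULL) {
  stopifnot(inherits(graph, "vessel_graph"))
  if (is.null(measurements)) measurements <- measure_segments(graph, maps)
  cfg <- graph$config
  s <- graph$segments
  m <- measurements
  m$node_a_cache <- s$node_a[match(m$segment_id, s$segment_id)]
  m$node_b_cache <- s$node_b[match(m$segment_id, s$segment_id)]

  empty <- tibble::tibble(node_id = integer(), vessel_class = character(),
                          parent = character(), daughter1 = character(),
                          daughter2 = character(), d0 = double(), d1 = double(),
                          d2 = double(), theta1 = double(), theta2 = double(),
                          ba = double(), ba_edge = double(), bc = double(),
                          aa = double(), ar = double(), jed = double(),
                          parent_tie = logical(), ba_edge_flag = character())
  branch_nodes <- graph$nodes$node_id[graph$nodes$kind == "branch"]
  if (!length(branch_nodes) || !nrow(s)) return(empty)
  inc <- incident_ends(graph)
  rows <- list()
  for (v in branch_nodes) {
    here <- inc[inc$node_id == v, ]
    if (nrow(here) != 3L) next
    idxs <- here$seg_idx
    cls <- unique(s$vessel_class[idxs])
    if (length(cls) != 1L) next
    mrow <- match(s$segment_id[idxs], m$segment_id)
    if (any(is.na(mrow))) next
    dloc <- vapply(seq_len(3L), function(j) {
      local_diameter_at_node(m, mrow[j], v, k = cfg$node_caliber_window)
    }, double(1))
    vo <- s$vessel_order[idxs]
    parent_tie <- FALSE
    if (all(is.na(vo))) {
      pj <- which.max(dloc); parent_tie <- TRUE
    } else {
      vo2 <- ifelse(is.na(vo), Inf, vo)
      lo <- which(vo2 == min(vo2))
      if (length(lo) > 1L) { pj <- lo[which.max(dloc[lo])]; parent_tie <- TRUE }
      else pj <- lo
    }
    dj <- setdiff(seq_len(3L), pj)
    if (dloc[dj[2]] > dloc[dj[1]]) dj <- rev(dj)
    win <- cfg$tangent_window
    end_skip <- vapply(seq_len(3L), function(j) {
      if (here$end[j] == "a") m$excl_a[mrow[j]] else m$excl_b[mrow[j]]
    }, integer(1))
    # daughters of a narrow-angle bifurcation run merged with their sibling
    # for several pixels past the node: their strokes overlap and the thinned
    # centerline between the split point and the node is not the vessel's
    # own axis. Start each daughter's window at the first point farther from
    # the sibling than the two half-calibers.
    from_node <- function(j) {
      pts <- s$points[[idxs[j]]]
      if (here$end[j] == "b") pts <- pts[nrow(pts):1, , drop = FALSE]
      pts
    }
    merge_skip <- function(jA, jB) {
      A <- from_node(jA); B <- from_node(jB)
      lim <- (m$mean_diameter[mrow[jA]] + m$mean_diameter[mrow[jB]]) / 2 + 1
      nB <- min(nrow(B), 40L)
      nA <- min(nrow(A), 40L)
      for (i in seq_len(nA)) {
        d <- sqrt(min((B[seq_len(nB), 1] - A[i, 1])^2 +
                      (B[seq_len(nB), 2] - A[i, 2])^2))
        if (d > lim) return(i - 1L)
      }
      nA - 1L
    }
    dj_pre <- setdiff(seq_len(3L), pj)
    msk <- merge_skip(dj_pre[1], dj_pre[2])
    for (j in dj_pre) end_skip[j] <- max(end_skip[j], msk)
    if (msk > 0L) {
      for (j in dj_pre) {
        dloc[j] <- local_diameter_at_node(m, mrow[j], v,
                                          k = cfg$node_caliber_window,
                                          skip_extra = msk)
      }
      if (dloc[dj[2]] > dloc[dj[1]]) dj <- rev(dj)
    }
    tang <- lapply(seq_len(3L), function(j) {
      segment_end_tangent(s$points[[idxs[j]]], here$end[j], win, end_skip[j])
    })
    # extrapolated parent direction: flow into the node, continued
    par_dir <- -tang[[pj]]
    th1 <- angle_between_deg(tang[[dj[1]]], par_dir)
    th2 <- angle_between_deg(tang[[dj[2]]], par_dir)
    ba <- angle_between_deg(tang[[dj[1]]], tang[[dj[2]]])
    mask <- if (cls == "artery") maps$artery else maps$vein
    bae <- branching_angle_edges(
      s$points[[idxs[dj[1]]]], here$end[dj[1]],
      s$points[[idxs[dj[2]]]], here$end[dj[2]],
      mask, reach = cfg$ba_edge_reach,
      skip = c(end_skip[dj[1]], end_skip[dj[2]]))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      node_id = v, vessel_class = cls,
      parent = s$segment_id[idxs[pj]],
      daughter1 = s$segment_id[idxs[dj[1]]],
      daughter2 = s$segment_id[idxs[dj[2]]],
      d0 = dloc[pj], d1 = dloc[dj[1]], d2 = dloc[dj[2]],
      theta1 = th1, theta2 = th2,
      ba = ba, ba_edge = bae$angle,
      bc = branching_coefficient(dloc[pj], dloc[dj[1]], dloc[dj[2]]),
      aa = angular_asymmetry(th1, th2),
      ar = asymmetry_ratio(dloc[dj[1]], dloc[dj[2]]),
      jed = junctional_exponent_deviation(dloc[pj], dloc[dj[1]], dloc[dj[2]]),
      parent_tie = parent_tie, ba_edge_flag = bae$flag)
  }
  if (!length(rows)) return(empty)
  dplyr::bind_rows(rows)
}

# Direction of one daughter from total-least-squares fits to its two wall
# contours; both daughters -> the edge-based branching angle.
daughter_edge_direction <- function(points, end, mask, reach = 10, skip = 2L) {
  n <- nrow(points)
  ord <- if (end == "a") seq_len(n) else rev(seq_len(n))
  pts <- points[ord, , drop = FALSE]
  keep <- seq(from = min(skip + 1L, n), to = n)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 3L) return(list(dir = NULL, flag = "insufficient_wall"))
  # restrict to the wall reach (path distance from the node end)
  steps <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  pts <- pts[steps <= reach, , drop = FALSE]
  if (nrow(pts) < 3L) return(list(dir = NULL, flag = "insufficient_wall"))
  nr <- nrow(mask); nc <- ncol(mask)
  inside <- function(r, c) {
    ri <- round(r); ci <- round(c)
    ri >= 1 && ri <= nr && ci >= 1 && ci <= nc && mask[ri, ci] == 1L
  }
  left <- NULL; right <- NULL
  for (i in seq_len(nrow(pts))) {
    lo <- max(1L, i - 2L); hi <- min(nrow(pts), i + 2L)
    tg <- pts[hi, ] - pts[lo, ]
    tg <- tg / sqrt(sum(tg^2))
    nrm <- c(-tg[2], tg[1])
    for (sgn in c(1, -1)) {
      t <- 0
      while (t < 20 && inside(pts[i, 1] + sgn * (t + 0.25) * nrm[1],
                              pts[i, 2] + sgn * (t + 0.25) * nrm[2])) t <- t + 0.25
      wall <- pts[i, ] + sgn * t * nrm
      if (sgn > 0) left <- rbind(left, wall) else right <- rbind(right, wall)
    }
  }
  fit_dir <- function(w) {
    if (is.null(w) || nrow(w) < 3L) return(NULL)
    X <- sweep(w, 2, colMeans(w))
    svd(X, nu = 0, nv = 1)$v[, 1]
  }
  dl <- fit_dir(left); dr <- fit_dir(right)
  if (is.null(dl) || is.null(dr)) return(list(dir = NULL, flag = "insufficient_wall"))
  ref <- pts[nrow(pts), ] - pts[1, ]
  if (sum(dl * ref) < 0) dl <- -dl
  if (sum(dr * ref) < 0) dr <- -dr
  d <- dl + dr
  list(dir = d / sqrt(sum(d^2)), flag = "ok")
}

branching_angle_edges <- function(points1, end1, points2, end2, mask,
                                  reach = 10, skip = c(2L, 2L)) {
  e1 <- daughter_edge_direction(points1, end1, mask, reach, skip[1])
  e2 <- daughter_edge_direction(points2, end2, mask, reach, skip[2])
  if (is.null(e1$dir) || is.null(e2$dir)) {
    return(list(angle = NA_real_, flag = "insufficient_wall"))
  }
  list(angle = angle_between_deg(e1$dir, e2$dir), flag = "ok")
}
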