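#' Specification of a synthetic vascular tree
#'
#' Parameterizes the bundled generator of artery/vein trees with exhaustive
#' ground truth. Defaults emulate a disc-centered fundus at the standard
#' 512-pixel analysis frame: three trunks per class radiating from the disc,
#' calibers tapering by Murray's law with exponent 3, a 70 degree nominal
#' branching angle, and a mild sinusoidal tortuosity.
#'
#' @param n_levels Number of branching generations (>= 1).
#' @param root_width Artery trunk caliber at the root, pixels.
#' @param vein_root_width Vein trunk caliber; default `1.25 * root_width`
#'   (venules are wider than arterioles).
#' @param murray_exponent Exponent x of the caliber taper
#'   `d0^x = d1^x + d2^x` at bifurcations; 3 is Murray's law.
#' @param asymmetry Daughter caliber ratio `d2/d1` in (0, 1]; 1 = symmetric.
#' @param branch_angle_deg Nominal angle between the two daughters, degrees.
#' @param tortuosity_amp Amplitude (pixels) of the sinusoidal centerline
#'   perturbation (one period per segment); 0 = straight segments.
#' @param len_ratio Factor by which segment length shrinks per generation
#'   (first-generation length is 1.5 disc radii). Default 0.8.
#' @param branch_angle_ratio Factor by which the branching angle shrinks per
#'   generation. Default 1 (constant angle); values below 1 keep deep trees
#'   planar (a constant-angle full binary tree self-intersects from about
#'   five generations).
#' @param disc_center `(row, col)` of the optic disc; default image center.
#' @param disc_radius Disc radius, pixels; default `image_side / 12`.
#' @param image_side Side of the square image, pixels.
#' @param n_trunks Trunks per vessel class radiating from the disc.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return List of class `synth_tree_spec`.
#' @export
synth_tree_spec <- function(n_levels = 4L, root_width = 9,
                            vein_root_width = NULL, murray_exponent = 3,
                            asymmetry = 1, branch_angle_deg = 70,
                            tortuosity_amp = 0.8, len_ratio = 0.8,
                            branch_angle_ratio = 1,
                            disc_center = NULL,
                            disc_radius = NULL, image_side = 512L,
                            n_trunks = 3L, seed = 1L) {
  stopifnot(n_levels >= 1, root_width >= 1, murray_exponent > 0,
            asymmetry > 0, asymmetry <= 1, branch_angle_deg > 0,
            tortuosity_amp >= 0, len_ratio > 0, len_ratio <= 1,
            branch_angle_ratio > 0, branch_angle_ratio <= 1,
            image_side >= 64, n_trunks >= 1)
  if (is.null(disc_center)) disc_center <- c(image_side / 2, image_side / 2)
  if (is.null(disc_radius)) disc_radius <- image_side / 12
  structure(list(n_levels = as.integer(n_levels), root_width = root_width,
                 vein_root_width = vein_root_width %||% 1.25 * root_width,
                 murray_exponent = murray_exponent, asymmetry = asymmetry,
                 branch_angle_deg = branch_angle_deg,
                 tortuosity_amp = tortuosity_amp, len_ratio = len_ratio,
                 branch_angle_ratio = branch_angle_ratio,
                 disc_center = disc_center, disc_radius = disc_radius,
                 image_side = as.integer(image_side),
                 n_trunks = as.integer(n_trunks), seed = as.integer(seed)),
            class = "synth_tree_spec")
}

# daughter calibers from the taper d0^x = d1^x + d2^x with d2 = a * d1
murray_daughters <- function(d0, x, a) {
  d1 <- d0 * (1 + a^x)^(-1 / x)
  c(d1, a * d1)
}

# dense centerline of one segment: straight run plus one sinusoid period
synth_centerline <- function(p0, angle_rad, len, amp, s_sign, step = 0.25) {
  t <- seq(0, len, by = step)
  if (t[length(t)] < len) t <- c(t, len)
  u <- c(cos(angle_rad), sin(angle_rad))
  nv <- c(-sin(angle_rad), cos(angle_rad))
  off <- s_sign * amp * sin(2 * pi * t / len)
  pts <- cbind(p0[1] + t * u[1] + off * nv[1],
               p0[2] + t * u[2] + off * nv[2])
  # analytic tangent rotation from the sinusoid at both endpoints
  beta <- atan(s_sign * amp * 2 * pi / len)
  list(points = pts, end = pts[nrow(pts), ],
       angle_start = angle_rad + beta, angle_end = angle_rad + beta)
}

#' Generate a synthetic vascular tree and its segmentation maps
#'
#' Grows one tree per class per trunk, rasterizes them as hard binary
#' strokes (discs of radius `width / 2` stamped along the centerline, no
#' anti-aliasing, so a stroke covers the pixels whose centers it contains
#' and the caliber estimator `2 * EDT - 1` is exact on odd-width straight
#' runs), draws the disc as a filled circle, and returns complete
#' ground truth: per-segment width, arc, chord, tortuosity, vessel order
#' and Strahler order; per-bifurcation calibers and angles; the topology
#' as parent-child edges. Artery and vein trunks are interleaved around the
#' disc so their peripheral branches cross, giving the union mask genuine
#' artery-vein crossing points.
#'
#' @param spec A [synth_tree_spec].
#' @return List with `truth` (list of tibbles `segments`, `bifurcations`,
#'   `edges`) and `maps` (a [seg_maps]).
#' @export
#' @examples
#' g <- generate_tree(synth_tree_spec(n_levels = 2, image_side = 256, seed = 7))
#' nrow(g$truth$segments)
generate_tree <- function(spec) {
  stopifnot(inherits(spec, "synth_tree_spec"))
  side <- spec$image_side
  r <- spec$disc_radius
  ctr <- spec$disc_center
  len1 <- 1.5 * r
  len_ratio <- spec$len_ratio %||% 0.8
  withr::with_seed(spec$seed, {
    seg_rows <- list(); bif_rows <- list(); edge_rows <- list()
    grow <- function(cls, trunk, p0, angle, width, level, parent_key) {
      len <- len1 * len_ratio^(level - 1)
      s_sign <- sample(c(-1, 1), 1)
      amp <- if (spec$tortuosity_amp > 0) spec$tortuosity_amp else 0
      cl <- synth_centerline(p0, angle, len, amp, s_sign)
      key <- sprintf("%s_t%d_l%d_n%d", substr(cls, 1, 1), trunk, level,
                     length(seg_rows) + 1L)
      pts <- cl$points
      arc <- arc_length(pts)
      chord <- chord_length(pts)
      seg_rows[[length(seg_rows) + 1L]] <<- tibble::tibble(
        segment_key = key, vessel_class = cls, trunk = trunk, level = level,
        width = width, arc = arc, chord = chord, tortuosity = arc / chord,
        r0 = pts[1, 1], c0 = pts[1, 2], r1 = cl$end[1], c1 = cl$end[2],
        angle_end = cl$angle_end, polyline = list(pts))
      if (!is.null(parent_key)) {
        edge_rows[[length(edge_rows) + 1L]] <<- tibble::tibble(
          parent_key = parent_key, child_key = key)
      }
      if (level < spec$n_levels) {
        dd <- murray_daughters(width, spec$murray_exponent, spec$asymmetry)
        ang_here <- spec$branch_angle_deg *
          (spec$branch_angle_ratio %||% 1)^(level - 1)
        half <- ang_here / 2 * pi / 180
        j <- stats::runif(2, -3, 3) * pi / 180
        ang_plus <- cl$angle_end + half + j[1]
        ang_minus <- cl$angle_end - half - j[2]
        flip <- sample(c(TRUE, FALSE), 1)
        w_plus <- if (flip) dd[2] else dd[1]
        w_minus <- if (flip) dd[1] else dd[2]
        k1 <- grow(cls, trunk, cl$end, ang_plus, w_plus, level + 1L, key)
        k2 <- grow(cls, trunk, cl$end, ang_minus, w_minus, level + 1L, key)
        # actual initial tangents of the daughters (sinusoid rotation
        # included; for a one-period sinusoid start and end tangents match,
        # so the stored angle_end is also the analytic start tangent)
        stored_angle <- function(kk) {
          for (srow in seg_rows) if (srow$segment_key == kk) return(srow$angle_end)
          NA_real_
        }
        u1 <- c(cos(stored_angle(k1)), sin(stored_angle(k1)))
        u2 <- c(cos(stored_angle(k2)), sin(stored_angle(k2)))
        pv <- c(cos(cl$angle_end), sin(cl$angle_end))
        th <- c(angle_between_deg(u1, pv), angle_between_deg(u2, pv))
        tang <- list(u1, u2)
        d1 <- max(w_plus, w_minus); d2 <- min(w_plus, w_minus)
        bif_rows[[length(bif_rows) + 1L]] <<- tibble::tibble(
          vessel_class = cls, trunk = trunk, level = level,
          row = cl$end[1], col = cl$end[2],
          d0 = width, d1 = d1, d2 = d2,
          ba_nominal = spec$branch_angle_deg *
            (spec$branch_angle_ratio %||% 1)^(level - 1),
          ba_actual = angle_between_deg(tang[[1]], tang[[2]]),
          theta1 = th[1], theta2 = th[2], aa = abs(th[1] - th[2]),
          jed = junctional_exponent_deviation(width, d1, d2))
      }
      key
    }
    base_a <- seq(90, 90 + 360 * (spec$n_trunks - 1) / 3, by = 120)[seq_len(spec$n_trunks)]
    base_v <- base_a - 60
    for (cls in c("artery", "vein")) {
      base <- if (cls == "artery") base_a else base_v
      w0 <- if (cls == "artery") spec$root_width else spec$vein_root_width
      for (tk in seq_len(spec$n_trunks)) {
        a <- (base[tk] + stats::runif(1, -8, 8)) * pi / 180
        p0 <- ctr + r * c(cos(a), sin(a))
        grow(cls, tk, p0, a, w0, 1L, NULL)
      }
    }
  })
  segments <- dplyr::bind_rows(seg_rows)
  bifs <- if (length(bif_rows)) dplyr::bind_rows(bif_rows) else
    tibble::tibble(vessel_class = character(), trunk = integer(),
                   level = integer(), row = double(), col = double(),
                   d0 = double(), d1 = double(), d2 = double(),
                   ba_nominal = double(), ba_actual = double(),
                   theta1 = double(), theta2 = double(), aa = double(),
                   jed = double())
  edges <- if (length(edge_rows)) dplyr::bind_rows(edge_rows) else
    tibble::tibble(parent_key = character(), child_key = character())

  # bounds check before rasterizing
  margin <- max(segments$width) / 2 + 2
  all_pts <- do.call(rbind, segments$polyline)
  if (min(all_pts) < margin || max(all_pts) > side - margin) {
    rlang::abort(paste0("tree exceeds image bounds; enlarge image_side ",
                        "(or reduce n_levels/disc_radius)"),
                 class = "vesselmetrics_layout_error")
  }

  segments$vessel_order <- segments$level
  segments$strahler_order <- truth_strahler(segments, edges)
  # the caliber the rasterization actually realizes: a binary grid cannot
  # draw fractional widths exactly (an axial 4.5-px stroke is 5 px wide),
  # so the drawn caliber is recorded numerically, like the tortuosity
  segments$width_realized <- vapply(seq_len(nrow(segments)), function(i) {
    realized_width(segments$polyline[[i]], segments$width[i])
  }, double(1))
  # bifurcation truth carries both nominal and realized calibers
  if (nrow(bifs)) {
    bifs$d0_realized <- NA_real_; bifs$d1_realized <- NA_real_
    bifs$d2_realized <- NA_real_
    for (i in seq_len(nrow(bifs))) {
      par <- segments[segments$vessel_class == bifs$vessel_class[i] &
                        abs(segments$r1 - bifs$row[i]) < 1e-6 &
                        abs(segments$c1 - bifs$col[i]) < 1e-6, ]
      kid <- segments[segments$vessel_class == bifs$vessel_class[i] &
                        abs(segments$r0 - bifs$row[i]) < 1e-6 &
                        abs(segments$c0 - bifs$col[i]) < 1e-6, ]
      if (nrow(par) == 1L && nrow(kid) == 2L) {
        bifs$d0_realized[i] <- par$width_realized
        bifs$d1_realized[i] <- max(kid$width_realized)
        bifs$d2_realized[i] <- min(kid$width_realized)
      }
    }
    bifs$jed_realized <- junctional_exponent_deviation(
      bifs$d0_realized, bifs$d1_realized, bifs$d2_realized)
  } else {
    bifs$d0_realized <- double(0); bifs$d1_realized <- double(0)
    bifs$d2_realized <- double(0); bifs$jed_realized <- double(0)
  }
  maps <- raster_tree(segments, ctr, r, side,
                      source_id = sprintf("synth_%d", spec$seed))
  list(truth = list(segments = segments, bifurcations = bifs, edges = edges,
                    spec = spec),
       maps = maps)
}

# inscribed caliber of an isolated rasterized stroke, measured on its
# analytic centerline: mean over interior samples of twice the distance to
# the nearest uncovered pixel center, minus one
realized_width <- function(pts, w) {
  rad <- max(0, w / 2 - 1e-6)
  R <- ceiling(rad)
  pad <- R + 3L
  r0 <- floor(min(pts[, 1])) - pad; c0 <- floor(min(pts[, 2])) - pad
  nr <- ceiling(max(pts[, 1])) - r0 + pad + 1L
  nc <- ceiling(max(pts[, 2])) - c0 + pad + 1L
  canvas <- matrix(0L, nr, nc)
  loc <- cbind(pts[, 1] - r0 + 1, pts[, 2] - c0 + 1)
  offs <- as.matrix(expand.grid(dr = -R:R, dc = -R:R))
  offs <- offs[offs[, 1]^2 + offs[, 2]^2 <= rad^2 + 1e-9, , drop = FALSE]
  lin <- (round(loc[, 2]) - 1L) * nr + round(loc[, 1])
  canvas[outer(lin, offs[, 2] * nr + offs[, 1], "+")] <- 1L
  steps <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  keep <- steps > w / 2 + 1 & steps < max(steps) - w / 2 - 1
  samp <- loc[keep, , drop = FALSE]
  samp <- samp[seq(1, nrow(samp), by = 8L), , drop = FALSE]
  if (!nrow(samp)) samp <- loc[round(nrow(loc) / 2), , drop = FALSE]
  win <- R + 2L
  dvals <- vapply(seq_len(nrow(samp)), function(i) {
    p <- samp[i, ]
    rr <- max(1L, round(p[1]) - win):min(nr, round(p[1]) + win)
    cc <- max(1L, round(p[2]) - win):min(nc, round(p[2]) + win)
    sub <- canvas[rr, cc]
    zero <- which(sub == 0L, arr.ind = TRUE)
    min(sqrt((zero[, 1] + rr[1] - 1 - p[1])^2 + (zero[, 2] + cc[1] - 1 - p[2])^2))
  }, double(1))
  mean(2 * dvals - 1)
}

# independent bottom-up Strahler on the truth topology
truth_strahler <- function(segments, edges) {
  n <- nrow(segments)
  st <- rep(NA_integer_, n)
  kids <- split(edges$child_key, edges$parent_key)
  compute <- function(key) {
    i <- match(key, segments$segment_key)
    if (!is.na(st[i])) return(st[i])
    ch <- kids[[key]]
    val <- if (is.null(ch)) 1L else {
      ks <- vapply(ch, compute, integer(1))
      m <- max(ks)
      if (sum(ks == m) >= 2L) m + 1L else m
    }
    st[i] <<- val
    val
  }
  for (key in segments$segment_key) compute(key)
  st
}

# stamp binary strokes along dense centerlines; returns seg_maps
raster_tree <- function(segments, disc_center, disc_radius, side, source_id) {
  canvas <- list(artery = matrix(0L, side, side), vein = matrix(0L, side, side))
  for (i in seq_len(nrow(segments))) {
    cls <- segments$vessel_class[i]
    pts <- segments$polyline[[i]]
    # a stroke of width w covers pixels whose centers lie within w/2 of the
    # centerline: odd integer widths rasterize exactly and the caliber
    # estimator 2*EDT - 1 recovers them; fractional widths quantize to the
    # nearest odd with at most ~1 px error
    rad <- max(0, segments$width[i] / 2 - 1e-6)
    R <- ceiling(rad)
    offs <- as.matrix(expand.grid(dr = -R:R, dc = -R:R))
    offs <- offs[offs[, 1]^2 + offs[, 2]^2 <= rad^2 + 1e-9, , drop = FALSE]
    ri <- round(pts[, 1]); ci <- round(pts[, 2])
    lin <- (ci - 1L) * side + ri
    delta <- offs[, 2] * side + offs[, 1]
    idx <- outer(lin, delta, "+")
    canvas[[cls]][idx] <- 1L
  }
  disc <- matrix(0L, side, side)
  rows <- matrix(seq_len(side), side, side)
  cols <- matrix(seq_len(side), side, side, byrow = TRUE)
  disc[(rows - disc_center[1])^2 + (cols - disc_center[2])^2 <= disc_radius^2] <- 1L
  seg_maps(canvas$artery, canvas$vein, disc, source_id = source_id)
}

#' Generate a repeat-imaging pair of the same synthetic eye
#'
#' Emulates repeated photography of one eye: the same tree is rasterized
#' twice, the second time after a small random rigid motion (rotation about
#' the image center plus translation) whose pixel displacement is bounded
#' by `jitter_px` anywhere in the frame.
#'
#' @param spec A [synth_tree_spec] (the eye).
#' @param jitter_px Upper bound for the rigid displacement, pixels; 0 gives
#'   two identical mask sets.
#' @param seed2 Seed for the rigid motion (independent of the tree seed).
#' @return List with `first` and `second` ([seg_maps]) and the shared
#'   `truth`.
#' @export
make_repeat_pair <- function(spec, jitter_px, seed2 = spec$seed + 1000L) {
  stopifnot(jitter_px >= 0)
  g <- generate_tree(spec)
  side <- spec$image_side
  segs <- g$truth$segments
  withr::with_seed(as.integer(seed2), {
    alpha <- stats::runif(1, -1, 1) * jitter_px / (side / 2) / 2
    mag <- stats::runif(1, 0, jitter_px / 2)
    dir <- stats::runif(1, 0, 2 * pi)
    tr <- mag * c(cos(dir), sin(dir))
  })
  rot <- matrix(c(cos(alpha), sin(alpha), -sin(alpha), cos(alpha)), 2, 2)
  ctr <- c(side / 2, side / 2)
  transform <- function(p) sweep(sweep(p, 2, ctr) %*% t(rot), 2, ctr + tr, "+")
  segs2 <- segs
  segs2$polyline <- lapply(segs$polyline, transform)
  d2 <- as.vector(transform(matrix(spec$disc_center, 1)))
  maps2 <- raster_tree(segs2, d2, spec$disc_radius, side,
                       source_id = paste0(g$maps$source_id, "_repeat"))
  list(first = g$maps, second = maps2, truth = g$truth)
}

#' Match measured segments and bifurcations to synthetic ground truth
#'
#' Measured segments are matched to the nearest truth centerline of the
#' same class (by the distance from the measured segment's midpoint to the
#' truth polyline); measured bifurcations to the nearest truth bifurcation
#' of the same class within `tol` pixels.
#'
#' @param truth `truth` element from [generate_tree()].
#' @param graph The `vessel_graph` measured from the rasterized maps.
#' @param measurements Output of [measure_segments()].
#' @param bifurcations Output of [measure_bifurcations()] (optional).
#' @param tol Matching tolerance in pixels.
#' @return List of tibbles `segments` (measured vs true width, arc,
#'   tortuosity, orders) and `bifurcations` (measured vs true calibers and
#'   angles).
#' @export
match_truth <- function(truth, graph, measurements, bifurcations = NULL,
                        tol = 6) {
  ts <- truth$segments
  seg_rows <- list()
  for (i in seq_len(nrow(measurements))) {
    sid <- measurements$segment_id[i]
    pts <- graph$segments$points[[match(sid, graph$segments$segment_id)]]
    mid <- pts[ceiling(nrow(pts) / 2), ]
    cls <- measurements$vessel_class[i]
    cand <- which(ts$vessel_class == cls)
    if (!length(cand)) next
    dmin <- vapply(cand, function(j) {
      pl <- ts$polyline[[j]]
      min(sqrt((pl[, 1] - mid[1])^2 + (pl[, 2] - mid[2])^2))
    }, double(1))
    j <- cand[which.min(dmin)]
    if (min(dmin) > tol) next
    seg_rows[[length(seg_rows) + 1L]] <- tibble::tibble(
      segment_id = sid, truth_key = ts$segment_key[j],
      vessel_class = cls,
      width_true = ts$width[j], width_realized = ts$width_realized[j],
      width_meas = measurements$mean_diameter[i],
      arc_true = ts$arc[j], arc_meas = measurements$arc_length[i],
      tort_true = ts$tortuosity[j], tort_meas = measurements$tortuosity[i],
      order_true = ts$vessel_order[j], order_meas = measurements$vessel_order[i],
      strahler_true = ts$strahler_order[j],
      strahler_meas = measurements$strahler_order[i],
      match_dist = min(dmin))
  }
  bif_rows <- list()
  if (!is.null(bifurcations) && nrow(bifurcations)) {
    tb <- truth$bifurcations
    for (i in seq_len(nrow(bifurcations))) {
      v <- bifurcations$node_id[i]
      nd <- graph$nodes[match(v, graph$nodes$node_id), ]
      cls <- bifurcations$vessel_class[i]
      cand <- which(tb$vessel_class == cls)
      if (!length(cand)) next
      dd <- sqrt((tb$row[cand] - nd$row)^2 + (tb$col[cand] - nd$col)^2)
      j <- cand[which.min(dd)]
      if (min(dd) > tol) next
      bif_rows[[length(bif_rows) + 1L]] <- tibble::tibble(
        node_id = v, vessel_class = cls, match_dist = min(dd),
        d0_true = tb$d0[j], d0_meas = bifurcations$d0[i],
        d1_true = tb$d1[j], d1_meas = bifurcations$d1[i],
        d2_true = tb$d2[j], d2_meas = bifurcations$d2[i],
        ba_true = tb$ba_actual[j], ba_nominal = tb$ba_nominal[j],
        ba_meas = bifurcations$ba[i], ba_edge_meas = bifurcations$ba_edge[i],
        aa_true = tb$aa[j], aa_meas = bifurcations$aa[i],
        jed_true = tb$jed[j], jed_realized = tb$jed_realized[j],
        jed_meas = bifurcations$jed[i])
    }
  }
  list(segments = dplyr::bind_rows(seg_rows),
       bifurcations = dplyr::bind_rows(bif_rows))
}
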