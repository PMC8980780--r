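#' Build the hierarchical vessel graph from segmentation maps
#'
#' Skeletonizes the union of the artery and vein masks (so that artery-vein
#' crossings appear as degree-4 nodes), splits the skeleton into segments at
#' branching and crossing points, assigns each segment a vessel class by
#' majority membership in the class masks, excludes short segments, resolves
#' crossings into vessel continuations, and assigns centrifugal vessel orders
#' and Strahler orders outward from the optic disc.
#'
#' @param maps A [seg_maps] object.
#' @param config A [vessel_config].
#' @return An object of class `vessel_graph` with elements `nodes`,
#'   `segments` (tibble with a `points` list-column), `junction_pixels`,
#'   `continuations`, `skeleton`, `disc` and `config`.
#' @export
#' @seealso [measure_segments()], [measure_bifurcations()]
build_vessel_graph <- function(maps, config = vessel_config()) {
  stopifnot(inherits(maps, "seg_maps"))
  union_mask <- fill_small_holes((maps$artery | maps$vein) * 1L)
  skel <- skeletonize(union_mask)
  topo <- skeleton_topology(skel)
  segs <- topo$segments

  if (nrow(segs)) {
    cls <- vapply(seq_len(nrow(segs)), function(i) {
      pts <- segs$points[[i]]
      a <- sum(maps$artery[pts])
      v <- sum(maps$vein[pts])
      if (a > v) "artery" else if (v > a) "vein" else "artery"
    }, character(1))
    segs$vessel_class <- cls
    segs$class_tie <- vapply(seq_len(nrow(segs)), function(i) {
      pts <- segs$points[[i]]
      sum(maps$artery[pts]) == sum(maps$vein[pts])
    }, logical(1))
  } else {
    segs$vessel_class <- character(0)
    segs$class_tie <- logical(0)
  }

  segs <- filter_short_segments(segs, config$min_segment_len)
  removed <- attr(segs, "removed")

  disc <- disc_geometry(maps$disc)
  graph <- structure(list(
    nodes = topo$nodes,
    segments = segs,
    junction_pixels = topo$junction_pixels,
    continuations = tibble::tibble(node_id = integer(), seg_a = character(),
                                   seg_b = character(), angle_deg = double()),
    skeleton = skel,
    disc = disc,
    config = config,
    source_id = maps$source_id,
    removed_segments = removed,
    orders_assigned = FALSE
  ), class = "vessel_graph")
  graph <- resolve_crossings(graph, maps)
  graph <- assign_vessel_orders(graph)
  graph <- assign_strahler(graph)
  graph
}

# Fill enclosed background components of at most `max_area` pixels.
# Pinholes where several strokes nearly meet force the skeleton into
# spurious loops; genuine enclosed regions (vessel meshes) are far larger
# and are preserved.
fill_small_holes <- function(mask, max_area = 12L) {
  bg <- EBImage::bwlabel(1 - mask)
  if (max(bg) == 0) return(mask)
  tab <- tabulate(as.integer(bg[bg > 0]))
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  fill <- setdiff(which(tab <= max_area), border)
  if (length(fill)) mask[bg %in% fill] <- 1L
  mask
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %s: %d nodes, %d segments (%d artery / %d vein)\n",
              x$source_id, nrow(x$nodes), nrow(x$segments),
              sum(x$segments$vessel_class == "artery"),
              sum(x$segments$vessel_class == "vein")))
  cat(sprintf("  disc %s, %d crossing continuations, orders %s\n",
              if (x$disc$present) sprintf("r=%.1f at (%.0f,%.0f)", x$disc$radius,
                                          x$disc$center[1], x$disc$center[2])
              else "absent",
              nrow(x$continuations),
              if (x$orders_assigned) "assigned" else "unset"))
  invisible(x)
}

#' Tidy a vessel graph into its edge list
#'
#' @param x A `vessel_graph`.
#' @param ... Unused.
#' @return Tibble with one row per segment: ids, terminal nodes, class,
#'   point count, vessel and Strahler orders, vessel path id.
#' @export
tidy.vessel_graph <- function(x, ...) {
  s <- x$segments
  tibble::tibble(segment_id = s$segment_id, node_a = s$node_a, node_b = s$node_b,
                 vessel_class = s$vessel_class, n_points = s$n_points,
                 cyclic = s$cyclic,
                 vessel_order = s$vessel_order %||% rep(NA_integer_, nrow(s)),
                 strahler_order = s$strahler_order %||% rep(NA_integer_, nrow(s)),
                 path_id = s$path_id %||% rep(NA_integer_, nrow(s)),
                 is_root = s$is_root %||% rep(FALSE, nrow(s)))
}

# Unit tangent of a segment at one of its ends, pointing away from that end
# into the segment: principal direction of `window` points starting `skip`
# points in from the end (skip jumps the junction-blob zone, and at
# bifurcations additionally the run where sibling daughters are merged,
# where the thinned centerline is not the vessel's own axis).
segment_end_tangent <- function(points, end = c("a", "b"), window = 5L,
                                skip = 0L) {
  end <- match.arg(end)
  n <- nrow(points)
  skip <- min(skip, max(0L, n - window))
  k <- min(window, n - skip)
  pts <- if (end == "a") points[skip + seq_len(k), , drop = FALSE]
         else points[n - skip + 1L - seq_len(k), , drop = FALSE]
  if (k == 1L) return(c(0, 0))
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  v <- svd(X, nu = 0, nv = 1)$v[, 1]
  # orient away from the end point (pts[1] is nearest the end in both cases)
  ref <- pts[k, ] - pts[1, ]
  if (sum(v * ref) < 0) v <- -v
  v / sqrt(sum(v^2))
}

angle_between_deg <- function(u, v) {
  cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# segment ends incident to each node: tibble(node_id, seg_idx, end)
incident_ends <- function(graph) {
  s <- graph$segments
  dplyr::bind_rows(
    tibble::tibble(node_id = s$node_a, seg_idx = seq_len(nrow(s)), end = "a"),
    tibble::tibble(node_id = s$node_b, seg_idx = seq_len(nrow(s)), end = "b")
  ) |> dplyr::filter(!is.na(.data$node_id))
}

#' Pair crossing segments into vessel continuations
#'
#' At each crossing node, incident segments of the same vessel class are
#' paired by minimal direction change (most collinear end tangents) and
#' marked as continuations of one vessel path; near-ties are broken in favor
#' of the more similar mean calibers when masks are supplied. Odd
#' leftovers stay unpaired and are flagged. Vessel path ids
#' (`segments$path_id`) merge continuation pairs so that one anatomical
#' vessel crossing another is counted once downstream.
#'
#' @param graph A `vessel_graph`.
#' @param maps Optional [seg_maps] for the caliber tie-break.
#' @return The graph with `continuations` filled and `path_id` set.
#' @export
resolve_crossings <- function(graph, maps = NULL) {
  s <- graph$segments
  n <- nrow(s)
  parent_uf <- seq_len(n)
  uf_find <- function(i) { while (parent_uf[i] != i) i <- parent_uf[i]; i }
  uf_union <- function(i, j) { parent_uf[uf_find(i)] <<- uf_find(j) }
  cont <- list()
  unpaired <- integer(0)
  win <- graph$config$tangent_window
  if (n > 0) {
    inc <- incident_ends(graph)
    rough_diam <- if (!is.null(maps)) {
      edt_a <- EBImage::distmap(maps$artery)
      edt_v <- EBImage::distmap(maps$vein)
      vapply(seq_len(n), function(i) {
        pts <- s$points[[i]]
        e <- if (s$vessel_class[i] == "artery") edt_a else edt_v
        2 * stats::median(e[pts]) - 1
      }, double(1))
    } else rep(NA_real_, n)
    cross_nodes <- graph$nodes$node_id[graph$nodes$kind == "crossing"]
    for (v in cross_nodes) {
      here <- inc[inc$node_id == v, ]
      for (cl in c("artery", "vein")) {
        sel <- here[s$vessel_class[here$seg_idx] == cl, ]
        while (nrow(sel) >= 2) {
          tangents <- lapply(seq_len(nrow(sel)), function(j) {
            segment_end_tangent(s$points[[sel$seg_idx[j]]], sel$end[j], win)
          })
          # most collinear pair: direction change closest to zero
          best <- NULL; best_score <- Inf
          for (i in seq_len(nrow(sel) - 1L)) for (j in seq(i + 1L, nrow(sel))) {
            dev <- angle_between_deg(tangents[[i]], -tangents[[j]])
            score <- dev
            if (!is.na(rough_diam[sel$seg_idx[i]])) {
              # small caliber-similarity penalty breaks near-ties
              score <- score + 0.5 * abs(rough_diam[sel$seg_idx[i]] -
                                         rough_diam[sel$seg_idx[j]])
            }
            if (score < best_score) { best_score <- score; best <- c(i, j) }
          }
          i1 <- sel$seg_idx[best[1]]; i2 <- sel$seg_idx[best[2]]
          cont[[length(cont) + 1L]] <- tibble::tibble(
            node_id = v, seg_a = s$segment_id[i1], seg_b = s$segment_id[i2],
            angle_deg = 180 - angle_between_deg(
              segment_end_tangent(s$points[[i1]], sel$end[best[1]], win),
              -segment_end_tangent(s$points[[i2]], sel$end[best[2]], win)))
          uf_union(i1, i2)
          sel <- sel[-best, ]
        }
        if (nrow(sel) == 1L) unpaired <- c(unpaired, sel$seg_idx)
      }
    }
  }
  graph$continuations <- if (length(cont)) dplyr::bind_rows(cont) else
    tibble::tibble(node_id = integer(), seg_a = character(),
                   seg_b = character(), angle_deg = double())
  roots <- vapply(seq_len(n), function(i) uf_find(i), integer(1))
  graph$segments$path_id <- if (n) match(roots, unique(roots)) else integer(0)
  graph$segments$unpaired_at_crossing <- seq_len(n) %in% unpaired
  graph
}

#' Assign centrifugal vessel orders
#'
#' Root segments are those with a centerline endpoint within
#' `root_radius_factor * disc_radius` of the disc center; they get order 1 and
#' ordering proceeds outward, incrementing at branch points. At a crossing,
#' the paired continuation keeps its order (the two passing vessels continue
#' through; crossings are not treated as branchings).
#'
#' @param graph A `vessel_graph` whose `disc` geometry is set.
#' @return The graph with `vessel_order`, `is_root` and (internally) parent
#'   links used by [assign_strahler()].
#' @export
assign_vessel_orders <- function(graph) {
  s <- graph$segments
  n <- nrow(s)
  graph$segments$vessel_order <- rep(NA_integer_, n)
  graph$segments$is_root <- rep(FALSE, n)
  graph$parent_idx <- rep(NA_integer_, n)
  if (n == 0L) { graph$orders_assigned <- FALSE; return(graph) }
  if (!isTRUE(graph$disc$present)) {
    graph$orders_assigned <- FALSE
    return(graph)
  }
  ctr <- graph$disc$center
  lim <- graph$config$root_radius_factor * graph$disc$radius
  end_dist <- function(i) {
    pts <- s$points[[i]]
    d1 <- sqrt(sum((pts[1, ] - ctr)^2)); d2 <- sqrt(sum((pts[nrow(pts), ] - ctr)^2))
    c(d1, d2)
  }
  dists <- t(vapply(seq_len(n), end_dist, double(2)))
  is_root <- pmin(dists[, 1], dists[, 2]) <= lim & !s$cyclic
  graph$segments$is_root <- is_root

  # continuation lookup: node -> partner segment index
  cont_key <- paste(graph$continuations$node_id,
                    graph$continuations$seg_a, graph$continuations$seg_b)
  partner_of <- function(node, idx) {
    id <- s$segment_id[idx]
    hit <- graph$continuations$node_id == node &
      (graph$continuations$seg_a == id | graph$continuations$seg_b == id)
    if (!any(hit)) return(NA_integer_)
    other <- ifelse(graph$continuations$seg_a[hit][1] == id,
                    graph$continuations$seg_b[hit][1],
                    graph$continuations$seg_a[hit][1])
    match(other, s$segment_id)
  }

  inc <- incident_ends(graph)
  order_vec <- rep(NA_integer_, n)
  kind_of <- function(node) graph$nodes$kind[match(node, graph$nodes$node_id)]
  queue <- list()
  root_idx <- order(dists[cbind(seq_len(n), ifelse(dists[, 1] <= dists[, 2], 1L, 2L))])
  root_idx <- root_idx[is_root[root_idx]]
  for (i in root_idx) {
    if (!is.na(order_vec[i])) next
    order_vec[i] <- 1L
    far_node <- if (dists[i, 1] <= dists[i, 2]) s$node_b[i] else s$node_a[i]
    near_node <- if (dists[i, 1] <= dists[i, 2]) s$node_a[i] else s$node_b[i]
    queue[[length(queue) + 1L]] <- list(idx = i, far = far_node)
    while (length(queue)) {
      item <- queue[[1L]]; queue <- queue[-1L]
      e <- item$idx; v <- item$far
      if (is.na(v)) next
      here <- inc[inc$node_id == v & inc$seg_idx != e, ]
      for (jj in seq_len(nrow(here))) {
        f <- here$seg_idx[jj]
        if (!is.na(order_vec[f])) next
        if (s$vessel_class[f] != s$vessel_class[e]) next
        vk <- kind_of(v)
        inc_order <- if (identical(vk, "crossing")) {
          p <- partner_of(v, e)
          if (!is.na(p) && p == f) 0L else 1L
        } else if (identical(vk, "link")) 0L else 1L
        order_vec[f] <- order_vec[e] + inc_order
        graph$parent_idx[f] <- e
        other_node <- if (here$end[jj] == "a") s$node_b[f] else s$node_a[f]
        queue[[length(queue) + 1L]] <- list(idx = f, far = other_node)
      }
    }
  }
  graph$segments$vessel_order <- order_vec
  graph$orders_assigned <- TRUE
  graph
}

#' Assign Strahler orders
#'
#' Bottom-up on the rooted orientation produced by [assign_vessel_orders()]:
#' a segment with no children has order 1; a segment whose children's maximal
#' order k is attained at least twice at a branch point gets k + 1, otherwise
#' k. Crossing nodes never increment (a vessel passing another continues, it
#' does not branch). Components without a root keep `NA` orders.
#'
#' @param graph A `vessel_graph` with vessel orders assigned.
#' @return The graph with `strahler_order` per segment.
#' @export
assign_strahler <- function(graph) {
  s <- graph$segments
  n <- nrow(s)
  graph$segments$strahler_order <- rep(NA_integer_, n)
  if (n == 0L || !isTRUE(graph$orders_assigned)) {
    if (n > 0L && !isTRUE(graph$orders_assigned)) {
      rlang::warn("Strahler orders unset: graph has no rooted components",
                  class = "vesselmetrics_unrooted")
    }
    return(graph)
  }
  parent <- graph$parent_idx
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(parent[i])) children[[parent[i]]] <- c(children[[parent[i]]], i)
  }
  kind_of <- function(node) graph$nodes$kind[match(node, graph$nodes$node_id)]
  strahler <- rep(NA_integer_, n)
  # process in order of decreasing vessel order: children are always deeper
  ord <- order(-(graph$segments$vessel_order %||% rep(1L, n)), na.last = TRUE)
  for (i in ord) {
    if (is.na(graph$segments$vessel_order[i])) next
    kids <- children[[i]]
    kids <- kids[!is.na(strahler[kids])]
    if (!length(kids)) { strahler[i] <- 1L; next }
    ks <- strahler[kids]
    m <- max(ks)
    # node where the children attach: the child's end shared with i
    attach_node <- intersect(c(s$node_a[kids[1]], s$node_b[kids[1]]),
                             c(s$node_a[i], s$node_b[i]))
    vk <- if (length(attach_node)) kind_of(attach_node[1]) else "branch"
    strahler[i] <- if (sum(ks == m) >= 2L && !identical(vk, "crossing")) m + 1L else m
  }
  graph$segments$strahler_order <- strahler
  graph
}
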