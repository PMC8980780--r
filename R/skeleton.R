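#' Skeletonize a binary mask
#'
#' Morphological thinning (Zhang-Suen two-subiteration algorithm) to a
#' one-pixel-wide, 8-connected medial skeleton. Connectivity of the input is
#' preserved; an empty mask yields an empty skeleton.
#'
#' @param mask Binary matrix.
#' @return Binary matrix of the same shape containing the skeleton.
#' @export
#' @examples
#' m <- matrix(0L, 11, 20); m[4:8, 3:18] <- 1L
#' sum(skeletonize(m))  # a single-pixel-wide line
skeletonize <- function(mask) {
  m <- as_binary_matrix(mask, "mask")
  if (sum(m) == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  NP <- nr + 2L
  P <- matrix(FALSE, NP, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- m == 1L
  # neighbours in Zhang-Suen ring order p2..p9 = N, NE, E, SE, S, SW, W, NW
  ring <- c(-1L, NP - 1L, NP, NP + 1L, 1L, 1L - NP, -NP, -NP - 1L)
  idx <- which(P)
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      if (!length(idx)) break
      nb <- vapply(ring, function(o) P[idx + o], logical(length(idx)))
      if (is.null(dim(nb))) nb <- matrix(nb, nrow = 1L)
      B <- rowSums(nb)
      nbw <- cbind(nb, nb[, 1L])
      A <- rowSums((!nbw[, 1:8, drop = FALSE]) & nbw[, 2:9, drop = FALSE])
      p2 <- nb[, 1L]; p4 <- nb[, 3L]; p6 <- nb[, 5L]; p8 <- nb[, 7L]
      del <- if (pass == 1L) {
        B >= 2 & B <= 6 & A == 1 & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        B >= 2 & B <= 6 & A == 1 & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(del)) {
        P[idx[del]] <- FALSE
        idx <- idx[!del]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  matrix(as.integer(P[2:(nr + 1L), 2:(nc + 1L)]), nr, nc)
}

# out[i, j] = M[i + dr, j + dc]; cells shifted in from outside are FALSE.
# M is assumed padded so only interior values matter.
shift_mat <- function(M, dr, dc) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(FALSE, nr, nc)
  ri <- max(1L, 1L - dr):min(nr, nr - dr)
  ci <- max(1L, 1L - dc):min(nc, nc - dc)
  out[ri, ci] <- M[ri + dr, ci + dc]
  out
}

# Full topology extraction from a skeleton: junction clustering, segment
# tracing, endpoint nodes. Internal workhorse behind classify_nodes() and
# extract_segments().
#
# Pixel classification uses the transition (crossing) number around the
# 8-neighbour ring rather than the raw neighbour count: a diagonal staircase
# pixel can have 3 neighbours yet is an ordinary path pixel (two of its
# neighbours are mutually adjacent). Transitions: 1 = endpoint, 2 = regular,
# >= 3 = junction.
skeleton_topology <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  NP <- nr + 2L
  P <- matrix(FALSE, NP, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- skel == 1L
  idx <- which(P)
  empty_nodes <- tibble::tibble(node_id = integer(), row = double(), col = double(),
                                kind = character(), degree = integer(),
                                n_pixels = integer())
  empty_segs <- tibble::tibble(segment_id = character(), node_a = integer(),
                               node_b = integer(), n_points = integer(),
                               cyclic = logical(), points = list())
  empty_jp <- tibble::tibble(node_id = integer(), row = integer(), col = integer())
  if (length(idx) == 0L) {
    return(list(nodes = empty_nodes, segments = empty_segs, junction_pixels = empty_jp))
  }
  # ring in clockwise order N, NE, E, SE, S, SW, W, NW (column-major offsets)
  ring <- c(-1L, NP - 1L, NP, NP + 1L, 1L, 1L - NP, -NP, -NP - 1L)
  nb <- vapply(ring, function(o) P[idx + o], logical(length(idx)))
  if (is.null(dim(nb))) nb <- matrix(nb, nrow = 1L)
  B <- rowSums(nb)
  nbw <- cbind(nb, nb[, 1L])
  trans <- rowSums((!nbw[, 1:8, drop = FALSE]) & nbw[, 2:9, drop = FALSE])
  # junction: >= 3 branches meet (transition number), or a residual thick
  # clump of the thinning: >= 4 neighbours including a run of 3 contiguous
  # ring neighbours (a 2x2 block), which the transition count misses. Plain
  # 45-degree staircases (two 2-runs) stay regular path pixels.
  nbw3 <- cbind(nb, nb[, 1:2, drop = FALSE])
  run3m <- vapply(1:8, function(k) {
    nbw3[, k] & nbw3[, k + 1L] & nbw3[, k + 2L]
  }, logical(length(idx)))
  if (is.null(dim(run3m))) run3m <- matrix(run3m, nrow = 1L)
  run3 <- rowSums(run3m) > 0
  is_junction <- trans >= 3 | (B >= 4 & run3)

  jmask <- matrix(FALSE, NP, nc + 2L)
  jmask[idx[is_junction]] <- TRUE
  segmask <- P & !jmask

  # --- cluster junction pixels (8-connected components) ---
  jidx <- idx[is_junction]
  jlab <- matrix(0L, NP, nc + 2L)
  n_clusters <- 0L
  if (length(jidx)) {
    offs8 <- ring
    for (s in jidx) {
      if (jlab[s] != 0L) next
      n_clusters <- n_clusters + 1L
      stack <- s; jlab[s] <- n_clusters
      while (length(stack)) {
        cur <- stack[[length(stack)]]; stack <- stack[-length(stack)]
        nbs <- cur + offs8
        new <- nbs[jmask[nbs] & jlab[nbs] == 0L]
        if (length(new)) { jlab[new] <- n_clusters; stack <- c(stack, new) }
      }
    }
  }

  # --- segment pixel adjacency with junction shortcut cut ---
  # A diagonal adjacency between two non-junction pixels that flank a common
  # junction pixel is a shortcut between different branches of the junction
  # and is severed (otherwise arms of an X would fuse into one segment).
  sidx <- which(segmask)
  pos <- matrix(0L, NP, nc + 2L)
  pos[sidx] <- seq_along(sidx)
  nseg <- length(sidx)
  adj <- matrix(0L, nseg, 8L)   # neighbour position per ring slot, 0 = none
  if (nseg) {
    for (k in 1:8) {
      o <- ring[k]
      tgt <- sidx + o
      ok <- segmask[tgt]
      if (k %% 2 == 0L) {       # even ring slots are diagonal moves
        # decompose the diagonal offset into its vertical and horizontal parts
        dv <- if (o %in% c(NP - 1L, -NP - 1L)) -1L else 1L
        dh <- if (o > 0L) NP else -NP
        cut <- jmask[sidx + dv] | jmask[sidx + dh]
        ok <- ok & !cut
      }
      adj[ok, k] <- pos[tgt[ok]]
    }
  }
  deg_in_seg <- rowSums(adj > 0L)

  # --- absorb orphan pixels into adjacent clusters / detect connectors ---
  cluster_pix <- split(jidx, jlab[jidx])
  seg_alive <- rep(TRUE, nseg)
  connector <- vector("list", 0L)
  if (nseg) {
    orphan <- which(deg_in_seg == 0L)
    for (p in orphan) {
      nbs <- sidx[p] + ring
      cl <- unique(jlab[nbs][jmask[nbs]])
      cl <- cl[cl > 0L]
      if (length(cl) == 0L) {
        seg_alive[p] <- FALSE                       # isolated pixel: drop
      } else if (length(cl) == 1L) {
        seg_alive[p] <- FALSE                       # spur: fold into cluster
        cluster_pix[[as.character(cl)]] <- c(cluster_pix[[as.character(cl)]], sidx[p])
      } else {
        seg_alive[p] <- FALSE                       # 1-px connector between clusters
        connector[[length(connector) + 1L]] <- list(pix = sidx[p], clusters = cl[1:2])
      }
    }
    dead <- which(!seg_alive)
    if (length(dead)) adj[adj %in% dead] <- 0L   # absorbed pixels leave the graph
  }

  # --- trace path components ---
  visited <- !seg_alive
  paths <- list()
  walk <- function(start) {
    path <- integer(0)
    cur <- start
    repeat {
      visited[cur] <<- TRUE
      path <- c(path, cur)
      nbs <- adj[cur, ]; nbs <- nbs[nbs > 0L]
      cand <- nbs[!visited[nbs]]
      if (!length(cand)) break
      if (length(cand) > 1L) {
        ax <- adj[cur, c(1L, 3L, 5L, 7L)]           # prefer axial continuation
        ax <- ax[ax > 0L]; ax <- ax[!visited[ax]]
        cur <- if (length(ax)) ax[1L] else cand[1L]
      } else cur <- cand[1L]
    }
    path
  }
  for (p in seq_len(nseg)) {
    if (nseg == 0L) break
    if (visited[p]) next
    # collect the component
    comp <- integer(0); stack <- p
    cvis <- visited
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (cvis[cur]) next
      cvis[cur] <- TRUE
      comp <- c(comp, cur)
      nbs <- adj[cur, ]; nbs <- nbs[nbs > 0L]
      stack <- c(stack, nbs[!cvis[nbs]])
    }
    term <- comp[rowSums(matrix(adj[comp, ] > 0L, nrow = length(comp))) <= 1L]
    if (length(term)) {
      start <- term[1L]
      maybe_ring <- FALSE
    } else {
      # every pixel has 2+ neighbours: either a closed ring or a thick
      # diagonal "ladder" left by thinning. Probe-walk to an extremity,
      # restore, and trace from there; ring-ness is decided afterwards.
      saved <- visited
      probe <- walk(comp[1L])
      visited <- saved
      start <- probe[length(probe)]
      maybe_ring <- TRUE
    }
    path <- walk(start)
    cyclic <- FALSE
    if (maybe_ring && length(path) == length(comp) && length(path) > 3L) {
      pa <- sidx[path[1L]]; pb <- sidx[path[length(path)]]
      dr <- abs(((pa - 1L) %% NP) - ((pb - 1L) %% NP))
      dc <- abs(((pa - 1L) %/% NP) - ((pb - 1L) %/% NP))
      cyclic <- dr <= 1L && dc <= 1L
    }
    # safety: leftovers (rare malformed components) traced separately
    while (length(left <- comp[!visited[comp]]) > 0L) {
      paths[[length(paths) + 1L]] <- list(path = path, cyclic = cyclic)
      path <- walk(left[1L]); cyclic <- FALSE
    }
    paths[[length(paths) + 1L]] <- list(path = path, cyclic = cyclic)
  }

  # --- assemble nodes ---
  lin_rc <- function(i) cbind(row = ((i - 1L) %% NP) + 1L - 1L,
                              col = ((i - 1L) %/% NP) + 1L - 1L)
  nodes <- list(); node_of_cluster <- integer(n_clusters)
  nid <- 0L
  jp_rows <- list()
  for (cl in seq_len(n_clusters)) {
    pix <- cluster_pix[[as.character(cl)]]
    rc <- lin_rc(pix)
    nid <- nid + 1L
    node_of_cluster[cl] <- nid
    nodes[[nid]] <- list(node_id = nid, row = mean(rc[, 1]), col = mean(rc[, 2]),
                         kind = "branch", degree = 0L, n_pixels = length(pix))
    jp_rows[[nid]] <- tibble::tibble(node_id = nid, row = as.integer(rc[, 1]),
                                     col = as.integer(rc[, 2]))
  }

  end_node_at <- function(pix) {
    rc <- lin_rc(pix)
    nid <<- nid + 1L
    nodes[[nid]] <<- list(node_id = nid, row = as.numeric(rc[1, 1]),
                          col = as.numeric(rc[1, 2]),
                          kind = "endpoint", degree = 1L, n_pixels = 1L)
    nid
  }
  adjacent_cluster <- function(pix) {
    cl <- jlab[pix + ring]
    cl <- cl[cl > 0L]
    if (length(cl)) node_of_cluster[cl[1L]] else NA_integer_
  }

  segs <- list()
  bump_degree <- function(id) {
    nodes[[id]]$degree <<- nodes[[id]]$degree + 1L
  }
  for (pp in paths) {
    path <- sidx[pp$path]       # positions -> padded linear indices
    rc <- lin_rc(path)
    if (pp$cyclic) {
      na_id <- NA_integer_; nb_id <- NA_integer_
    } else {
      na_id <- adjacent_cluster(path[1L])
      nb_id <- adjacent_cluster(path[length(path)])
      if (is.na(na_id)) na_id <- end_node_at(path[1L]) else bump_degree(na_id)
      if (is.na(nb_id)) nb_id <- end_node_at(path[length(path)]) else bump_degree(nb_id)
    }
    segs[[length(segs) + 1L]] <- list(node_a = na_id, node_b = nb_id,
                                      n_points = nrow(rc), cyclic = pp$cyclic,
                                      points = rc)
  }
  for (cn in connector) {
    rc <- lin_rc(cn$pix)
    a <- node_of_cluster[cn$clusters[1L]]; b <- node_of_cluster[cn$clusters[2L]]
    bump_degree(a); bump_degree(b)
    segs[[length(segs) + 1L]] <- list(node_a = a, node_b = b, n_points = 1L,
                                      cyclic = FALSE, points = rc)
  }

  # cluster kind from incident-segment degree: 3 = branch, >= 4 = crossing
  nodes_tb <- dplyr::bind_rows(lapply(nodes, tibble::as_tibble))
  if (nrow(nodes_tb)) {
    nodes_tb$kind <- ifelse(nodes_tb$kind == "endpoint", "endpoint",
                     ifelse(nodes_tb$degree >= 4L, "crossing",
                     ifelse(nodes_tb$degree == 3L, "branch", "link")))
  } else nodes_tb <- empty_nodes
  segs_tb <- if (length(segs)) {
    tibble::tibble(
      segment_id = sprintf("s%03d", seq_along(segs)),
      node_a = vapply(segs, function(s) s$node_a, integer(1)),
      node_b = vapply(segs, function(s) s$node_b, integer(1)),
      n_points = vapply(segs, function(s) s$n_points, integer(1)),
      cyclic = vapply(segs, function(s) s$cyclic, logical(1)),
      points = lapply(segs, function(s) s$points)
    )
  } else empty_segs
  jp <- if (length(jp_rows)) dplyr::bind_rows(jp_rows) else empty_jp
  list(nodes = nodes_tb, segments = segs_tb, junction_pixels = jp)
}

#' Classify skeleton pixels into endpoint, branch and crossing nodes
#'
#' Junction pixels (transition number of the 8-neighbour ring at least 3) are
#' merged into clusters by 8-connectivity; each cluster becomes one node at
#' its centroid, with kind assigned from the number of incident segments
#' (3 = branch, 4 or more = crossing). Skeleton endpoints become degree-1
#' endpoint nodes.
#'
#' @param skeleton Binary skeleton matrix (see [skeletonize()]).
#' @return A tibble with columns `node_id`, `row`, `col`, `kind`, `degree`,
#'   `n_pixels`.
#' @export
classify_nodes <- function(skeleton) {
  skeleton_topology(skeleton)$nodes
}

#' Split a skeleton into vessel segments at its junctions
#'
#' Every maximal skeleton path between two nodes becomes one segment with an
#' ordered centerline; each skeleton pixel belongs to exactly one segment or
#' one junction cluster. Closed rings with no junction become a single
#' segment flagged `cyclic`.
#'
#' @param skeleton Binary skeleton matrix.
#' @param vessel_class Class label attached to all segments ("artery" or
#'   "vein").
#' @return A tibble of segments with a `points` list-column of ordered
#'   `(row, col)` centerline coordinates.
#' @export
extract_segments <- function(skeleton, vessel_class = "artery") {
  segs <- skeleton_topology(skeleton)$segments
  segs$vessel_class <- rep(vessel_class, nrow(segs))
  segs
}

#' Exclude short vessel segments
#'
#' Segments whose centerline has fewer than `min_len` points are excluded
#' from analysis (length is counted in centerline points, matching a
#' pixel-count reading of the threshold). The ids of removed segments are
#' kept in the `"removed"` attribute.
#'
#' @param segments Segment tibble from [extract_segments()].
#' @param min_len Minimum number of centerline points; default 10, i.e.
#'   segments shorter than 10 pixels are dropped and 10-point segments kept.
#' @return Filtered segment tibble.
#' @export
filter_short_segments <- function(segments, min_len = 10L) {
  keep <- segments$n_points >= min_len
  out <- segments[keep, , drop = FALSE]
  attr(out, "removed") <- segments$segment_id[!keep]
  out
}
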