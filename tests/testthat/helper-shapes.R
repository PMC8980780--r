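# Shared fixtures: all raster inputs are built in code.

# stamp a straight stroke of a given width between two (row, col) points
draw_stroke <- function(canvas, p0, p1, width = 3) {
  len <- sqrt(sum((p1 - p0)^2))
  t <- seq(0, 1, length.out = max(2L, ceiling(len / 0.25)))
  rad <- max(0, width / 2 - 1e-6)
  R <- ceiling(rad)
  offs <- as.matrix(expand.grid(dr = -R:R, dc = -R:R))
  offs <- offs[offs[, 1]^2 + offs[, 2]^2 <= rad^2 + 1e-9, , drop = FALSE]
  side <- nrow(canvas)
  pts <- cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]))
  lin <- (round(pts[, 2]) - 1L) * side + round(pts[, 1])
  canvas[outer(lin, offs[, 2] * side + offs[, 1], "+")] <- 1L
  canvas
}

filled_circle <- function(side, center, radius) {
  rows <- matrix(seq_len(side), side, side)
  cols <- matrix(seq_len(side), side, side, byrow = TRUE)
  matrix(as.integer((rows - center[1])^2 + (cols - center[2])^2 <= radius^2),
         side, side)
}

y_mask <- function(side = 64, width = 3) {
  m <- matrix(0L, side, side)
  m <- draw_stroke(m, c(55, 32), c(35, 32), width)
  m <- draw_stroke(m, c(35, 32), c(15, 18), width)
  draw_stroke(m, c(35, 32), c(15, 46), width)
}

x_mask <- function(side = 64, width = 3) {
  m <- matrix(0L, side, side)
  m <- draw_stroke(m, c(10, 10), c(54, 54), width)
  draw_stroke(m, c(54, 10), c(10, 54), width)
}

plus_mask <- function(side = 64, width = 3) {
  m <- matrix(0L, side, side)
  m <- draw_stroke(m, c(32, 5), c(32, 60), width)
  draw_stroke(m, c(5, 32), c(60, 32), width)
}

ring_mask <- function(side = 64, radius = 20, width = 3) {
  m <- matrix(0L, side, side)
  th <- seq(0, 2 * pi, length.out = 900)
  pts <- cbind(side / 2 + radius * cos(th), side / 2 + radius * sin(th))
  rad <- max(0, width / 2 - 1e-6)
  R <- ceiling(rad)
  offs <- as.matrix(expand.grid(dr = -R:R, dc = -R:R))
  offs <- offs[offs[, 1]^2 + offs[, 2]^2 <= rad^2 + 1e-9, , drop = FALSE]
  lin <- (round(pts[, 2]) - 1L) * side + round(pts[, 1])
  m[outer(lin, offs[, 2] * side + offs[, 1], "+")] <- 1L
  m
}

# independent Strahler oracle: literal post-order recursion on an edge list
# (parent_key -> child_key), nothing shared with the package implementation
oracle_strahler <- function(keys, edges) {
  children <- lapply(keys, function(k) edges$child_key[edges$parent_key == k])
  names(children) <- keys
  rec <- function(k) {
    ch <- children[[k]]
    if (length(ch) == 0L) return(1L)
    vals <- vapply(ch, rec, integer(1))
    top <- max(vals)
    if (sum(vals == top) >= 2L) top + 1L else top
  }
  vapply(keys, rec, integer(1))
}

# independent AUC oracle: enumerate all positive-negative pairs
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  cmp <- outer(pos, neg, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# independent revised-pairing oracle, coded as explicit recursion
oracle_knudtson <- function(w, const) {
  if (length(w) == 1L) return(w)
  w <- sort(w)
  n <- length(w)
  if (n %% 2L == 0L) {
    nxt <- const * sqrt(w[1:(n / 2)]^2 + rev(w)[1:(n / 2)]^2)
  } else {
    mid <- w[(n + 1L) / 2L]
    lo <- w[seq_len((n - 1L) / 2L)]
    hi <- rev(w)[seq_len((n - 1L) / 2L)]
    nxt <- c(const * sqrt(lo^2 + hi^2), mid)
  }
  oracle_knudtson(nxt, const)
}

# small synthetic eye for pipeline-level tests (fast to measure)
small_eye_spec <- function(seed, root_width = 7, n_levels = 3, ...) {
  synth_tree_spec(n_levels = n_levels, root_width = root_width,
                  image_side = 320, disc_radius = 28, seed = seed, ...)
}
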