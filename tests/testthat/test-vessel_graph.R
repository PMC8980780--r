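test_that("skeletonize thins to one pixel and preserves topology", {
  bar <- matrix(0L, 15, 40); bar[6:10, 3:38] <- 1L
  sk <- skeletonize(bar)
  rows_used <- unique(which(sk == 1L, arr.ind = TRUE)[, 1])
  expect_length(rows_used, 1L)
  expect_identical(skeletonize(matrix(0L, 8, 8)), matrix(0L, 8, 8))
  nodes <- classify_nodes(skeletonize(y_mask()))
  expect_identical(sum(nodes$kind == "branch"), 1L)
  expect_identical(sum(nodes$kind == "endpoint"), 3L)
})

test_that("node classification separates endpoints, branches and crossings", {
  line <- matrix(0L, 30, 30); line[15, 5:24] <- 1L
  nl <- classify_nodes(line)
  expect_identical(sort(nl$kind), c("endpoint", "endpoint"))

  nx <- classify_nodes(skeletonize(x_mask()))
  expect_identical(sum(nx$kind == "crossing"), 1L)
  expect_identical(sum(nx$kind == "endpoint"), 4L)
  np <- classify_nodes(skeletonize(plus_mask()))
  expect_identical(sum(np$kind == "crossing"), 1L)
})

test_that("segment extraction splits at junctions and conserves pixels", {
  expect_identical(nrow(extract_segments(skeletonize(y_mask()))), 3L)
  expect_identical(nrow(extract_segments(skeletonize(x_mask()))), 4L)

  ring <- skeletonize(ring_mask())
  segs <- extract_segments(ring)
  expect_identical(nrow(segs), 1L)
  expect_true(segs$cyclic[1])

  for (shape in list(y_mask(), x_mask(), plus_mask(), ring_mask())) {
    sk <- skeletonize(shape)
    topo <- vesselmetrics:::skeleton_topology(sk)
    expect_identical(sum(sk),
                     sum(topo$segments$n_points) + nrow(topo$junction_pixels))
  }
})

test_that("short segments are excluded at the 10-point boundary", {
  seg <- function(n) tibble::tibble(segment_id = paste0("s", n),
                                    node_a = 1L, node_b = 2L, n_points = n,
                                    cyclic = FALSE, points = list(cbind(1, seq_len(n))))
  segs <- dplyr::bind_rows(lapply(c(3L, 9L, 10L, 25L), seg))
  kept <- filter_short_segments(segs, 10L)
  expect_identical(kept$n_points, c(10L, 25L))
  expect_identical(attr(kept, "removed"), c("s3", "s9"))
  empty <- filter_short_segments(segs[0, ], 10L)
  expect_identical(nrow(empty), 0L)
})

test_that("vessel and Strahler orders match the truth on clean trees", {
  # opposite-side single trunks: no artery-vein overlap, exact recovery
  spec <- synth_tree_spec(n_levels = 3, n_trunks = 1, tortuosity_amp = 0,
                          image_side = 384, disc_radius = 32, seed = 11)
  g <- generate_tree(spec)
  expect_identical(sum(g$maps$artery & g$maps$vein), 0L)
  rec <- measure_fundus(g$maps)
  mt <- match_truth(g$truth, rec$graph, rec$segments)
  expect_identical(nrow(mt$segments), nrow(g$truth$segments))
  expect_identical(mt$segments$order_meas, mt$segments$order_true)
  expect_identical(mt$segments$strahler_meas, mt$segments$strahler_true)
  # and the truth table itself agrees with an independent recursion
  oracle <- oracle_strahler(g$truth$segments$segment_key, g$truth$edges)
  expect_identical(unname(oracle), g$truth$segments$strahler_order)
})

test_that("crossing resolution pairs collinear same-class halves", {
  side <- 96
  art <- matrix(0L, side, side)
  art <- draw_stroke(art, c(14, 14), c(82, 82), 5)
  vein <- matrix(0L, side, side)
  vein <- draw_stroke(vein, c(82, 14), c(14, 82), 5)
  disc <- filled_circle(side, c(14, 14), 6)
  maps <- seg_maps(art, vein, disc)
  graph <- build_vessel_graph(maps, vessel_config(min_segment_len = 5))
  cont <- graph$continuations
  expect_identical(nrow(cont), 2L)   # one artery pairing + one vein pairing
  cls_of <- function(id) graph$segments$vessel_class[
    match(id, graph$segments$segment_id)]
  expect_identical(cls_of(cont$seg_a), cls_of(cont$seg_b))
  # straight vessels continue almost straight through the crossing
  expect_true(all(cont$angle_deg > 160))
  # continuation merging: each class is one vessel path
  paths <- split(graph$segments$path_id, graph$segments$vessel_class)
  expect_identical(length(unique(paths$artery)), 1L)
  expect_identical(length(unique(paths$vein)), 1L)
})

test_that("orders are invariant under 90-degree rotation", {
  spec <- synth_tree_spec(n_levels = 3, n_trunks = 1, tortuosity_amp = 0,
                          image_side = 384, disc_radius = 32, seed = 5)
  g <- generate_tree(spec)
  rot <- function(m) t(m)[, nrow(m):1]
  maps_r <- seg_maps(rot(g$maps$artery), rot(g$maps$vein), rot(g$maps$disc))
  g1 <- build_vessel_graph(g$maps)
  g2 <- build_vessel_graph(maps_r)
  tab <- function(gr) table(gr$segments$vessel_class, gr$segments$vessel_order)
  expect_identical(tab(g1), tab(g2))
  expect_identical(sort(g1$segments$strahler_order),
                   sort(g2$segments$strahler_order))
})

test_that("graphs without a disc carry no orders and warn on Strahler", {
  maps <- seg_maps(y_mask(), matrix(0L, 64, 64), matrix(0L, 64, 64))
  expect_warning(g <- build_vessel_graph(maps, vessel_config(min_segment_len = 5)),
                 class = "vesselmetrics_unrooted")
  expect_false(g$orders_assigned)
  expect_true(all(is.na(g$segments$vessel_order)))
})
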