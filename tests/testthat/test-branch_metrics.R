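# one artery bifurcation: vertical trunk, daughters at +/- half-angle
bifurcation_maps <- function(theta1 = 30, theta2 = -30, w0 = 9, w1 = 7, w2 = 7,
                             side = 160) {
  apex <- c(70, 80)
  art <- matrix(0L, side, side)
  art <- draw_stroke(art, c(125, 80), apex, w0)
  up <- c(-1, 0)  # trunk direction of travel (toward decreasing row)
  for (k in 1:2) {
    th <- (if (k == 1) theta1 else theta2) * pi / 180
    d <- c(cos(th) * up[1] - sin(th) * up[2], sin(th) * up[1] + cos(th) * up[2])
    art <- draw_stroke(art, apex, apex + 45 * d, if (k == 1) w1 else w2)
  }
  disc <- filled_circle(side, c(133, 80), 8)
  seg_maps(art, matrix(0L, side, side), disc)
}

test_that("pure bifurcation indices follow their closed forms", {
  expect_equal(branching_coefficient(10, 10, 10), 2)
  expect_equal(branching_coefficient(10, 10 * 2^(-1 / 3), 10 * 2^(-1 / 3)),
               2^(1 / 3), tolerance = 1e-12)
  expect_equal(branching_coefficient(10, 8, 6), 1)
  expect_equal(asymmetry_ratio(10, 10), 1)
  expect_equal(asymmetry_ratio(10, 5), 0.25)
  expect_equal(asymmetry_ratio(5, 10), 0.25)     # order-agnostic
  expect_equal(angular_asymmetry(30, 30), 0)
  expect_equal(angular_asymmetry(50, 10), 40)
  expect_equal(junctional_exponent_deviation(10, 10 * 2^(-1 / 3), 10 * 2^(-1 / 3)),
               0, tolerance = 1e-12)
  expect_equal(junctional_exponent_deviation(10, 10, 10),
               (2000^(1 / 3) - 10) / 10, tolerance = 1e-12)
  expect_equal(junctional_exponent_deviation(12, 8, 6),
               (728^(1 / 3) - 12) / 12, tolerance = 1e-12)
})

test_that("bifurcations are detected at branch points only", {
  g <- generate_tree(synth_tree_spec(n_levels = 3, n_trunks = 1,
                                     tortuosity_amp = 0, image_side = 384,
                                     disc_radius = 32, seed = 2))
  rec <- measure_fundus(g$maps)
  # full binary artery tree of depth 3 has 3 internal nodes per class
  expect_identical(sum(rec$bifurcations$vessel_class == "artery"), 3L)
  expect_identical(sum(rec$bifurcations$vessel_class == "vein"), 3L)
  # the detected parent is the lower-order (trunk-side) segment
  b <- rec$bifurcations
  s <- rec$graph$segments
  ord <- function(id) s$vessel_order[match(id, s$segment_id)]
  expect_true(all(ord(b$parent) <= pmin(ord(b$daughter1), ord(b$daughter2))))

  # an X crossing yields no bifurcation
  art <- matrix(0L, 96, 96)
  art <- draw_stroke(art, c(14, 14), c(82, 82), 5)
  vein <- matrix(0L, 96, 96)
  vein <- draw_stroke(vein, c(82, 14), c(14, 82), 5)
  maps <- seg_maps(art, vein, filled_circle(96, c(14, 14), 6))
  recx <- measure_fundus(maps, vessel_config(min_segment_len = 5))
  expect_identical(nrow(recx$bifurcations), 0L)
})

test_that("branching angles recover constructed geometry", {
  cfg <- vessel_config()
  for (case in list(list(t1 = 30, t2 = -30, ba = 60),
                    list(t1 = 45, t2 = -45, ba = 90))) {
    rec <- measure_fundus(bifurcation_maps(case$t1, case$t2), cfg)
    expect_identical(nrow(rec$bifurcations), 1L)
    b <- rec$bifurcations
    expect_lt(abs(b$ba - case$ba), 2)
    expect_lt(abs(b$aa - 0), 2)
    expect_lt(abs(b$ba_edge - case$ba), 3)
  }
  rec <- measure_fundus(bifurcation_maps(50, -10))
  expect_lt(abs(rec$bifurcations$aa - 40), 3)
  expect_lt(abs(rec$bifurcations$ba - 60), 2)
})

test_that("angular asymmetry never exceeds the branching angle by more than tolerance", {
  for (seed in 1:4) {
    g <- generate_tree(small_eye_spec(seed, tortuosity_amp = 0))
    rec <- measure_fundus(g$maps)
    b <- rec$bifurcations
    expect_true(all(b$aa <= b$ba + 4))
  }
})

test_that("caliber ratios are scale-invariant at the population level", {
  # single-junction calibers carry up to one pixel of grid quantization, so
  # the dimensionless-ratio property is asserted on tree-level means
  g <- generate_tree(small_eye_spec(12, tortuosity_amp = 0))
  rec1 <- measure_fundus(g$maps)
  up <- function(x) x[rep(seq_len(nrow(x)), each = 2), rep(seq_len(ncol(x)), each = 2)]
  maps2 <- seg_maps(up(g$maps$artery), up(g$maps$vein), up(g$maps$disc))
  rec2 <- measure_fundus(maps2)
  expect_gt(nrow(rec1$bifurcations), 5)
  expect_lt(abs(mean(rec2$bifurcations$bc) / mean(rec1$bifurcations$bc) - 1), 0.05)
  expect_lt(abs(mean(rec2$bifurcations$ar) / mean(rec1$bifurcations$ar) - 1), 0.05)
})
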