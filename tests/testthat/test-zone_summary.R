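test_that("disc geometry comes from the largest component's equivalent circle", {
  d <- filled_circle(256, c(100, 100), 40)
  g <- disc_geometry(d)
  expect_true(g$present)
  expect_lt(max(abs(g$center - c(100, 100))), 1)
  expect_lt(abs(g$radius - 40), 1)
  expect_false(disc_geometry(matrix(0L, 32, 32))$present)

  two <- d
  two[200:210, 200:210] <- 1L
  g2 <- disc_geometry(two)
  expect_true(g2$multi_component)
  expect_lt(max(abs(g2$center - c(100, 100))), 1)
})

test_that("the standard zone is the exact 2r-3r annulus", {
  disc <- disc_geometry(filled_circle(512, c(256, 256), 40))
  z <- standard_zone(disc, c(512, 512))
  r <- disc$radius
  at <- function(dist) z[256 + round(dist), 256]
  expect_identical(at(100), 1L)
  expect_identical(at(79), 0L)
  expect_identical(at(121), 0L)
  # area within 1% of pi * ((3r)^2 - (2r)^2)
  expect_lt(abs(sum(z) / (pi * ((3 * r)^2 - (2 * r)^2)) - 1), 0.01)
  absent <- structure(list(present = FALSE), class = "disc_geometry")
  expect_error(standard_zone(absent, c(64, 64)),
               class = "vesselmetrics_qc_trigger")
})

test_that("zone widths pick the six largest distinct vessels", {
  side <- 400
  ctr <- c(200, 200)
  art <- matrix(0L, side, side)
  widths <- c(3, 5, 7, 9, 11, 13, 15, 17)
  angs <- seq(0, 315, by = 45) * pi / 180
  for (i in seq_along(widths)) {
    u <- c(cos(angs[i]), sin(angs[i]))
    art <- draw_stroke(art, ctr + 25 * u, ctr + 130 * u, widths[i])
  }
  maps <- seg_maps(art, matrix(0L, side, side),
                   filled_circle(side, ctr, 20))
  graph <- build_vessel_graph(maps)
  meas <- measure_segments(graph, maps)
  zone <- standard_zone(graph$disc, dim(art))
  zw <- zone_vessel_widths(graph, meas, zone, "artery")
  expect_identical(zw$count, 8L)
  expect_length(zw$widths, 6L)
  expect_identical(order(zw$widths, decreasing = TRUE), 1:6)
  # caliber errors are under a pixel, so nearest-true matching is unique
  # with the 2-px spacing: the true six widest strokes were selected
  nearest <- vapply(zw$widths, function(w) widths[which.min(abs(widths - w))],
                    double(1))
  expect_identical(nearest, c(17, 15, 13, 11, 9, 7))
})

test_that("the revised pairing reproduces hand-iterated equivalents", {
  expect_equal(knudtson_equivalent(c(10, 10), "artery"), 0.88 * sqrt(200),
               tolerance = 1e-12)
  # hand iteration for six equal widths, to four decimals
  expect_equal(round(knudtson_equivalent(rep(10, 6), "artery"), 4), 17.4843)
  expect_equal(round(knudtson_equivalent(rep(10, 6), "vein"), 4), 21.3761)
  # a single width passes through unchanged: the constant is per pairing
  expect_identical(knudtson_equivalent(12.3, "artery"), 12.3)
  expect_warning(out <- knudtson_equivalent(numeric(0), "artery"),
                 class = "vesselmetrics_undefined_measure")
  expect_true(is.na(out))
  expect_error(knudtson_equivalent(c(3, -1), "vein"),
               class = "vesselmetrics_contract_error")
})

test_that("the pairing is permutation-invariant and strictly monotone", {
  withr::with_seed(99, {
    for (i in 1:50) {
      w <- runif(sample(1:6, 1), 3, 20)
      base <- knudtson_equivalent(w, "artery")
      expect_equal(knudtson_equivalent(w[sample.int(length(w))], "artery"),
                   base, tolerance = 1e-12)
      j <- sample(length(w), 1)
      w2 <- w; w2[j] <- w2[j] + 0.5
      expect_gt(knudtson_equivalent(w2, "artery"), base)
    }
  })
})

test_that("AVRe divides the equivalents and flags undefined input", {
  expect_equal(avre(15, 15), 1)
  expect_equal(avre(17.4843, 21.3761), 0.8179, tolerance = 1e-4)
  expect_warning(out <- avre(15, NA), class = "vesselmetrics_undefined_measure")
  expect_true(is.na(out))
})

test_that("zone equivalents are stable under 2x upscaling (ratio robustness)", {
  g <- generate_tree(synth_tree_spec(seed = 3))
  rec1 <- measure_fundus(g$maps)
  up <- function(m) m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2)]
  maps2 <- seg_maps(up(g$maps$artery), up(g$maps$vein), up(g$maps$disc))
  rec2 <- measure_fundus(maps2)
  expect_lt(abs(rec2$zone$avre / rec1$zone$avre - 1), 0.02)
})

test_that("whole-fundus summaries average and length-weight the segments", {
  meas <- tibble::tibble(
    vessel_class = c("artery", "artery"), mean_diameter = c(10, 20),
    arc_length = c(10, 30), chord_length = c(10, 30),
    ldr = c(1, 1.5), tortuosity = c(1, 1))
  g <- global_summary(meas)
  ga <- g[g$vessel_class == "artery", ]
  expect_equal(ga$weighted_diameter, 17.5)
  expect_equal(ga$mean_diameter, 15)
  gv <- g[g$vessel_class == "vein", ]
  expect_identical(gv$n_segments, 0L)
  expect_true(is.na(gv$weighted_diameter))

  single <- global_summary(meas[1, ])
  sa <- single[single$vessel_class == "artery", ]
  expect_equal(sa$weighted_diameter, sa$mean_diameter)
})

test_that("box-counting dimension separates lines from filled regions", {
  line <- matrix(0L, 256, 256); line[128, ] <- 1L
  expect_lt(abs(fractal_dimension(line) - 1), 0.1)
  full <- matrix(1L, 256, 256)
  expect_lt(abs(fractal_dimension(full) - 2), 0.1)
  expect_true(is.na(fractal_dimension(matrix(0L, 64, 64))))
})
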