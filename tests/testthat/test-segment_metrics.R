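test_that("diameter profiles recover stroke widths from the distance transform", {
  m <- matrix(0L, 11, 30); m[4:8, 2:29] <- 1L         # width-5 slab
  pts <- cbind(row = rep(6L, 20), col = 6:25)
  prof <- profile_diameters(pts, m)
  expect_true(all(prof$diameter == 5))
  expect_true(all(prof$valid))

  thin <- matrix(0L, 9, 30); thin[5, 2:29] <- 1L      # width-1 line
  p1 <- profile_diameters(cbind(row = rep(5L, 10), col = 8:17), thin)
  expect_true(all(p1$diameter == 1))

  expect_error(profile_diameters(cbind(row = 1L, col = 1L), m),
               class = "vesselmetrics_contract_error")

  excl <- profile_diameters(pts, m, junction_exclude = c(3L, 2L))
  expect_identical(which(!excl$valid), c(1:3, 19:20))
})

test_that("arc and chord lengths follow step geometry and analytic curves", {
  expect_equal(arc_length(cbind(1, 1:11)), 10)
  expect_equal(arc_length(cbind(1:11, 1:11)), 10 * sqrt(2))
  expect_equal(chord_length(cbind(1, 1:11)), 10)

  th <- seq(0, pi, length.out = 400)
  semi <- cbind(60 + 50 * sin(th), 60 + 50 * cos(th))
  expect_lt(abs(arc_length(semi) / (50 * pi) - 1), 0.02)
  expect_lt(abs(chord_length(semi) / 100 - 1), 0.02)
})

test_that("tortuosity is arc over chord with analytic values on arcs", {
  expect_equal(tortuosity(cbind(5, 1:50)), 1)
  th <- seq(0, pi, length.out = 400)
  semi <- cbind(50 * sin(th), 50 * cos(th))
  expect_lt(abs(tortuosity(semi) / (pi / 2) - 1), 0.02)
  quarter <- cbind(50 * sin(th[1:200]), 50 * cos(th[1:200]))
  expect_lt(abs(tortuosity(quarter) / ((pi / 2) / sqrt(2)) - 1), 0.02)
  loop <- rbind(cbind(1, 1:10), cbind(2, 10:1), c(1, 1))
  expect_warning(val <- tortuosity(loop),
                 class = "vesselmetrics_undefined_measure")
  expect_true(is.na(val))
})

test_that("LDR is scale-invariant arc per caliber", {
  expect_equal(ldr(100, 10), 10)
  expect_equal(ldr(57, 5.7), 10)
  # synthetic straight bar 80 x 5: LDR near 80/5 (discretization < 10%)
  m <- matrix(0L, 15, 90); m[6:10, 5:84] <- 1L
  sk <- skeletonize(m)
  segs <- extract_segments(sk)
  pts <- segs$points[[1]]
  prof <- profile_diameters(pts, m)
  expect_lt(abs(ldr(arc_length(pts), mean(prof$diameter)) / (80 / 5) - 1), 0.10)
})

test_that("measurements scale with the mask and survive rotation", {
  side <- 160
  m <- matrix(0L, side, side)
  th <- seq(0, pi / 2, length.out = 500)
  pts <- cbind(120 - 80 * sin(th), 30 + 80 * (1 - cos(th)))  # quarter arc
  for (i in seq_len(nrow(pts))) {
    m <- draw_stroke(m, pts[i, ], pts[i, ], 5)
  }
  measure_one <- function(mask) {
    sk <- skeletonize(mask)
    seg <- extract_segments(sk)
    seg <- seg[which.max(seg$n_points), ]
    p <- seg$points[[1]]
    prof <- profile_diameters(p, mask)
    list(arc = arc_length(p), chord = chord_length(p),
         d = mean(prof$diameter), tort = tortuosity(p))
  }
  a <- measure_one(m)
  up <- m[rep(seq_len(side), each = 2), rep(seq_len(side), each = 2)]
  b <- measure_one(up)
  expect_lt(abs(b$arc / a$arc - 2), 0.1)
  expect_lt(abs(b$chord / a$chord - 2), 0.1)
  expect_lt(abs(b$d / a$d - 2), 0.1)
  expect_lt(abs(b$tort / a$tort - 1), 0.05)

  # rotation by 90 degrees leaves a straight tilted bar unchanged
  bar <- matrix(0L, side, side)
  bar <- draw_stroke(bar, c(30, 40), c(120, 100), 5)
  ab <- measure_one(bar)
  rb <- measure_one(t(bar)[, side:1])
  expect_lt(abs(rb$arc / ab$arc - 1), 0.01)
  expect_lt(abs(rb$d / ab$d - 1), 0.01)
})

test_that("tortuosity never drops below 1 on traced segments", {
  for (seed in 1:5) {
    g <- generate_tree(small_eye_spec(seed, tortuosity_amp = 1.2))
    rec <- measure_fundus(g$maps)
    expect_true(all(rec$segments$tortuosity >= 1 - 1e-9, na.rm = TRUE))
  }
})
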