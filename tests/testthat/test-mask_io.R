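test_that("seg_maps enforces co-registration and binarity", {
  m64 <- matrix(0L, 64, 64)
  maps <- seg_maps(m64, m64, m64)
  expect_identical(dim(maps$artery), c(64L, 64L))
  expect_true(all(maps$fov == 1L))
  expect_identical(maps$quality_grade, "unknown")
  expect_error(seg_maps(m64, matrix(0L, 32, 32), m64),
               class = "vesselmetrics_shape_error")
  soft <- matrix(runif(64 * 64), 64, 64)
  expect_true(all(seg_maps(soft, m64, m64)$artery %in% c(0L, 1L)))
})

test_that("mask files round-trip bit-exactly and indexed maps decode by color", {
  dir <- withr::local_tempdir()
  a <- y_mask(); v <- x_mask(); d <- filled_circle(64, c(20, 20), 6)
  maps <- seg_maps(a, v, d, source_id = "rt")
  save_segmentation_maps(maps, dir)
  rt <- load_segmentation_maps(artery = file.path(dir, "rt_artery.png"),
                               vein = file.path(dir, "rt_vein.png"),
                               disc = file.path(dir, "rt_disc.png"))
  expect_identical(rt$artery, a)
  expect_identical(rt$vein, v)
  expect_identical(rt$disc, d)

  # indexed color map: artery red, vein blue, disc yellow (disjoint classes)
  img <- array(0, c(64, 64, 3))
  img[, , 1][a == 1 & d == 0] <- 1                           # red
  img[, , 3][v == 1 & a == 0 & d == 0] <- 1                  # blue
  img[, , 1][d == 1] <- 1; img[, , 2][d == 1] <- 1           # yellow
  idx_path <- file.path(dir, "indexed.png")
  png::writePNG(img, idx_path)
  im <- load_segmentation_maps(indexed = idx_path)
  expect_identical(sum(im$disc), sum(d))
  expect_identical(sum(im$vein), sum(v == 1 & a == 0 & d == 0))
  expect_identical(sum(im$artery), sum(a == 1 & d == 0))
  # a color outside the palette triggers a palette error
  img[, , 2][1:10, 1:10] <- 1; img[, , 1][1:10, 1:10] <- 0
  png::writePNG(img, idx_path)
  expect_error(load_segmentation_maps(indexed = idx_path),
               class = "vesselmetrics_palette_error")
})

test_that("preprocess crops to the FOV and resizes with masks kept binary", {
  m <- matrix(0L, 64, 64); m[20:40, 20:40] <- 1L
  out <- preprocess_maps(seg_maps(m, m, m), target_side = 512)
  expect_identical(dim(out$artery), c(512L, 512L))
  expect_true(all(out$artery %in% c(0L, 1L)))

  # already conformant input is untouched (preprocessing is idempotent)
  a512 <- matrix(0L, 512, 512); a512[100:150, 200:230] <- 1L
  maps <- seg_maps(a512, a512, a512)
  once <- preprocess_maps(maps, 512)
  expect_identical(once$artery, a512)
  expect_identical(preprocess_maps(once, 512)$artery, once$artery)

  # 2x downscale of a centered full-frame circular FOV quarters the area
  big <- matrix(0L, 1024, 1024)
  big[300:700, 300:700] <- 1L
  fov <- filled_circle(1024, c(512, 512), 512)
  down <- preprocess_maps(seg_maps(big, big, big, fov), 512)
  expect_lt(abs(sum(down$artery) / sum(big) - 0.25), 0.05 * 0.25)

  empty_fov <- matrix(0L, 8, 8)
  expect_error(seg_maps(m[1:8, 1:8], m[1:8, 1:8], m[1:8, 1:8], empty_fov),
               class = "vesselmetrics_degenerate_input")
})

test_that("overlay colors encode agreement and conserve pixel counts", {
  ref <- matrix(0L, 16, 16); ref[8, 3:12] <- 1L
  ov_same <- render_overlay(ref, ref)
  expect_equal(sum(ov_same[, , 2]), sum(ref))   # all green
  expect_equal(sum(ov_same[, , 1]), 0)          # no red
  expect_equal(sum(ov_same[, , 3]), 0)          # no blue

  none <- matrix(0L, 16, 16)
  ov_miss <- render_overlay(none, ref)
  expect_equal(sum(ov_miss[, , 3]), sum(ref))   # k blue pixels

  pred <- matrix(0L, 16, 16); pred[2, 1:5] <- 1L    # disjoint from ref
  ov <- render_overlay(pred, ref)
  expect_equal(sum(ov[, , 1]), sum(pred))
  expect_equal(sum(ov[, , 3]), sum(ref))
  # green + blue = |reference|, green + red = |predicted|
  expect_equal(sum(ov[, , 2]) + sum(ov[, , 3]), sum(ref))
  expect_equal(sum(ov[, , 2]) + sum(ov[, , 1]), sum(pred))
  expect_error(render_overlay(pred, matrix(0L, 8, 8)),
               class = "vesselmetrics_shape_error")
})
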