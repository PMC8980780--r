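#' Segmentation map bundle
#'
#' Bundles co-registered binary artery, vein and optic-disc masks (plus a
#' field-of-view mask) on one pixel grid. This is the sole required input of
#' the measurement pipeline. Coordinates are 1-based `(row, col)` with pixel
#' centers at integer positions.
#'
#' @param artery,vein,disc Binary matrices (0/1, logical, or numeric in
#'   \[0,1\] which is thresholded at 0.5) of identical shape.
#' @param fov Optional binary matrix marking the valid (illuminated) field of
#'   view. Defaults to all ones, so bare masks are analyzable.
#' @param source_id Identifier carried through to all outputs.
#' @param quality_grade Optional photographic quality label passed through as
#'   metadata: one of `"good"`, `"usable"`, `"reject"`, `"unknown"`.
#'
#' @return An object of class `seg_maps`.
#' @export
#' @examples
#' m <- matrix(0L, 32, 32)
#' maps <- seg_maps(artery = m, vein = m, disc = m)
#' dim(maps$artery)
seg_maps <- function(artery, vein, disc, fov = NULL,
                     source_id = "image", quality_grade = "unknown") {
  artery <- as_binary_matrix(artery, "artery")
  vein   <- as_binary_matrix(vein, "vein")
  disc   <- as_binary_matrix(disc, "disc")
  if (!identical(dim(artery), dim(vein)) || !identical(dim(artery), dim(disc))) {
    rlang::abort("artery, vein and disc masks must share one shape",
                 class = "vesselmetrics_shape_error")
  }
  if (is.null(fov)) {
    fov <- matrix(1L, nrow(artery), ncol(artery))
  } else {
    fov <- as_binary_matrix(fov, "fov")
    if (!identical(dim(fov), dim(artery))) {
      rlang::abort("fov mask shape differs from the vessel masks",
                   class = "vesselmetrics_shape_error")
    }
  }
  if (sum(fov) == 0L) {
    rlang::abort("field of view is empty", class = "vesselmetrics_degenerate_input")
  }
  quality_grade <- match.arg(quality_grade, c("unknown", "good", "usable", "reject"))
  structure(list(artery = artery, vein = vein, disc = disc, fov = fov,
                 source_id = source_id, quality_grade = quality_grade),
            class = "seg_maps")
}

as_binary_matrix <- function(x, what) {
  if (is.logical(x)) x <- x * 1L
  if (!is.matrix(x) || !is.numeric(x)) {
    rlang::abort(paste0(what, " mask must be a numeric matrix"),
                 class = "vesselmetrics_shape_error")
  }
  m <- matrix(as.integer(x > 0.5), nrow(x), ncol(x))
  m
}

#' @export
print.seg_maps <- function(x, ...) {
  cat(sprintf("<seg_maps> %s  %d x %d px  quality=%s\n", x$source_id,
              nrow(x$artery), ncol(x$artery), x$quality_grade))
  cat(sprintf("  artery %d px | vein %d px | disc %d px | fov %d px\n",
              sum(x$artery), sum(x$vein), sum(x$disc), sum(x$fov)))
  invisible(x)
}

default_palette <- function() {
  list(artery = c(1, 0, 0), vein = c(0, 0, 1), disc = c(1, 1, 0))
}

read_raster <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "vesselmetrics_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = rlang::abort("JPEG masks are not supported; use the fundus argument",
                        class = "vesselmetrics_io_error"),
    rlang::abort(paste0("unsupported raster format: .", ext),
                 class = "vesselmetrics_io_error"))
  img
}

to_gray <- function(img) {
  if (length(dim(img)) == 3L) {
    nc <- min(dim(img)[3], 3L)
    g <- img[, , 1]
    if (nc > 1) for (k in 2:nc) g <- g + img[, , k]
    g / nc
  } else {
    img
  }
}

#' Load segmentation maps from raster files
#'
#' Reads per-class binary masks (PNG or TIFF) or a single indexed color map,
#' optionally with the source fundus photograph from which the field of view
#' is estimated as its largest bright region.
#'
#' @param artery,vein,disc Paths to 8-bit binary mask images.
#' @param fundus Optional path to the source fundus photograph (PNG); used
#'   only to estimate the field of view.
#' @param indexed Optional path to a single RGB map encoding all classes by
#'   color; overrides `artery`/`vein`/`disc`.
#' @param palette Named list of RGB triplets (values in \[0,1\]) for classes
#'   `artery`, `vein`, `disc` used to decode an indexed map. Default: artery
#'   red, vein blue, disc yellow.
#' @param source_id Identifier; defaults to the first input file name.
#' @param quality_grade Optional pass-through quality label.
#'
#' @return A [seg_maps] object.
#' @export
load_segmentation_maps <- function(artery = NULL, vein = NULL, disc = NULL,
                                   fundus = NULL, indexed = NULL,
                                   palette = default_palette(),
                                   source_id = NULL, quality_grade = "unknown") {
  if (!is.null(indexed)) {
    img <- read_raster(indexed)
    if (length(dim(img)) != 3L || dim(img)[3] < 3L) {
      rlang::abort("indexed map must be an RGB image",
                   class = "vesselmetrics_palette_error")
    }
    if (!all(c("artery", "vein", "disc") %in% names(palette))) {
      rlang::abort("palette must name artery, vein and disc colors",
                   class = "vesselmetrics_palette_error")
    }
    dm <- dim(img)[1:2]
    match_col <- function(rgb) {
      d <- abs(img[, , 1] - rgb[1]) + abs(img[, , 2] - rgb[2]) + abs(img[, , 3] - rgb[3])
      matrix(as.integer(d < 0.3), dm[1], dm[2])
    }
    a <- match_col(palette$artery); v <- match_col(palette$vein); d <- match_col(palette$disc)
    fg <- to_gray(img) > 0.1
    unmapped <- fg & !(a | v | d)
    if (sum(unmapped) > 0.01 * sum(fg) && sum(unmapped) > 16) {
      rlang::abort(sprintf("indexed map has %d foreground pixels matching no palette color",
                           sum(unmapped)),
                   class = "vesselmetrics_palette_error")
    }
    masks <- list(artery = a, vein = v, disc = d)
    src <- source_id %||% basename(indexed)
  } else {
    if (is.null(artery) || is.null(vein) || is.null(disc)) {
      rlang::abort("either `indexed` or all of artery/vein/disc paths are required",
                   class = "vesselmetrics_io_error")
    }
    masks <- lapply(list(artery = artery, vein = vein, disc = disc), function(p) {
      as_binary_matrix(to_gray(read_raster(p)), basename(p))
    })
    dims <- lapply(masks, dim)
    if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
      rlang::abort("mask files have mismatched shapes",
                   class = "vesselmetrics_shape_error")
    }
    src <- source_id %||% sub("_(artery|a)\\.[A-Za-z]+$", "", basename(artery))
  }
  fov <- NULL
  if (!is.null(fundus)) {
    fimg <- read_raster(fundus)
    fov <- estimate_fov(fimg)
    if (!identical(dim(fov), dim(masks$artery))) {
      rlang::abort("fundus image shape differs from the masks",
                   class = "vesselmetrics_shape_error")
    }
  }
  seg_maps(masks$artery, masks$vein, masks$disc, fov = fov,
           source_id = src, quality_grade = quality_grade)
}

#' Estimate the field of view from a fundus photograph
#'
#' The field of view is taken as the filled largest bright connected
#' component of the gray-level image (the illuminated circle of the fundus).
#'
#' @param img RGB array or gray matrix with values in \[0,1\].
#' @return Binary matrix of the same height/width.
#' @export
estimate_fov <- function(img) {
  g <- to_gray(img)
  thr <- 0.1 * max(g)
  bright <- matrix(as.numeric(g > thr), nrow(g), ncol(g))
  if (sum(bright) == 0) {
    rlang::abort("no bright region found in fundus image",
                 class = "vesselmetrics_degenerate_input")
  }
  lab <- EBImage::bwlabel(bright)
  tab <- tabulate(as.integer(lab[lab > 0]))
  keep <- which.max(tab)
  comp <- matrix(as.numeric(lab == keep), nrow(g), ncol(g))
  filled <- EBImage::fillHull(comp)
  matrix(as.integer(filled > 0), nrow(g), ncol(g))
}

#' Save segmentation maps as PNG files
#'
#' @param maps A [seg_maps] object.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix; defaults to `maps$source_id`.
#' @return Invisibly, the paths written (artery, vein, disc, fov).
#' @export
save_segmentation_maps <- function(maps, dir, prefix = NULL) {
  stopifnot(inherits(maps, "seg_maps"))
  prefix <- prefix %||% maps$source_id
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(c("artery", "vein", "disc", "fov"), function(cl) {
    p <- file.path(dir, paste0(prefix, "_", cl, ".png"))
    png::writePNG(maps[[cl]] * 1.0, p)
    p
  }, character(1))
  invisible(paths)
}

#' Nearest-neighbor resize of a matrix
#'
#' Nearest-neighbor interpolation is used throughout so that binary masks stay
#' strictly binary (no fractional labels).
#' @param m Matrix.
#' @param out_r,out_c Output dimensions.
#' @return Resized matrix.
#' @keywords internal
resize_nn <- function(m, out_r, out_c) {
  ri <- pmin(nrow(m), pmax(1L, floor((seq_len(out_r) - 0.5) * nrow(m) / out_r) + 1L))
  ci <- pmin(ncol(m), pmax(1L, floor((seq_len(out_c) - 0.5) * ncol(m) / out_c) + 1L))
  m[ri, ci, drop = FALSE]
}

#' Preprocess masks to the analysis frame
#'
#' Crops all masks to the bounding box of the field of view, then resizes to
#' a square `target_side` frame with nearest-neighbor interpolation. Scale
#' factors are recorded in the `"scale"` attribute for traceability.
#'
#' @param maps A [seg_maps] object.
#' @param target_side Side of the square output frame, default 512.
#' @return A [seg_maps] object of shape `target_side x target_side`.
#' @export
#' @examples
#' m <- matrix(0L, 64, 64); m[20:40, 20:40] <- 1L
#' out <- preprocess_maps(seg_maps(m, m, m), target_side = 32)
#' dim(out$artery)
preprocess_maps <- function(maps, target_side = 512L) {
  stopifnot(inherits(maps, "seg_maps"))
  if (sum(maps$fov) == 0L) {
    rlang::abort("cannot preprocess maps with an empty field of view",
                 class = "vesselmetrics_degenerate_input")
  }
  idx <- which(maps$fov == 1L, arr.ind = TRUE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1]); c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  crop_resize <- function(m) resize_nn(m[r0:r1, c0:c1, drop = FALSE], target_side, target_side)
  out <- seg_maps(crop_resize(maps$artery), crop_resize(maps$vein),
                  crop_resize(maps$disc), crop_resize(maps$fov),
                  source_id = maps$source_id, quality_grade = maps$quality_grade)
  attr(out, "scale") <- c(row = target_side / (r1 - r0 + 1),
                          col = target_side / (c1 - c0 + 1))
  attr(out, "crop") <- c(r0 = r0, r1 = r1, c0 = c0, c1 = c1)
  out
}

#' Render a tri-color agreement overlay
#'
#' Compares a predicted binary mask against a reference: green where both
#' agree on vessel, blue where only the reference has vessel (false
#' negatives), red where only the prediction does (false positives).
#'
#' @param predicted,reference Binary matrices of identical shape.
#' @return An `h x w x 3` RGB array in \[0,1\], class `vessel_overlay`.
#' @export
#' @examples
#' a <- matrix(0L, 8, 8); a[4, 2:6] <- 1L
#' b <- matrix(0L, 8, 8); b[4, 4:8] <- 1L
#' ov <- render_overlay(a, b)
#' table(apply(ov, c(1, 2), paste, collapse = ","))
render_overlay <- function(predicted, reference) {
  predicted <- as_binary_matrix(predicted, "predicted")
  reference <- as_binary_matrix(reference, "reference")
  if (!identical(dim(predicted), dim(reference))) {
    rlang::abort("predicted and reference masks differ in shape",
                 class = "vesselmetrics_shape_error")
  }
  both <- predicted & reference
  fp <- predicted & !reference
  fn <- reference & !predicted
  out <- array(0, c(nrow(predicted), ncol(predicted), 3))
  out[, , 1][fp] <- 1      # red: false positive
  out[, , 2][both] <- 1    # green: agreement
  out[, , 3][fn] <- 1      # blue: false negative
  structure(out, class = c("vessel_overlay", class(out)))
}

#' @export
print.vessel_overlay <- function(x, ...) {
  g <- sum(x[, , 2] == 1); r <- sum(x[, , 1] == 1); b <- sum(x[, , 3] == 1)
  cat(sprintf("<vessel_overlay> %d x %d  green=%d red=%d blue=%d\n",
              dim(x)[1], dim(x)[2], g, r, b))
  invisible(x)
}

#' @rdname render_overlay
#' @param object A `vessel_overlay`.
#' @param ... Unused.
#' @export
autoplot.vessel_overlay <- function(object, ...) {
  h <- dim(object)[1]; w <- dim(object)[2]
  df <- expand.grid(row = seq_len(h), col = seq_len(w))
  df$fill <- grDevices::rgb(object[, , 1], object[, , 2], object[, , 3])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
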