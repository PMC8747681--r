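# Imaging stage: chart location and scaling, affine color correction, Otsu
# segmentation of grains on a white background, and contour extraction with
# filtering. Images are H x W x 3 numeric/integer arrays with 8-bit values,
# indexed image[row, col, channel].

#' Read a seed image from PNG or JPG
#' @param path image file path (PNG; 8-bit).
#' @return H x W x 3 numeric array with values in \[0, 255\].
#' @export
read_seed_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE] * 255
}

# Mean color of the central fraction of a square patch.
patch_mean <- function(image, cx, cy, halfwidth, central = 0.5) {
  hw <- halfwidth * central
  xs <- round(cx - hw):round(cx + hw)
  ys <- round(cy - hw):round(cy + hw)
  if (min(xs) < 1 || min(ys) < 1 || max(xs) > dim(image)[2] ||
      max(ys) > dim(image)[1])
    stop("patch region falls outside the image")
  c(mean(image[ys, xs, 1]), mean(image[ys, xs, 2]), mean(image[ys, xs, 3]))
}

#' Measure the reference chart in an image
#'
#' Verifies the dark corner fiducial is present at its configured location,
#' then measures the mean RGB of the central 50% of every patch and derives
#' the physical scale from the patch pitch.
#'
#' @param image H x W x 3 array, 8-bit values.
#' @param layout a [build_chart_layout()] describing where the chart is.
#' @param fiducial_max_lum maximum mean luminance (0-255) of the fiducial
#'   region for the chart to count as present.
#' @return List with `measured` (n x 3 matrix of patch means), `reference`
#'   (n x 3 matrix of layout reference colors) and `mm_per_px`
#'   (= pitch_mm / pitch_px).
#' @export
locate_chart <- function(image, layout, fiducial_max_lum = 90) {
  fid <- layout$fiducial
  fm <- tryCatch(patch_mean(image, fid$center[1], fid$center[2],
                            fid$halfwidth, central = 0.6),
                 error = function(e) stop("chart geometry error: ",
                                          conditionMessage(e)))
  lum <- rgb_to_ycrcb8(matrix(fm, 1))[1, 1]
  if (lum > fiducial_max_lum)
    stop("chart not found: fiducial region is not dark (luminance ",
         round(lum, 1), ")")
  p <- layout$patches
  measured <- t(vapply(seq_len(nrow(p)), function(i)
    patch_mean(image, p$cx[i], p$cy[i], layout$halfwidth_px), numeric(3)))
  colnames(measured) <- c("R", "G", "B")
  list(measured = measured,
       reference = as.matrix(p[, c("R", "G", "B")]),
       mm_per_px = layout$pitch_mm / layout$pitch_px)
}

#' Fit an affine color correction from measured to reference patch colors
#'
#' Least-squares fit of a 3 x 4 affine map (3 x 3 matrix plus offset) sending
#' the measured patch colors to their references. At least four linearly
#' independent patches are required.
#'
#' @param measured n x 3 matrix of measured patch RGB means.
#' @param reference n x 3 matrix of reference RGB values.
#' @return Object of class `color_transform`: list with `matrix` (3 x 4,
#'   \[A | b\]) and `residual_rms`.
#' @export
fit_color_correction <- function(measured, reference) {
  measured <- as.matrix(measured); reference <- as.matrix(reference)
  if (nrow(measured) < 4L)
    stop("need at least 4 patch pairs for an affine color fit")
  if (nrow(measured) != nrow(reference))
    stop("measured and reference must have the same number of rows")
  X <- cbind(measured, 1)
  if (qr(X)$rank < 4L)
    stop("rank-deficient patch colors: affine fit is under-determined")
  B <- qr.solve(X, reference)        # 4 x 3
  resid <- X %*% B - reference
  structure(list(matrix = t(B),
                 residual_rms = sqrt(mean(resid^2))),
            class = "color_transform")
}

#' @export
print.color_transform <- function(x, ...) {
  cat("color_transform (3 x 4 affine), residual RMS",
      format(x$residual_rms, digits = 3), "\n")
  print(round(x$matrix, 4))
  invisible(x)
}

#' Apply an affine color correction to an image
#'
#' Per-pixel affine map, rounded and clipped to \[0, 255\]. Clipping is
#' defined behavior; the clipped-pixel fraction is attached as an attribute.
#'
#' @param image H x W x 3 array, 8-bit values.
#' @param transform a [fit_color_correction()] result.
#' @return Corrected H x W x 3 integer array with attribute
#'   `clipped_fraction`.
#' @export
apply_color_correction <- function(image, transform) {
  d <- dim(image)
  flat <- cbind(matrix(image, ncol = 3), 1)
  out <- flat %*% t(transform$matrix)
  clipped <- mean(out < 0 | out > 255)
  out <- array(as.integer(pmin(pmax(round(out), 0), 255)), dim = d)
  attr(out, "clipped_fraction") <- clipped
  out
}

#' Segment grains from the white background
#'
#' Otsu threshold on the BT.601 luminance of the (corrected) image, inverted
#' so that the darker grains are foreground, followed by morphological
#' opening and hole filling. The chart region is forced to background both
#' before thresholding and in the result.
#'
#' @param image H x W x 3 array, 8-bit values (ideally color-corrected).
#' @param chart_bbox numeric (xmin, xmax, ymin, ymax) of the chart region to
#'   exclude, or `NULL`.
#' @param opening_radius disk radius in pixels of the morphological opening.
#' @return Binary H x W matrix (1 = grain pixel).
#' @export
segment_grains <- function(image, chart_bbox = NULL, opening_radius = 2) {
  lum <- matrix(rgb_to_ycrcb8(matrix(image, ncol = 3))[, 1],
                dim(image)[1], dim(image)[2]) / 255
  if (!is.null(chart_bbox)) {
    xs <- max(1, floor(chart_bbox["xmin"])):min(ncol(lum), ceiling(chart_bbox["xmax"]))
    ys <- max(1, floor(chart_bbox["ymin"])):min(nrow(lum), ceiling(chart_bbox["ymax"]))
    lum[ys, xs] <- 1
  }
  thr <- EBImage::otsu(lum, range = c(0, 1))
  mask <- (lum < thr) * 1
  if (opening_radius > 0)
    mask <- EBImage::opening(mask,
                             EBImage::makeBrush(2L * opening_radius + 1L, "disc"))
  mask <- EBImage::fillHull(mask)
  mask <- matrix(as.numeric(mask > 0), nrow(lum), ncol(lum))
  if (!is.null(chart_bbox)) mask[ys, xs] <- 0
  mask
}

#' Contour filter configuration
#'
#' @param min_area_mm2,max_area_mm2 accepted grain area range (mm^2).
#' @param max_aspect maximum length/width ratio of the minimum-area
#'   bounding rectangle.
#' @param exclude_border drop components touching the image border.
#' @export
contour_filters <- function(min_area_mm2 = 4, max_area_mm2 = 80,
                            max_aspect = 5, exclude_border = TRUE) {
  structure(list(min_area_mm2 = min_area_mm2, max_area_mm2 = max_area_mm2,
                 max_aspect = max_aspect, exclude_border = exclude_border),
            class = "contour_filters")
}

#' Extract grain contours from a segmentation mask
#'
#' Labels connected components, rejects those failing the filters (too
#' small/large in mm^2, too elongated, touching the border) and builds a
#' sub-pixel [grain_contour()] for each accepted component, with all derived
#' measures (area, perimeter, convex hull, maximum Feret diameter,
#' minimum-area rectangle) populated.
#'
#' @param mask binary H x W matrix from [segment_grains()].
#' @param mm_per_px physical scale from [locate_chart()].
#' @param filters a [contour_filters()].
#' @return List with `contours` (list of `grain_contour`, coordinates in the
#'   source image frame) and `rejected` (data frame: label, n_pixels,
#'   reason).
#' @export
extract_grain_contours <- function(mask, mm_per_px,
                                   filters = contour_filters()) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  contours <- list(); rejected <- list()
  if (n == 0) return(list(contours = contours,
                          rejected = data.frame(label = integer(),
                                                n_pixels = integer(),
                                                reason = character())))
  H <- nrow(lab); W <- ncol(lab)
  for (i in seq_len(n)) {
    px <- which(lab == i, arr.ind = TRUE)
    npx <- nrow(px)
    area_mm2 <- npx * mm_per_px^2
    reason <- NULL
    if (filters$exclude_border &&
        (min(px) == 1L || max(px[, 1]) == H || max(px[, 2]) == W))
      reason <- "border_touching"
    else if (area_mm2 < filters$min_area_mm2) reason <- "too_small"
    else if (area_mm2 > filters$max_area_mm2) reason <- "too_large"
    if (is.null(reason)) {
      r0 <- min(px[, 1]) - 3L; c0 <- min(px[, 2]) - 3L
      sub <- matrix(0, max(px[, 1]) - r0 + 3L, max(px[, 2]) - c0 + 3L)
      sub[cbind(px[, 1] - r0, px[, 2] - c0)] <- 1
      ct <- mask_to_contour(sub, offset = c(r0, c0))
      if (ct$rect_w > 0 && ct$rect_l / ct$rect_w > filters$max_aspect) {
        reason <- "too_elongated"
      } else {
        contours[[length(contours) + 1L]] <- ct
      }
    }
    if (!is.null(reason))
      rejected[[length(rejected) + 1L]] <-
        data.frame(label = i, n_pixels = npx, reason = reason)
  }
  list(contours = contours,
       rejected = if (length(rejected)) do.call(rbind, rejected)
       else data.frame(label = integer(), n_pixels = integer(),
                       reason = character()))
}
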