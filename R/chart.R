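# Color reference chart: layout description shared by the synthetic renderer
# (which draws the chart) and the imaging stage (which measures it). The
# default layout mimics a 24-patch ColorChecker-style target laid out as a
# 4 x 6 grid with a black fiducial square outside the grid corner fixing
# position and orientation. The real chart's physical geometry is not
# reproduced; the patch pitch in mm is the scale reference.

#' Reference sRGB values of a 24-patch ColorChecker-style target
#'
#' Classic published 8-bit sRGB coordinates of the 24 patches, row-major from
#' dark skin to black.
#' @return 24 x 3 matrix with rownames naming the patches.
#' @export
colorchecker_classic_colors <- function() {
  m <- matrix(c(
    115,  82,  68,   194, 150, 130,    98, 122, 157,    87, 108,  67,
    133, 128, 177,   103, 189, 170,   214, 126,  44,    80,  91, 166,
    193,  90,  99,    94,  60, 108,   157, 188,  64,   224, 163,  46,
     56,  61, 150,    70, 148,  73,   175,  54,  60,   231, 199,  31,
    187,  86, 149,     8, 133, 161,   243, 243, 242,   200, 200, 200,
    160, 160, 160,   122, 122, 121,    85,  85,  85,    52,  52,  52),
    ncol = 3, byrow = TRUE)
  rownames(m) <- c("dark_skin", "light_skin", "blue_sky", "foliage",
                   "blue_flower", "bluish_green", "orange", "purplish_blue",
                   "moderate_red", "purple", "yellow_green", "orange_yellow",
                   "blue", "green", "red", "yellow", "magenta", "cyan",
                   "white", "neutral_8", "neutral_6_5", "neutral_5",
                   "neutral_3_5", "black")
  colnames(m) <- c("R", "G", "B")
  m
}

#' Build a chart layout
#'
#' Describes where the reference chart sits in the image and what its patches
#' should look like: patch centers in pixels, patch half-width, reference
#' 8-bit RGB colors in row-major order, the physical patch pitch in mm (the
#' source of the mm-per-pixel scale) and a dark corner fiducial used to
#' verify the chart is present.
#'
#' @param colors n x 3 matrix of reference 8-bit RGB values, row-major over
#'   the grid; at least 4 patches (an affine color fit needs 4 anchors).
#' @param n_rows,n_cols grid shape; `n_rows * n_cols` must equal `nrow(colors)`.
#' @param origin_px (x, y) pixel center of the top-left patch.
#' @param pitch_px center-to-center patch spacing in pixels.
#' @param pitch_mm physical patch pitch in mm.
#' @param patch_halfwidth_px half side length of the rendered patch square.
#' @param centers optional n x 2 matrix of explicit patch centers (x, y),
#'   overriding the grid; must be unique.
#' @return Object of class `chart_layout`: list with `patches` (data frame of
#'   cx, cy, R, G, B), `pitch_px`, `pitch_mm`, `halfwidth_px`, `fiducial`
#'   (center and half-width of the dark corner square) and `bbox`
#'   (xmin, xmax, ymin, ymax covering chart plus fiducial with margin).
#' @examples
#' layout <- build_chart_layout()
#' nrow(layout$patches)  # 24
#' @export
build_chart_layout <- function(colors = colorchecker_classic_colors(),
                               n_rows = 4, n_cols = 6,
                               origin_px = c(60, 60),
                               pitch_px = 40, pitch_mm = 4,
                               patch_halfwidth_px = 14,
                               centers = NULL) {
  colors <- as.matrix(colors)
  if (nrow(colors) < 4L)
    stop("chart needs at least 4 patches for an affine color fit")
  if (any(colors < 0 | colors > 255))
    stop("reference colors must be 8-bit values in [0, 255]")
  if (is.null(centers)) {
    if (n_rows * n_cols != nrow(colors))
      stop("n_rows * n_cols must match the number of reference colors")
    grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
    centers <- cbind(origin_px[1] + (grid$col - 1) * pitch_px,
                     origin_px[2] + (grid$row - 1) * pitch_px)
  } else {
    centers <- as.matrix(centers)
    if (nrow(centers) != nrow(colors))
      stop("centers and colors must have the same number of rows")
  }
  if (anyDuplicated(centers))
    stop("duplicate patch positions")
  if (pitch_px <= 0 || pitch_mm <= 0) stop("patch pitch must be positive")
  fid_c <- c(min(centers[, 1]) - pitch_px, min(centers[, 2]) - pitch_px)
  hw <- patch_halfwidth_px
  bbox <- c(xmin = fid_c[1] - hw - 4, xmax = max(centers[, 1]) + hw + 4,
            ymin = fid_c[2] - hw - 4, ymax = max(centers[, 2]) + hw + 4)
  structure(list(
    patches = data.frame(cx = centers[, 1], cy = centers[, 2],
                         R = colors[, 1], G = colors[, 2], B = colors[, 3]),
    pitch_px = pitch_px, pitch_mm = pitch_mm, halfwidth_px = hw,
    fiducial = list(center = fid_c, halfwidth = hw),
    bbox = bbox
  ), class = "chart_layout")
}

#' @export
print.chart_layout <- function(x, ...) {
  cat(sprintf("chart_layout: %d patches, pitch %g px = %g mm (%.3g mm/px)\n",
              nrow(x$patches), x$pitch_px, x$pitch_mm, x$pitch_mm / x$pitch_px))
  invisible(x)
}

# Draw the chart (patches + fiducial) into an H x W x 3 canvas, in place.
render_chart <- function(canvas, layout) {
  hw <- layout$halfwidth_px
  draw_square <- function(canvas, cx, cy, col) {
    xs <- max(1, round(cx - hw)):min(dim(canvas)[2], round(cx + hw))
    ys <- max(1, round(cy - hw)):min(dim(canvas)[1], round(cy + hw))
    for (ch in 1:3) canvas[ys, xs, ch] <- col[ch]
    canvas
  }
  p <- layout$patches
  for (i in seq_len(nrow(p)))
    canvas <- draw_square(canvas, p$cx[i], p$cy[i], c(p$R[i], p$G[i], p$B[i]))
  canvas <- draw_square(canvas, layout$fiducial$center[1],
                        layout$fiducial$center[2], c(0, 0, 0))
  canvas
}
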