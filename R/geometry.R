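# Planar geometry for grain contours: area/perimeter, convex hull, maximum
# Feret diameter and minimum-area bounding rectangle. All functions take a
# closed polygon as an n x 2 matrix of (x, y) vertices (last edge implicit).

polygon_signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

polygon_perimeter <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

convex_hull <- function(v) {
  v[rev(grDevices::chull(v[, 1], v[, 2])), , drop = FALSE]  # chull is clockwise
}

# Maximum Feret diameter: largest pairwise distance between hull vertices.
# Hull sizes here are small (tens of vertices), so the quadratic scan is fine.
feret_max <- function(hull) {
  if (nrow(hull) == 1L) return(0)
  d <- dist(hull)
  max(d)
}

# Minimum-area bounding rectangle via rotating over hull edge directions.
# Returns c(long_side, short_side).
min_area_rect <- function(hull) {
  n <- nrow(hull)
  if (n == 1L) return(c(0, 0))
  if (n == 2L) {
    return(c(sqrt(sum((hull[1, ] - hull[2, ])^2)), 0))
  }
  best <- c(Inf, Inf, Inf)  # area, side1, side2
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < .Machine$double.eps) next
    u <- e / len
    w <- c(-u[2], u[1])
    pu <- hull %*% u
    pw <- hull %*% w
    s1 <- max(pu) - min(pu)
    s2 <- max(pw) - min(pw)
    if (s1 * s2 < best[1]) best <- c(s1 * s2, s1, s2)
  }
  sort(best[2:3], decreasing = TRUE)
}

#' Construct a grain contour with derived shape measures
#'
#' Builds the geometric record used by the shape descriptors from a closed
#' boundary polygon (and optionally the filled pixel mask it came from).
#' Vertices are stored counter-clockwise; the contour must be simple.
#'
#' @param vertices n x 2 numeric matrix of boundary vertices (x, y), ordered
#'   along the boundary; the closing edge is implicit.
#' @param pixels optional m x 2 integer matrix of (row, col) mask pixel
#'   coordinates in the source image; kept for color extraction.
#' @param n_pixels optional pixel count of the filled mask. Defaults to
#'   `nrow(pixels)` when pixels are given, otherwise the polygon area is used
#'   where a pixel area is requested.
#' @return An object of class `grain_contour`: a list with `vertices`,
#'   `area` (polygon area), `perimeter` (Ps), `hull_perimeter` (Pc),
#'   `hull_area`, `feret_max` (major axis), `rect_l`/`rect_w` (minimum-area
#'   bounding rectangle sides, long and short), `n_pixels`, `pixels`,
#'   `centroid`.
#' @examples
#' sq <- grain_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' sq$area        # 1
#' circularity(sq)  # pi / 4
#' @export
grain_contour <- function(vertices, pixels = NULL, n_pixels = NULL) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("vertices must be an n x 2 matrix with n >= 3")
  sa <- polygon_signed_area(vertices)
  if (abs(sa) < .Machine$double.eps)
    stop("degenerate contour: zero area")
  if (sa < 0) vertices <- vertices[rev(seq_len(nrow(vertices))), ]  # force CCW
  hull <- convex_hull(vertices)
  if (is.null(n_pixels) && !is.null(pixels)) n_pixels <- nrow(pixels)
  structure(list(
    vertices = vertices,
    area = abs(sa),
    perimeter = polygon_perimeter(vertices),
    hull_perimeter = polygon_perimeter(hull),
    hull_area = abs(polygon_signed_area(hull)),
    feret_max = feret_max(hull),
    rect_l = min_area_rect(hull)[1],
    rect_w = min_area_rect(hull)[2],
    n_pixels = n_pixels,
    pixels = pixels,
    centroid = colMeans(vertices)
  ), class = "grain_contour")
}

#' @export
print.grain_contour <- function(x, ...) {
  cat(sprintf(
    "grain_contour: %d vertices, area %.1f, perimeter %.1f, feret %.1f\n",
    nrow(x$vertices), x$area, x$perimeter, x$feret_max))
  invisible(x)
}

# Separable Gaussian smoothing of a matrix with zero padding. Used to obtain
# a sub-pixel boundary from a binary mask: contouring the raw 0/1 raster
# produces a staircase polygon whose perimeter is biased high (~6% for a
# disk), which would bias circularity low.
smooth_matrix <- function(m, sd = 1, radius = 4L) {
  k <- stats::dnorm(seq(-radius, radius), sd = sd)
  k <- k / sum(k)
  pad <- matrix(0, nrow(m) + 2L * radius, ncol(m) + 2L * radius)
  pad[radius + seq_len(nrow(m)), radius + seq_len(ncol(m))] <- m
  pad <- apply(pad, 2, function(v) as.numeric(stats::filter(v, k, sides = 2)))
  pad <- t(apply(pad, 1, function(v) as.numeric(stats::filter(v, k, sides = 2))))
  pad[radius + seq_len(nrow(m)), radius + seq_len(ncol(m))]
}

#' Extract a sub-pixel boundary contour from a binary mask
#'
#' Lightly smooths the mask and traces the 0.5 iso-contour (marching squares)
#' so that the measured perimeter is unbiased for smooth blobs; the filled
#' pixel count is kept separately as the pixel area.
#'
#' @param mask binary (0/1) matrix, one connected component; indexed
#'   `mask[row, col]`.
#' @param smooth_sd standard deviation in pixels of the Gaussian applied
#'   before contouring.
#' @param offset length-2 integer (row, col) offset subtracted earlier when
#'   cropping the mask from a larger image; added back so vertex and pixel
#'   coordinates are in the source frame.
#' @return A [grain_contour()] whose vertices are in (x = col, y = row)
#'   image coordinates and whose `n_pixels` is `sum(mask)`.
#' @export
mask_to_contour <- function(mask, smooth_sd = 1, offset = c(0L, 0L)) {
  if (!any(mask > 0)) stop("empty mask")
  sm <- smooth_matrix(mask, sd = smooth_sd)
  cl <- grDevices::contourLines(seq_len(nrow(mask)), seq_len(ncol(mask)),
                                sm, levels = 0.5)
  if (length(cl) == 0L) stop("no contour found at level 0.5")
  # keep the largest loop (smoothing can create satellite specks)
  areas <- vapply(cl, function(c0)
    abs(polygon_signed_area(cbind(c0$x, c0$y))), numeric(1))
  c0 <- cl[[which.max(areas)]]
  # contourLines x follows the first index (rows); convert to (x=col, y=row)
  verts <- cbind(c0$y + offset[2], c0$x + offset[1])
  px <- which(mask > 0, arr.ind = TRUE)
  px[, 1] <- px[, 1] + offset[1]
  px[, 2] <- px[, 2] + offset[2]
  grain_contour(verts, pixels = px, n_pixels = nrow(px))
}
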