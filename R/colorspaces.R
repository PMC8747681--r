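# 8-bit color space conversions. All converters take and return an n x 3
# numeric matrix. Inputs are 8-bit sRGB values in [0, 255]; outputs follow
# the 8-bit conventions in which every component lies in [0, 255] except
# hue, which is stored in half-degrees in [0, 180):
#   HSV:   H = degrees / 2, S = 255 * (max - min) / max, V = max
#   Lab:   L = 255 * L* / 100, a = a* + 128, b = b* + 128  (sRGB -> D65 XYZ)
#   YCrCb: ITU-R BT.601 full range, Cr = (R - Y) * 0.713 + 128,
#          Cb = (B - Y) * 0.564 + 128
# Under these conventions gray (g, g, g) maps to Y = g, Cr = Cb = 128,
# a = b = 128, S = 0, and white maps to L = 255.

# sRGB D65 linear-RGB -> XYZ matrix; its row sums are used as the white
# point so that exact grays give a = b = 128 to machine precision.
.srgb_xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)

#' Convert 8-bit RGB to 8-bit HSV (H in half-degrees)
#' @param rgb n x 3 matrix of R, G, B in \[0, 255\].
#' @return n x 3 matrix of H in \[0, 180), S and V in \[0, 255\].
#' @export
rgb_to_hsv8 <- function(rgb) {
  rgb <- rbind(rgb)
  r <- rgb[, 1]; g <- rgb[, 2]; b <- rgb[, 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- numeric(length(r))
  nz <- d > 0
  i <- nz & mx == r
  h[i] <- 60 * (g[i] - b[i]) / d[i]
  i <- nz & mx == g & mx != r
  h[i] <- 120 + 60 * (b[i] - r[i]) / d[i]
  i <- nz & mx == b & mx != r & mx != g
  h[i] <- 240 + 60 * (r[i] - g[i]) / d[i]
  h <- (h %% 360) / 2
  s <- ifelse(mx > 0, 255 * d / mx, 0)
  cbind(H = h, S = s, V = mx)
}

lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

lab_finv <- function(t) {
  d <- 6 / 29
  ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
}

#' Convert 8-bit sRGB to 8-bit CIELAB
#' @param rgb n x 3 matrix of R, G, B in \[0, 255\].
#' @return n x 3 matrix with L = 255 L*/100, a = a* + 128, b = b* + 128.
#' @export
rgb_to_lab8 <- function(rgb) {
  rgb <- rbind(rgb)
  s <- rgb / 255
  lin <- ifelse(s <= 0.04045, s / 12.92, ((s + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb_xyz)
  xyz <- sweep(xyz, 2, rowSums(.srgb_xyz), "/")
  fx <- lab_f(xyz)
  L <- 116 * fx[, 2] - 16
  a <- 500 * (fx[, 1] - fx[, 2])
  b <- 200 * (fx[, 2] - fx[, 3])
  cbind(L = L * 255 / 100, a = a + 128, b = b + 128)
}

#' Convert 8-bit CIELAB (package convention) back to 8-bit sRGB
#'
#' Inverse of [rgb_to_lab8()]; used by the synthetic generator to pick coat
#' colors directly on the lightness/redness axes. Out-of-gamut results are
#' clipped to \[0, 255\].
#' @param lab n x 3 matrix of L, a, b in the 8-bit convention.
#' @return n x 3 matrix of R, G, B in \[0, 255\].
#' @export
lab8_to_rgb <- function(lab) {
  lab <- rbind(lab)
  L <- lab[, 1] * 100 / 255
  a <- lab[, 2] - 128
  b <- lab[, 3] - 128
  fy <- (L + 16) / 116
  wn <- rowSums(.srgb_xyz)
  xyz <- cbind(lab_finv(fy + a / 500) * wn[1],
               lab_finv(fy) * wn[2],
               lab_finv(fy - b / 200) * wn[3])
  lin <- xyz %*% t(solve(.srgb_xyz))
  s <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * pmax(lin, 0)^(1 / 2.4) - 0.055)
  pmin(pmax(s * 255, 0), 255)
}

#' Convert 8-bit RGB to 8-bit YCrCb (BT.601 full range)
#' @param rgb n x 3 matrix of R, G, B in \[0, 255\].
#' @return n x 3 matrix of Y, Cr, Cb in \[0, 255\].
#' @export
rgb_to_ycrcb8 <- function(rgb) {
  rgb <- rbind(rgb)
  y <- 0.299 * rgb[, 1] + 0.587 * rgb[, 2] + 0.114 * rgb[, 3]
  # saturate: the BT.601 chroma gains overshoot 255 by up to 0.5 at the
  # primaries, as in any 8-bit implementation
  cr <- pmin(pmax((rgb[, 1] - y) * 0.713 + 128, 0), 255)
  cb <- pmin(pmax((rgb[, 3] - y) * 0.564 + 128, 0), 255)
  cbind(Y = y, Cr = cr, Cb = cb)
}

# The four descriptor spaces in canonical order, with component labels as
# they appear in trait names.
color_space_components <- function() {
  list(RGB   = c("R", "G", "B"),
       HSV   = c("H", "S", "V"),
       Lab   = c("L", "a", "b"),
       YCrCb = c("Y", "Cr", "Cb"))
}

#' Convert RGB pixels to one of the four descriptor color spaces
#' @param rgb n x 3 matrix of R, G, B in \[0, 255\].
#' @param space one of `"RGB"`, `"HSV"`, `"Lab"`, `"YCrCb"`.
#' @return n x 3 matrix in the requested space (8-bit conventions).
#' @export
convert_color_space <- function(rgb, space) {
  switch(match.arg(space, names(color_space_components())),
         RGB = {
           m <- rbind(rgb)
           colnames(m) <- c("R", "G", "B")
           m
         },
         HSV = rgb_to_hsv8(rgb),
         Lab = rgb_to_lab8(rgb),
         YCrCb = rgb_to_ycrcb8(rgb))
}
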