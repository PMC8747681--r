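# Per-grain descriptors: 3 size (sL, sW, sA), 4 shape (sCi, sRo, sRu, sSo)
# and 48 color traits. Color traits are computed in four spaces (RGB, HSV,
# CIELAB, YCrCb): per space the 3-sigma-trimmed mean of each component
# (SPACE_mC) and the components of the three k-means dominant colors ranked
# by pixel fraction (SPACE_dCC_i, i = 1..3).

#' Size traits of a grain
#'
#' Length and width are the long and short side of the minimum-area bounding
#' rectangle of the contour; area is the filled pixel count. All are scaled
#' to mm / mm^2.
#'
#' @param contour a [grain_contour()].
#' @param mm_per_px physical scale (> 0).
#' @return Named vector `c(sL, sW, sA)`.
#' @export
size_traits <- function(contour, mm_per_px) {
  stopifnot(mm_per_px > 0)
  npx <- contour$n_pixels
  if (is.null(npx)) npx <- contour$area
  c(sL = contour$rect_l * mm_per_px,
    sW = contour$rect_w * mm_per_px,
    sA = npx * mm_per_px^2)
}

#' Circularity: 4 pi area / perimeter^2
#'
#' Equals 1 for a circle (the figure with the smallest perimeter for a given
#' area) and less for any other shape; small boundary convexities inflate
#' the perimeter and drive the index down.
#' @param contour a [grain_contour()].
#' @export
circularity <- function(contour) {
  if (contour$perimeter <= 0) stop("zero perimeter")
  4 * pi * contour$area / contour$perimeter^2
}

#' Roundness: 4 area / (pi major_axis^2)
#'
#' Uses the maximum Feret diameter as the major axis, so the isodiametric
#' inequality bounds the index by 1 (attained by the circle); unlike
#' circularity it is insensitive to boundary roughness.
#' @param contour a [grain_contour()].
#' @export
roundness <- function(contour) {
  if (contour$feret_max <= 0) stop("degenerate contour: zero major axis")
  4 * contour$area / (pi * contour$feret_max^2)
}

#' Rugosity: contour perimeter / convex-hull perimeter
#'
#' At least 1 (the hull perimeter is minimal among enclosing convex shapes);
#' larger for ragged outlines.
#' @param contour a [grain_contour()].
#' @export
rugosity <- function(contour) {
  if (contour$hull_perimeter <= 0) stop("degenerate contour")
  contour$perimeter / contour$hull_perimeter
}

#' Solidity: contour area / convex-hull area
#'
#' In (0, 1]; smaller for concave shapes.
#' @param contour a [grain_contour()].
#' @export
solidity <- function(contour) {
  if (contour$hull_area <= 0) stop("degenerate contour")
  contour$area / contour$hull_area
}

#' Trimmed mean color descriptors (12 values, SPACE_mC)
#'
#' For each color space and each component independently: compute the mean
#' and (population) standard deviation over all grain pixels, discard pixels
#' whose value deviates from the mean by strictly more than 3 SD (a zero SD
#' discards nothing), and report the mean of the survivors. Exactly one trim
#' iteration is applied.
#'
#' @param pixels_rgb n x 1..3 matrix of 8-bit RGB pixel values (n >= 1).
#' @return Named vector of the 12 `SPACE_mC` descriptors.
#' @export
mean_color_descriptors <- function(pixels_rgb) {
  pixels_rgb <- rbind(pixels_rgb)
  if (nrow(pixels_rgb) < 1L) stop("empty pixel set")
  comps <- color_space_components()
  out <- numeric(0)
  for (space in names(comps)) {
    m <- convert_color_space(pixels_rgb, space)
    vals <- vapply(1:3, function(j) trimmed_mean_3sd(m[, j]), numeric(1))
    names(vals) <- paste0(space, "_m", comps[[space]])
    out <- c(out, vals)
  }
  out
}

trimmed_mean_3sd <- function(v) {
  m1 <- mean(v)
  s1 <- sqrt(mean((v - m1)^2))
  if (s1 == 0) return(m1)
  mean(v[abs(v - m1) <= 3 * s1])
}

#' Dominant color descriptors (36 values, SPACE_dCC_i) and pixel fractions
#'
#' Clusters the grain pixels by k-means (k = 3) separately in each color
#' space, ranks clusters by descending pixel fraction (ties broken by the
#' brightness component: V, L, Y, or R+G+B for RGB) and reports each ranked
#' centroid's components. If the grain has fewer than k distinct colors, the
#' distinct colors fill the leading ranks and the remaining ranks duplicate
#' rank 1 (with fraction 0), keeping the schema fixed.
#'
#' @param pixels_rgb n x 3 matrix of 8-bit RGB pixel values.
#' @param k number of dominant colors (3 by convention).
#' @param seed RNG seed for the k-means restarts, so a grain's descriptors
#'   are reproducible.
#' @return List with `descriptors` (named vector of the 36 `SPACE_dCC_i`
#'   values) and `fractions` (k-vector of rank pixel fractions per space,
#'   averaged presentation uses the RGB space; stored per space as a k x 4
#'   matrix).
#' @export
dominant_color_descriptors <- function(pixels_rgb, k = 3, seed = 1L) {
  pixels_rgb <- rbind(pixels_rgb)
  if (nrow(pixels_rgb) < 1L) stop("empty pixel set")
  comps <- color_space_components()
  bright_idx <- c(RGB = NA, HSV = 3, Lab = 1, YCrCb = 1)
  out <- numeric(0)
  fr <- matrix(NA_real_, k, length(comps),
               dimnames = list(NULL, names(comps)))
  for (space in names(comps)) {
    m <- convert_color_space(pixels_rgb, space)
    uniq <- unique(m)
    if (nrow(uniq) <= k) {
      # degenerate: fewer distinct colors than clusters
      cent <- uniq
      frac <- vapply(seq_len(nrow(uniq)), function(i)
        mean(colSums(t(m) == uniq[i, ]) == 3L), numeric(1))
    } else {
      set.seed(seed)
      km <- stats::kmeans(m, centers = k, nstart = 10, iter.max = 100)
      cent <- km$centers
      frac <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) /
        nrow(m)
    }
    bright <- if (space == "RGB") rowSums(cent) else cent[, bright_idx[space]]
    ord <- order(-frac, -bright)
    cent <- cent[ord, , drop = FALSE]
    frac <- frac[ord]
    while (nrow(cent) < k) {            # pad by duplicating rank 1
      cent <- rbind(cent, cent[1, ])
      frac <- c(frac, 0)
    }
    vals <- as.numeric(t(cent))
    names(vals) <- paste0(space, "_dC", rep(comps[[space]], times = k), "_",
                          rep(seq_len(k), each = 3))
    out <- c(out, vals)
    fr[, space] <- frac
  }
  list(descriptors = out, fractions = fr)
}

#' Canonical trait names
#'
#' The 55 descriptor columns in canonical order: sL, sW, sA, sCi, sRo, sRu,
#' sSo, then for each space RGB / HSV / Lab / YCrCb the three trimmed means
#' followed by the dominant-color components in rank order.
#' @return Character vector of length 55.
#' @export
trait_names <- function() {
  comps <- color_space_components()
  cols <- c("sL", "sW", "sA", "sCi", "sRo", "sRu", "sSo")
  for (space in names(comps)) {
    cols <- c(cols, paste0(space, "_m", comps[[space]]),
              paste0(space, "_dC", rep(comps[[space]], times = 3), "_",
                     rep(1:3, each = 3)))
  }
  cols
}

# All traits for one grain: contour -> size/shape, pixels -> color.
grain_traits <- function(contour, pixels_rgb, mm_per_px, seed = 1L) {
  dc <- dominant_color_descriptors(pixels_rgb, seed = seed)
  c(size_traits(contour, mm_per_px),
    sCi = circularity(contour), sRo = roundness(contour),
    sRu = rugosity(contour), sSo = solidity(contour),
    mean_color_descriptors(pixels_rgb)[trait_color_m_order()],
    dc$descriptors)[trait_names()]
}

trait_color_m_order <- function() {
  comps <- color_space_components()
  unlist(lapply(names(comps), function(s) paste0(s, "_m", comps[[s]])))
}

#' Process one seed image end to end
#'
#' Runs the imaging stages (chart measurement, color correction,
#' segmentation, contour extraction) and computes all 55 traits for every
#' accepted grain.
#'
#' @param image H x W x 3 array (8-bit) or a path to a PNG.
#' @param layout a [build_chart_layout()].
#' @param filters a [contour_filters()].
#' @param image_id identifier copied into the output rows and used to derive
#'   per-grain k-means seeds.
#' @param seed master seed combined with (image_id, grain_id) for the
#'   dominant-color k-means.
#' @return List with `traits` (data frame: image_id, grain_id + 55 trait
#'   columns), `rejected`, `mm_per_px`, `correction` (the fitted
#'   [fit_color_correction()] transform).
#' @export
process_seed_image <- function(image, layout, filters = contour_filters(),
                               image_id = "img", seed = 1L) {
  if (is.character(image)) image <- read_seed_image(image)
  chart <- locate_chart(image, layout)
  tr <- fit_color_correction(chart$measured, chart$reference)
  corrected <- apply_color_correction(image, tr)
  mask <- segment_grains(corrected, chart_bbox = layout$bbox)
  ext <- extract_grain_contours(mask, chart$mm_per_px, filters)
  rows <- vector("list", length(ext$contours))
  for (i in seq_along(ext$contours)) {
    ct <- ext$contours[[i]]
    px <- ct$pixels
    pix_rgb <- cbind(corrected[cbind(px[, 1], px[, 2], 1)],
                     corrected[cbind(px[, 1], px[, 2], 2)],
                     corrected[cbind(px[, 1], px[, 2], 3)])
    tv <- grain_traits(ct, pix_rgb, chart$mm_per_px,
                       seed = stable_seed(paste(image_id, i), seed))
    rows[[i]] <- data.frame(image_id = image_id, grain_id = i,
                            t(tv), check.names = FALSE)
  }
  traits <- if (length(rows)) do.call(rbind, rows) else NULL
  list(traits = traits, rejected = ext$rejected,
       mm_per_px = chart$mm_per_px, correction = tr)
}

#' Compute the per-seed trait table for a whole study
#'
#' Iterates [process_seed_image()] over the design table and assembles one
#' row per accepted grain with identifiers (image_id, grain_id, genotype_id,
#' year) followed by exactly the 55 trait columns of [trait_names()].
#'
#' @param design design table (image_id, image_path, genotype_id, year),
#'   e.g. from [generate_study()].
#' @param layout a [build_chart_layout()] (must match how the images were
#'   taken/rendered).
#' @param filters a [contour_filters()].
#' @param seed master seed for the per-grain k-means streams.
#' @param verbose print one line per image.
#' @return Data frame: 4 identifier columns + 55 trait columns.
#' @export
compute_trait_table <- function(design, layout, filters = contour_filters(),
                                seed = 1L, verbose = FALSE) {
  need <- c("image_id", "image_path", "genotype_id", "year")
  if (!all(need %in% names(design)))
    stop("design table must have columns: ", paste(need, collapse = ", "))
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    res <- process_seed_image(design$image_path[i], layout, filters,
                              image_id = design$image_id[i], seed = seed)
    if (!is.null(res$traits))
      out[[i]] <- cbind(res$traits[, 1, drop = FALSE],
                        genotype_id = design$genotype_id[i],
                        year = design$year[i],
                        res$traits[, -1, drop = FALSE])
    if (verbose)
      message(design$image_id[i], ": ",
              if (is.null(res$traits)) 0 else nrow(res$traits), " grains")
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
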