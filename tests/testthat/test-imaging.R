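test_that("affine color fit recovers exact transforms", {
  ref <- colorchecker_classic_colors()
  t_id <- fit_color_correction(ref, ref)
  expect_equal(t_id$matrix, cbind(diag(3), 0), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(t_id$residual_rms, 1e-8)

  t_half <- fit_color_correction(ref * 0.5, ref)
  expect_equal(unname(diag(t_half$matrix[, 1:3])), rep(2, 3),
               tolerance = 1e-8)

  expect_error(fit_color_correction(ref[1:3, ], ref[1:3, ]), "at least 4")
  gray <- cbind(1:6, 1:6, 1:6)
  expect_error(fit_color_correction(gray, gray), "rank-deficient")
})

test_that("cast round trip restores patch colors within 2 levels", {
  layout <- build_chart_layout(pitch_px = 30, patch_halfwidth_px = 10,
                               origin_px = c(45, 45))
  cast <- diag(c(0.9, 1.0, 1.04))
  cfg <- study_config(n_genotypes = 1, years = 2003,
                      grains_per_image = c(3, 3),
                      image_width = 420, image_height = 300,
                      chart = layout, cast_matrix = cast, seed = 11)
  gp <- grainpheno:::make_genotype_params(cfg)
  yp <- grainpheno:::make_year_params(cfg)
  res <- render_seed_image(gp[1, ], yp[1, ], 3, cfg, seed = 11)
  chart <- locate_chart(res$image, layout)
  # forward model: measured patch means are the cast-scaled references
  white <- which(rownames(colorchecker_classic_colors()) == "white")
  expect_equal(chart$measured[white, ],
               pmin(chart$reference[white, ] * diag(cast), 255),
               tolerance = 1.2, ignore_attr = TRUE)
  tr <- fit_color_correction(chart$measured, chart$reference)
  corrected <- apply_color_correction(res$image, tr)
  after <- locate_chart(corrected, layout)
  expect_lt(max(abs(after$measured - after$reference)), 2)
  expect_true(all(corrected >= 0 & corrected <= 255))
  id <- fit_color_correction(chart$reference, chart$reference)
  expect_equal(apply_color_correction(corrected, id), corrected,
               ignore_attr = TRUE)
})

test_that("a saturating cast is still corrected on unclipped channels", {
  # a 1.1 blue gain clips the white patch at quantization; the unclipped
  # red/green channels must still come back within 2 levels
  layout <- build_chart_layout(pitch_px = 30, patch_halfwidth_px = 10,
                               origin_px = c(45, 45))
  img <- grainpheno:::render_chart(array(250, dim = c(300, 420, 3)), layout)
  flat <- matrix(img, ncol = 3) %*% diag(c(0.9, 1.0, 1.1))
  cast_img <- array(pmin(pmax(round(flat), 0), 255), dim = dim(img))
  chart <- locate_chart(cast_img, layout)
  tr <- fit_color_correction(chart$measured, chart$reference)
  after <- locate_chart(apply_color_correction(cast_img, tr), layout)
  expect_lt(max(abs(after$measured[, 1:2] - after$reference[, 1:2])), 2)
})

test_that("chart location reports scale and fails when the chart is absent", {
  layout <- build_chart_layout(pitch_px = 40, pitch_mm = 4)
  blank <- array(250, dim = c(300, 420, 3))
  expect_error(locate_chart(blank, layout), "chart not found")
  img <- grainpheno:::render_chart(blank, layout)
  chart <- locate_chart(img, layout)
  expect_equal(chart$mm_per_px, 0.1)
  expect_equal(chart$measured, chart$reference, tolerance = 1,
               ignore_attr = TRUE)
  small <- array(250, dim = c(16, 16, 3))
  expect_error(locate_chart(small, layout), "geometry")
})

test_that("chart layout validates its spec", {
  expect_equal(nrow(build_chart_layout()$patches), 24)
  four <- build_chart_layout(colors = colorchecker_classic_colors()[c(19, 24, 15, 14), ],
                             n_rows = 2, n_cols = 2)
  expect_equal(nrow(four$patches), 4)
  expect_error(build_chart_layout(colors = colorchecker_classic_colors()[1:3, ],
                                  n_rows = 1, n_cols = 3), "at least 4")
  expect_error(build_chart_layout(centers = matrix(1, 24, 2)), "duplicate")
})

test_that("segmentation matches ground-truth masks", {
  cfg <- study_config(n_genotypes = 1, years = c(2003, 2004),
                      grains_per_image = c(6, 6),
                      image_width = 560, image_height = 420, seed = 5)
  gp <- grainpheno:::make_genotype_params(cfg)
  yp <- grainpheno:::make_year_params(cfg)
  res <- render_seed_image(gp[1, ], yp[1, ], 6, cfg, seed = 5)
  chart <- locate_chart(res$image, cfg$chart)
  tr <- fit_color_correction(chart$measured, chart$reference)
  corrected <- apply_color_correction(res$image, tr)
  mask <- segment_grains(corrected, chart_bbox = cfg$chart$bbox)

  bb <- cfg$chart$bbox
  expect_equal(sum(mask[bb["ymin"]:bb["ymax"], bb["xmin"]:bb["xmax"]]), 0)

  lab <- EBImage::bwlabel(mask)
  expect_equal(max(lab), 6)
  for (i in 1:6) {
    gt_i <- res$labels == i
    ov <- table(factor(lab[gt_i], levels = 0:max(lab)))
    j <- as.integer(names(which.max(ov[-1])))
    seg_j <- lab == j
    iou <- sum(gt_i & seg_j) / sum(gt_i | seg_j)
    expect_gte(iou, 0.95)
  }
})

test_that("blank images give empty masks", {
  blank <- array(250, dim = c(100, 100, 3))
  expect_equal(sum(segment_grains(blank)), 0)
})

test_that("contour filters reject and log bad components", {
  mask <- matrix(0, 200, 200)
  mask[50:90, 50:110] <- 1         # plausible grain (41x61 px)
  mask[150:152, 150:152] <- 1      # too small
  mask[1:40, 150:190] <- 1         # touches border
  ext <- extract_grain_contours(mask, mm_per_px = 0.1)
  expect_length(ext$contours, 1)
  expect_setequal(ext$rejected$reason, c("too_small", "border_touching"))

  permissive <- contour_filters(min_area_mm2 = 0, exclude_border = FALSE)
  ext2 <- extract_grain_contours(mask, 0.1, permissive)
  expect_length(ext2$contours, 3)

  # every emitted contour satisfies the hull inequalities exactly
  for (ct in ext2$contours) {
    expect_gte(ct$perimeter, ct$hull_perimeter)
    expect_gte(ct$hull_area, ct$area)
  }
})
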