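small_cfg <- function(...) {
  study_config(n_genotypes = 2, years = c(2003, 2004, 2009, 2014),
               grains_per_image = c(4, 5), image_width = 520,
               image_height = 380, seed = 7, ...)
}

test_that("study config validates its invariants", {
  expect_error(study_config(years = c(2004, 2003)), "strictly increasing")
  expect_error(study_config(grains_per_image = c(5, 3)), "range")
  expect_error(study_config(grains_per_image = c(0, 3)), "min >= 1")
  expect_error(study_config(mm_per_px = 0), "positive")
  expect_error(study_config(redness_noise_sd = -1), "SDs")
  expect_s3_class(study_config(), "study_config")
})

test_that("a study bundle has the right shape and is deterministic", {
  cfg <- small_cfg()
  d1 <- tempfile("study"); d2 <- tempfile("study")
  s1 <- generate_study(cfg, d1)
  s2 <- generate_study(cfg, d2)
  expect_equal(nrow(s1$design), 2 * 4)            # one image per genotype-year
  expect_true(all(file.exists(s1$design$image_path)))
  counts <- table(s1$ground_truth$image_id)
  expect_true(all(counts >= 4 & counts <= 5))
  # byte-identical ground truth and identical pixel rasters from the same seed
  expect_identical(s1$ground_truth, s2$ground_truth)
  expect_identical(readBin(s1$design$image_path[1], "raw", 1e6),
                   readBin(s2$design$image_path[1], "raw", 1e6))
})

test_that("grain masks avoid the chart and each other", {
  cfg <- small_cfg()
  gp <- grainpheno:::make_genotype_params(cfg)
  yp <- grainpheno:::make_year_params(cfg)
  res <- render_seed_image(gp[1, ], yp[1, ], 5, cfg, seed = 3)
  bb <- cfg$chart$bbox
  expect_equal(sum(res$labels[bb["ymin"]:bb["ymax"], bb["xmin"]:bb["xmax"]]), 0)
  # labels partition the grain pixels: no pixel carries two grains by
  # construction, so per-grain pixel counts sum to the foreground count
  expect_equal(sum(res$labels > 0), sum(table(res$labels[res$labels > 0])))
  expect_equal(sort(unique(as.vector(res$labels))), 0:5)
  expect_identical(render_seed_image(gp[1, ], yp[1, ], 5, cfg, seed = 3)$image,
                   res$image)
})

test_that("placement failure reports the achieved count", {
  cfg <- study_config(n_genotypes = 1, years = 2003,
                      grains_per_image = c(1, 1),
                      image_width = 340, image_height = 260, seed = 1)
  gp <- grainpheno:::make_genotype_params(cfg)
  yp <- grainpheno:::make_year_params(cfg)
  expect_error(render_seed_image(gp[1, ], yp[1, ], 40, cfg, seed = 1,
                                 max_attempts = 30),
               "placed [0-9]+ of 40")
})

test_that("the injected year trend matches its configured correlation", {
  cfg <- study_config(n_genotypes = 25, grains_per_image = c(17, 20),
                      image_width = 520, image_height = 380, seed = 31)
  # brute force on the generator's redness model, no rendering: draw the
  # per-seed redness exactly as render_seed_image does
  gp <- grainpheno:::make_genotype_params(cfg)
  yp <- grainpheno:::make_year_params(cfg)
  set.seed(99)
  reps <- 18
  a <- c(); geno <- c(); rank <- c()
  for (g in seq_len(nrow(gp))) for (y in seq_len(nrow(yp))) {
    a <- c(a, gp$a0[g] + yp$a_shift[y] + rnorm(reps, 0, cfg$redness_noise_sd))
    geno <- c(geno, rep(gp$genotype_id[g], reps))
    rank <- c(rank, rep(yp$rank[y], reps))
  }
  r <- cor(center_by_group(a, geno), rank)
  expect_equal(r, cfg$trend_r_redness, tolerance = 0.05)
})

test_that("the emitted ground-truth table carries the trend", {
  st <- demo_study()
  gt <- st$ground_truth
  r <- cor(center_by_group(gt$redness, gt$genotype_id),
           encode_year(gt$year, year_encoding("YearRank", st$config$years)))
  expect_equal(r, st$config$trend_r_redness, tolerance = 0.08)
})

test_that("germination follows the redness link and stays in range", {
  st <- demo_study()
  link0 <- germination_link(slope = 0, noise_sd = 2, outliers = NULL,
                            n_genotypes = 16)
  g0 <- generate_germination(st$design, st$ground_truth, link0, seed = 2)
  cell_red <- aggregate(redness ~ genotype_id + year, st$ground_truth, mean)
  m0 <- merge(aggregate(percent ~ genotype_id + year, g0, mean), cell_red)
  ym <- tapply(m0$percent, m0$year, mean)
  centered <- m0$percent - ym[as.character(m0$year)]
  red_c <- m0$redness - tapply(m0$redness, m0$year, mean)[as.character(m0$year)]
  expect_lt(abs(cor(centered, red_c)), 0.25)   # null link, 64 cells

  link_neg <- germination_link(slope = -3, noise_sd = 1, outliers = NULL,
                               n_genotypes = 16)
  gn <- generate_germination(st$design, st$ground_truth, link_neg, seed = 2)
  mn <- merge(aggregate(percent ~ genotype_id + year, gn, mean), cell_red)
  centered <- mn$percent - tapply(mn$percent, mn$year, mean)[as.character(mn$year)]
  red_c <- mn$redness - tapply(mn$redness, mn$year, mean)[as.character(mn$year)]
  expect_lt(cor(centered, red_c), -0.5)

  expect_true(all(gn$percent >= 0 & gn$percent <= 100))
  expect_equal(nrow(gn), 16 * 4 * 4)  # genotype x year x replicate
  expect_error(generate_germination(st$design[1, ], st$ground_truth),
               "absent from the design")
})
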