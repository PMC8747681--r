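study_years <- c(2003, 2004, 2009, 2014)

test_that("the three year encodings match their definitions", {
  expect_equal(encode_year(study_years, year_encoding("YearRank", study_years)),
               c(1, 2, 3, 4))
  expect_equal(encode_year(study_years, year_encoding("Year01", study_years)),
               c(0, 0, 1, 1))
  expect_equal(encode_year(study_years, year_encoding("Year", study_years)),
               study_years)
  expect_equal(encode_year(c(2009, 2003, 2009),
                           year_encoding("YearRank", study_years)),
               c(3, 1, 3))
  expect_error(encode_year(1999, year_encoding("YearRank", study_years)),
               "unknown year")
})

test_that("group centering removes group means exactly", {
  expect_equal(center_by_group(c(1, 2, 3), rep("a", 3)), c(-1, 0, 1))
  expect_equal(center_by_group(c(5, 9), c("a", "b")), c(0, 0))
  set.seed(1)
  v <- rnorm(60); g <- sample(letters[1:5], 60, replace = TRUE)
  res <- center_by_group(v, g)
  expect_equal(as.numeric(tapply(res, g, sum)), rep(0, 5), tolerance = 1e-12)
  expect_error(center_by_group(1:3, 1:2), "same length")
})

test_that("one-way ANOVA agrees with hand sums and with aov", {
  res <- one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$F, 13.5)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 4)
  set.seed(4)
  v <- rnorm(40, rep(c(0, 1, 3), length.out = 40))
  f <- factor(rep(c("a", "b", "c"), length.out = 40))
  mine <- one_way_anova(v, f)
  ref <- anova(stats::aov(v ~ f))  # independent route
  expect_equal(mine$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 1e-10)

  expect_equal(one_way_anova(c(1, 2, 1, 2), c("a", "a", "b", "b"))$F, 0)
  expect_error(one_way_anova(1:4, rep("a", 4)), "at least 2")
  flat <- one_way_anova(rep(2, 4), c("a", "a", "b", "b"))
  expect_true(flat$undefined)
})

test_that("pearson_r matches exact cases and is affine invariant", {
  x <- c(1, 2, 5, 7, 11)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  set.seed(2); y <- rnorm(5)
  expect_equal(pearson_r(3 * x + 10, y), pearson_r(x, y), tolerance = 1e-12)
  expect_warning(r <- pearson_r(rep(1, 5), y), "constant")
  expect_true(is.na(r))
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
})

test_that("the envelope rule flags perfect trends and is deterministic", {
  x <- rep(1:4, each = 44)
  rt <- randomization_test(x, x, n_rep = 2000, seed = 5)
  expect_equal(rt$r_real, 1)
  expect_true(rt$significant)
  expect_lt(rt$perm_max, 1)
  expect_lt(rt$boot_max, 1)
  expect_lte(rt$perm_min, rt$perm_max)
  expect_lte(rt$boot_min, rt$boot_max)
  expect_true(all(abs(c(rt$perm_min, rt$perm_max, rt$boot_min, rt$boot_max)) <= 1))

  rt2 <- randomization_test(x, x, n_rep = 2000, seed = 5)
  expect_identical(unclass(rt), unclass(rt2))

  y <- -x + rnorm(176, 0, 0.5)
  expect_true(randomization_test(x, y, seed = 1)$significant)
  expect_error(randomization_test(x[1:5], x[1:5]), "n >= 10")
  expect_error(randomization_test(x, rep(1, 176)), "constant")
})

test_that("null data is almost never declared significant", {
  x <- rep(1:4, each = 44)
  set.seed(77)
  hits <- 0
  for (i in 1:60) {
    rt <- randomization_test(x, rnorm(176), n_rep = 500, seed = i)
    hits <- hits + rt$significant
  }
  expect_lte(hits, 1)  # rule's type-I error is about 2/(n_rep+1)
})

test_that("trend analysis recovers the generator's correlation from ground truth", {
  st <- demo_study()
  gt <- st$ground_truth
  tab <- data.frame(genotype_id = gt$genotype_id, year = gt$year,
                    redness = gt$redness, lightness = gt$lightness)
  res <- year_trend_analysis(tab, traits = c("redness", "lightness"),
                             n_rep = 1000, seed = 1)
  expect_equal(nrow(res), 2 * 3)  # traits x schemes
  rr <- res[res$trait == "redness" & res$scheme == "YearRank", ]
  expect_equal(rr$r, st$config$trend_r_redness, tolerance = 0.1)
  expect_true(rr$significant)
  # encodings agree to well within 0.1 on a monotone effect
  rs <- res$r[res$trait == "redness"]
  expect_lt(max(rs) - min(rs), 0.1)
  rl <- res[res$trait == "lightness" & res$scheme == "YearRank", ]
  expect_equal(rl$r, st$config$trend_r_lightness, tolerance = 0.12)
})

test_that("trend analysis also runs on genotype-year means", {
  st <- demo_study()
  gt <- st$ground_truth
  tab <- data.frame(genotype_id = gt$genotype_id, year = gt$year,
                    redness = gt$redness)
  res <- year_trend_analysis(tab, traits = "redness", n_rep = 500,
                             unit = "genotype_year")
  rr <- res[res$scheme == "YearRank", ]
  # aggregation averages away seed noise, so |r| grows
  expect_lt(rr$r, st$config$trend_r_redness + 0.05)
  expect_true(rr$significant)
})

test_that("germination analysis applies the exclusion rule arithmetic", {
  # two years; year A has mean 64.9 by construction
  genos <- sprintf("G%02d", 1:10)
  germ <- rbind(
    data.frame(genotype_id = genos, year = 2009,
               replicate = 1, percent = c(80, 70, rep(64.0625, 8))),
    data.frame(genotype_id = genos, year = 2014,
               replicate = 1, percent = rep(90, 10)))
  # year-2009 mean = (80 + 70 + 8 * 64.0625) / 10 = 66.25; make it 64.9:
  germ$percent[3:10] <- (64.9 * 10 - 80 - 70) / 8
  traits <- do.call(rbind, lapply(genos, function(g)
    data.frame(genotype_id = g, year = c(2009, 2014),
               sL = rnorm(2, 6), Lab_ma = rnorm(2, 137))))
  res <- germination_analysis(germ, traits, traits = c("sL", "Lab_ma"),
                              n_rep = 100, seed = 1)
  ex <- res$excluded_cells
  # 80 - 64.9 = 15.1 -> excluded; 70 - 64.9 = 5.1 -> retained
  expect_equal(nrow(ex), 1)
  expect_equal(ex$genotype_id, "G01")
  expect_equal(ex$centered_mean, 15.1, tolerance = 1e-9)
  expect_false("G02" %in% ex$genotype_id)
  # retained seeds: all cells except (G01, 2009)
  expect_equal(res$n_seeds, 19)
  expect_true(all(c("genotype", "year") %in% names(res$anova)))
})

test_that("germination analysis recovers a planted redness link", {
  st <- demo_study()
  tt <- demo_traits()
  germ <- generate_germination(st$design, st$ground_truth,
                               germination_link(n_genotypes = 16), seed = 4)
  res <- germination_analysis(germ, tt, n_rep = 1000, seed = 2)
  cors <- res$correlations
  worst <- cors$trait[which.min(cors$r)]
  expect_true(worst %in% c("Lab_ma", "Lab_dCa_1", "Lab_dCa_2", "Lab_dCa_3"))
  expect_true(cors$significant[cors$trait == "Lab_ma"])
  expect_lt(cors$r[cors$trait == "Lab_ma"], 0)
  # exclusions are exactly the cells outside the central interval
  expect_true(all(abs(res$cells$centered_mean[res$cells$excluded]) > 15))
  expect_true(all(abs(res$cells$centered_mean[!res$cells$excluded]) <= 15))
})
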