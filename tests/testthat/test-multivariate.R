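test_that("standardize yields unit z-scores and drops constant columns", {
  set.seed(6)
  x <- cbind(a = rnorm(30, 5, 3), b = runif(30, 0, 100), c = rnorm(30))
  z <- standardize(x)
  expect_equal(unname(colMeans(z)), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 3), tolerance = 1e-10)
  expect_equal(standardize(z), z, tolerance = 1e-10, ignore_attr = TRUE)
  expect_warning(z2 <- standardize(cbind(x, k = rep(2, 30))), "constant")
  expect_equal(ncol(z2), 3)
  expect_equal(attr(z2, "dropped"), "k")
  expect_error(standardize(matrix(1, 5, 2)), "all columns are constant")
})

test_that("genotype means conserve the grand mean and row count", {
  tt <- demo_traits()
  gm <- genotype_trait_means(tt)
  expect_equal(nrow(gm), 16)
  counts <- table(tt$genotype_id)[rownames(gm)]
  expect_equal(colSums(gm * as.numeric(counts)) / nrow(tt),
               colMeans(as.matrix(tt[colnames(gm)])), tolerance = 1e-10)
  one <- tt[1, ]
  gm1 <- genotype_trait_means(one)
  expect_equal(as.numeric(gm1), as.numeric(one[colnames(gm1)]))
})

test_that("UPGMA reproduces the worked 3-point example and ultrametrics", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 2
  d["A", "C"] <- d["C", "A"] <- 4
  d["B", "C"] <- d["C", "B"] <- 4
  tr <- upgma_tree(d)
  expect_equal(sort(tr$heights), c(1, 2))
  first <- cutree(tr$hclust, k = 2)
  expect_equal(first[["A"]], first[["B"]])
  expect_false(first[["A"]] == first[["C"]])
  # cophenetic round trip is exact on ultrametric input
  co <- as.matrix(cophenetic(tr$hclust))[rownames(d), rownames(d)]
  expect_equal(co, d, tolerance = 1e-12, ignore_attr = TRUE)
  expect_match(tr$newick, "^\\(")
  expect_equal(sort(ape::read.tree(text = tr$newick)$tip.label),
               c("A", "B", "C"))

  d2 <- as.dist(matrix(c(0, 3, 3, 0), 2,
                       dimnames = list(c("x", "y"), c("x", "y"))))
  tr2 <- upgma_tree(d2)
  expect_equal(tr2$heights, 1.5)

  expect_error(upgma_tree(matrix(c(0, 1, 2, 0), 2), is_dist = TRUE),
               "symmetric")
})

test_that("merge heights never decrease", {
  set.seed(12)
  x <- matrix(rnorm(40 * 6), 40)
  tr <- upgma_tree(x)
  expect_true(all(diff(tr$heights) >= -1e-12))
})

test_that("cluster cutting covers the edge ks and recovers blobs", {
  set.seed(13)
  centers <- rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 8))
  x <- do.call(rbind, lapply(1:3, function(i)
    sweep(matrix(rnorm(15 * 3, sd = 0.5), 15), 2, centers[i, ], "+")))
  rownames(x) <- paste0("g", 1:45)
  tr <- upgma_tree(x, standardize_cols = FALSE)
  expect_equal(unname(cut_clusters(tr, 1)), rep(1, 45))
  expect_equal(length(unique(cut_clusters(tr, 45))), 45)
  cl <- cut_clusters(tr, 3)
  truth <- rep(1:3, each = 15)
  expect_equal(length(unique(cl)), 3)
  for (i in 1:3) expect_equal(length(unique(cl[truth == i])), 1)
  expect_error(cut_clusters(tr, 0), "k must be")
})

test_that("LDA finds the separating axis and matches MASS", {
  set.seed(14)
  n <- 60
  cl <- rep(c("a", "b"), each = n / 2)
  x <- cbind(rnorm(n, ifelse(cl == "a", 0, 4)), rnorm(n))
  colnames(x) <- c("v1", "v2")
  lb <- lda_biplot(x, cl)
  expect_equal(ncol(lb$scores), 1)   # n_classes - 1
  # axis 1 loads on the separated variable, not the noise one
  expect_gt(abs(lb$loadings["v1", 1]), 0.9)
  expect_lt(abs(lb$loadings["v2", 1]), 0.5)
  expect_true(abs(diff(lb$class_means)) > 2)

  ref <- MASS::lda(scale(x), grouping = cl)  # independent route
  ref_scores <- predict(ref, scale(x))$x
  expect_gt(abs(cor(lb$scores[, 1], ref_scores[, 1])), 0.999)

  set.seed(15)
  cl3 <- rep(c("a", "b", "c"), each = 20)
  x3 <- cbind(rnorm(60, as.integer(factor(cl3)) * 3), rnorm(60), rnorm(60))
  lb3 <- lda_biplot(x3, cl3)
  expect_equal(ncol(lb3$scores), 2)
  cm <- lb3$class_means[, 1]
  expect_true(all(diff(sort(cm)) > 0.5))   # ordered, distinct class means

  expect_error(lda_biplot(x, rep("a", n)), "at least 2 classes")
  expect_error(lda_biplot(x[1:3, ], c("a", "a", "b")), "at least 2 rows")
})

test_that("LDA regularizes a singular within-class scatter", {
  set.seed(16)
  cl <- rep(c("a", "b"), each = 6)
  base <- rnorm(12)
  x <- cbind(base + ifelse(cl == "a", 0, 3), base + ifelse(cl == "a", 0, 3),
             rnorm(12))  # first two columns identical => singular W
  x[, 2] <- x[, 1]
  lb <- lda_biplot(x, cl)
  expect_true(lb$regularized)
  expect_true(all(is.finite(lb$scores)))
})
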