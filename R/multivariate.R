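# Exploratory structure: column standardization, UPGMA (average-linkage)
# clustering with Euclidean distances and Newick export, dendrogram cutting,
# and canonical variates (LDA) biplots computed separately for color and
# size/shape trait sets.

#' Standardize a matrix to z-scores
#'
#' Columns are centered and scaled to unit SD. Zero-variance columns carry
#' no information for Euclidean distances or LDA and are dropped with a
#' warning.
#'
#' @param x numeric matrix or data frame (>= 2 rows).
#' @return Matrix with column means 0 and SDs 1; attribute `dropped` lists
#'   removed constant columns.
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows")
  sds <- apply(x, 2, stats::sd)
  drop <- sds == 0 | is.na(sds)
  if (all(drop)) stop("all columns are constant")
  if (any(drop))
    warning("dropping constant column(s): ",
            paste(colnames(x)[drop], collapse = ", "))
  z <- scale(x[, !drop, drop = FALSE])
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  attr(z, "dropped") <- colnames(x)[drop]
  z
}

#' Genotype mean trait matrix
#'
#' Arithmetic mean of every trait per genotype, pooling years and seeds --
#' the item matrix for genotype clustering.
#'
#' @param trait_table per-seed trait table with a `genotype_id` column.
#' @param traits trait columns (default all of [trait_names()] present).
#' @return Numeric matrix, one row per genotype (rownames = genotype ids).
#' @export
genotype_trait_means <- function(trait_table, traits = NULL) {
  if (is.null(traits))
    traits <- intersect(trait_names(), names(trait_table))
  ag <- stats::aggregate(trait_table[traits],
                         by = trait_table["genotype_id"], FUN = mean)
  m <- as.matrix(ag[, -1, drop = FALSE])
  rownames(m) <- ag$genotype_id
  m
}

#' UPGMA dendrogram with Newick export
#'
#' Average-linkage hierarchical clustering. Given a raw item matrix, rows
#' are standardized by column and Euclidean distances computed; a `dist` or
#' symmetric matrix is used as-is. UPGMA trees are ultrametric: merge
#' heights are non-decreasing and the cophenetic distance of two leaves is
#' the height of their lowest common merge.
#'
#' @param x items x variables matrix, a `dist`, or a symmetric distance
#'   matrix.
#' @param labels optional leaf labels (default rownames).
#' @param is_dist force treating a square matrix as distances.
#' @param standardize_cols standardize columns before computing distances
#'   (ignored for distance input).
#' @return Object of class `upgma_tree`: list with `hclust`, `phylo`
#'   ([ape::as.phylo]), `newick` (string with branch lengths = height
#'   differences) and `heights`.
#' @export
upgma_tree <- function(x, labels = NULL, is_dist = FALSE,
                       standardize_cols = TRUE) {
  if (inherits(x, "dist")) {
    d <- x
  } else {
    x <- as.matrix(x)
    square <- nrow(x) == ncol(x) && all(abs(x - t(x)) < 1e-8) &&
      all(diag(x) == 0)
    if (is_dist || square) {
      if (!isTRUE(all.equal(x, t(x), tolerance = 1e-8)))
        stop("distance matrix must be symmetric")
      if (any(x < 0)) stop("distances must be non-negative")
      d <- stats::as.dist(x)
    } else {
      z <- if (standardize_cols) standardize(x) else x
      d <- stats::dist(z)
    }
  }
  hc <- stats::hclust(d, method = "average")
  if (!is.null(labels)) hc$labels <- labels
  if (is.null(hc$labels)) hc$labels <- as.character(seq_len(attr(d, "Size")))
  ph <- ape::as.phylo(hc)
  # ultrametric node heights: two leaves at distance d merge at height d/2,
  # so the leaf-to-leaf path through the tree reproduces d exactly
  structure(list(hclust = hc, phylo = ph,
                 newick = ape::write.tree(ph), heights = hc$height / 2),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("upgma_tree: %d leaves, heights %.3g .. %.3g\n",
              length(x$hclust$labels), min(x$heights), max(x$heights)))
  invisible(x)
}

#' Cut a dendrogram into k clusters
#'
#' Cuts the k - 1 highest merges of the UPGMA tree.
#' @param tree an [upgma_tree()].
#' @param k number of clusters (1..n_leaves).
#' @return Named integer vector of cluster labels.
#' @export
cut_clusters <- function(tree, k) {
  n <- length(tree$hclust$labels)
  if (k < 1 || k > n) stop("k must be in 1..", n)
  stats::cutree(tree$hclust, k = k)
}

#' Canonical variates (LDA) biplot
#'
#' Finds the axes maximizing the ratio of between-class to within-class
#' scatter of the standardized traits: the eigenvectors of W^-1 B, where W
#' is the pooled within-class and B the between-class scatter matrix. If W
#' is singular a ridge (scaled identity) is added and noted. Scores place
#' the items and loadings the traits on the first axes (at most
#' `n_classes - 1`), jointly forming the biplot.
#'
#' @param x items x traits matrix.
#' @param classes class label per row (>= 2 classes, each >= 2 rows).
#' @param n_axes number of axes to keep (default all canonical axes).
#' @param ridge ridge added to W as `ridge * mean(diag(W)) * I` when W is
#'   computationally singular.
#' @return Object of class `lda_biplot`: list with `scores` (items x axes),
#'   `loadings` (traits x axes: correlations of each standardized trait
#'   with the axis scores), `coefficients` (raw discriminant vectors),
#'   `eigenvalues`, `class_means` (class mean scores), `regularized`.
#' @export
lda_biplot <- function(x, classes, n_axes = NULL, ridge = 1e-8) {
  x <- as.matrix(x)
  classes <- factor(classes)
  if (nlevels(classes) < 2L) stop("need at least 2 classes")
  if (any(table(classes) < 2L)) stop("every class needs at least 2 rows")
  z <- standardize(x)
  p <- ncol(z); g <- nlevels(classes)
  grand <- colMeans(z)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (lev in levels(classes)) {
    zi <- z[classes == lev, , drop = FALSE]
    mi <- colMeans(zi)
    W <- W + crossprod(sweep(zi, 2, mi))
    B <- B + nrow(zi) * tcrossprod(mi - grand)
  }
  regularized <- FALSE
  Winv <- tryCatch(solve(W), error = function(e) NULL)
  if (is.null(Winv) || rcond(W) < 1e-12) {
    W <- W + ridge * mean(diag(W)) * diag(p)
    Winv <- solve(W)
    regularized <- TRUE
  }
  ei <- eigen(Winv %*% B)
  k <- min(p, g - 1L)
  if (!is.null(n_axes)) k <- min(k, n_axes)
  vec <- Re(ei$vectors[, seq_len(k), drop = FALSE])
  val <- Re(ei$values[seq_len(k)])
  # scale each axis to unit pooled within-class variance (MASS convention)
  nw <- nrow(z) - g
  for (j in seq_len(k)) {
    s <- sqrt(drop(t(vec[, j]) %*% W %*% vec[, j]) / nw)
    if (s > 0) vec[, j] <- vec[, j] / s
  }
  scores <- sweep(z, 2, grand) %*% vec
  colnames(scores) <- paste0("Axis", seq_len(k))
  loadings <- stats::cor(z, scores)
  cm <- apply(scores, 2, function(s) tapply(s, classes, mean))
  structure(list(scores = scores, loadings = loadings, coefficients = vec,
                 eigenvalues = val, class_means = cm,
                 regularized = regularized, dropped = attr(z, "dropped")),
            class = "lda_biplot")
}

#' @export
print.lda_biplot <- function(x, ...) {
  cat(sprintf("lda_biplot: %d axes, eigenvalues %s%s\n",
              ncol(x$scores),
              paste(signif(x$eigenvalues, 3), collapse = ", "),
              if (x$regularized) " (ridge-regularized)" else ""))
  invisible(x)
}
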