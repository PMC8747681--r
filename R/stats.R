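# Trend inference: harvest-year encodings, genotype centering, one-way
# ANOVA, Pearson correlation, and the permutation + bootstrap extreme-value
# decision rule (2000 replicates each by default): a correlation counts as
# significant only if the observed value falls strictly outside the min-max
# envelope of BOTH randomization tests.

#' Harvest-year encoding schemes
#'
#' Three numeric codings of the calendar harvest year used for trend
#' correlations: `Year01` (0 for the earlier half of the study years, 1 for
#' the later half), `YearRank` (1..n in chronological order, equalizing the
#' unequal gaps between harvests) and `Year` (the calendar year itself).
#'
#' @param name one of `"Year01"`, `"YearRank"`, `"Year"`.
#' @param study_years sorted vector of the study's calendar years.
#' @return Object of class `year_encoding`: list with `name` and `map`
#'   (named numeric vector keyed by year).
#' @examples
#' encode_year(c(2003, 2004, 2009, 2014),
#'             year_encoding("YearRank", c(2003, 2004, 2009, 2014)))
#' @export
year_encoding <- function(name = c("Year01", "YearRank", "Year"),
                          study_years) {
  name <- match.arg(name)
  study_years <- sort(unique(study_years))
  n <- length(study_years)
  codes <- switch(name,
                  Year01 = as.numeric(seq_len(n) > n / 2),
                  YearRank = as.numeric(seq_len(n)),
                  Year = as.numeric(study_years))
  structure(list(name = name,
                 map = stats::setNames(codes, study_years)),
            class = "year_encoding")
}

#' Encode a vector of calendar years under a scheme
#' @param years vector of calendar years (all must be study years).
#' @param scheme a [year_encoding()].
#' @return Numeric vector of codes.
#' @export
encode_year <- function(years, scheme) {
  idx <- match(as.character(years), names(scheme$map))
  if (anyNA(idx))
    stop("unknown year(s): ",
         paste(unique(years[is.na(idx)]), collapse = ", "))
  unname(scheme$map[idx])
}

#' Center values by group
#'
#' Subtracts each group's mean from its values (used to remove the genotype
#' component before trend correlations); per-group residual means are zero.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return Numeric vector of residuals.
#' @export
center_by_group <- function(values, groups) {
  if (length(values) != length(groups))
    stop("values and groups must have the same length")
  gm <- tapply(values, groups, mean)
  as.numeric(values - gm[as.character(groups)])
}

#' One-way ANOVA
#'
#' Standard one-way decomposition of a trait on a single factor (genotype or
#' harvest year are analyzed independently, not as a two-way model), with
#' the F test p-value.
#'
#' @param values numeric vector.
#' @param factor_ grouping factor (>= 2 levels).
#' @return List: `F`, `df_between`, `df_within`, `p`. `F` is `NA` (flagged
#'   via `undefined = TRUE`) when both between- and within-group variances
#'   are zero.
#' @export
one_way_anova <- function(values, factor_) {
  f <- factor(factor_)
  if (nlevels(f) < 2L) stop("need at least 2 factor levels")
  if (length(values) <= nlevels(f))
    stop("need more observations than levels")
  gm <- tapply(values, f, mean)
  n_g <- tabulate(f)
  grand <- mean(values)
  ssb <- sum(n_g * (gm - grand)^2)
  ssw <- sum((values - gm[f])^2)
  dfb <- nlevels(f) - 1L
  dfw <- length(values) - nlevels(f)
  if (ssw == 0 && ssb == 0)
    return(list(F = NA_real_, df_between = dfb, df_within = dfw,
                p = NA_real_, undefined = TRUE))
  Fv <- (ssb / dfb) / (ssw / dfw)
  list(F = Fv, df_between = dfb, df_within = dfw,
       p = stats::pf(Fv, dfb, dfw, lower.tail = FALSE), undefined = FALSE)
}

#' Pearson correlation with validity checks
#'
#' @param x,y numeric vectors of equal length, n >= 3, neither constant.
#'   A constant input yields `NA` with a warning (propagated downstream as
#'   non-significant) rather than an error.
#' @return Correlation coefficient in \[-1, 1\], or `NA`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3L) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Permutation + bootstrap envelope test for a Pearson correlation
#'
#' Runs two randomization experiments of `n_rep` replicates each: a
#' permutation test (shuffle `y`, recompute r) and a null bootstrap
#' (resample `x` and `y` independently with replacement, which destroys
#' their association, and recompute r). The min and max replicate
#' correlations of each experiment form its envelope; the observed
#' correlation is declared significant only if it lies strictly below both
#' minima or strictly above both maxima. Both experiments therefore sample
#' the no-association distribution of r, so a perfectly correlated input
#' always falls outside both envelopes.
#'
#' @param x,y numeric vectors, n >= 10.
#' @param n_rep replicates per experiment (2000 by convention).
#' @param seed RNG seed.
#' @return Object of class `rand_test`: list with `r_real`, `perm_min`,
#'   `perm_max`, `boot_min`, `boot_max`, `n_rep`, `significant`.
#' @export
randomization_test <- function(x, y, n_rep = 2000, seed = 1L) {
  n <- length(x)
  if (n < 10L) stop("need n >= 10")
  if (n_rep < 1L) stop("n_rep must be >= 1")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  set.seed(seed)
  xs <- (x - mean(x)) / stats::sd(x)
  ys <- (y - mean(y)) / stats::sd(y)
  r_real <- sum(xs * ys) / (n - 1)

  # permutation: y reshuffled; mean/sd are permutation-invariant so each
  # replicate r is a single inner product
  perm_idx <- vapply(seq_len(n_rep), function(i) sample.int(n), integer(n))
  r_perm <- as.numeric(crossprod(xs, matrix(ys[perm_idx], n))) / (n - 1)

  # null bootstrap: x and y resampled independently with replacement,
  # breaking the pairing; per-replicate moments
  X <- matrix(x[sample.int(n, n * n_rep, replace = TRUE)], n)
  Y <- matrix(y[sample.int(n, n * n_rep, replace = TRUE)], n)
  sx <- colMeans(X); sy <- colMeans(Y)
  sxx <- colMeans(X^2) - sx^2
  syy <- colMeans(Y^2) - sy^2
  sxy <- colMeans(X * Y) - sx * sy
  ok <- sxx > 0 & syy > 0
  r_boot <- ifelse(ok, sxy / sqrt(sxx * syy), NA_real_)

  res <- list(r_real = r_real,
              perm_min = min(r_perm), perm_max = max(r_perm),
              boot_min = min(r_boot, na.rm = TRUE),
              boot_max = max(r_boot, na.rm = TRUE),
              n_rep = n_rep)
  res$significant <-
    (r_real < res$perm_min && r_real < res$boot_min) ||
    (r_real > res$perm_max && r_real > res$boot_max)
  structure(res, class = "rand_test")
}

#' @export
print.rand_test <- function(x, ...) {
  cat(sprintf(
    "rand_test: r = %.3f; perm [%.3f, %.3f]; boot [%.3f, %.3f]; %s (%d reps)\n",
    x$r_real, x$perm_min, x$perm_max, x$boot_min, x$boot_max,
    if (x$significant) "significant" else "not significant", x$n_rep))
  invisible(x)
}

#' Year trend analysis over a trait table
#'
#' For every trait and year encoding: center the trait by genotype, encode
#' the year, and compute the Pearson correlation. The randomization envelope
#' test is run on the `YearRank` encoding (the coding used for significance
#' testing); its envelopes and decision are reported on those rows.
#'
#' @param trait_table data frame with `genotype_id`, `year` and trait
#'   columns.
#' @param traits character vector of trait columns (default: all of
#'   [trait_names()] present in the table).
#' @param schemes encodings to evaluate.
#' @param n_rep randomization replicates.
#' @param seed RNG seed (one stream per trait, derived stably).
#' @param unit `"seed"` correlates per-seed rows; `"genotype_year"`
#'   aggregates to genotype x year means first.
#' @return Data frame, one row per trait x scheme: `trait`, `scheme`, `r`,
#'   and for YearRank rows `perm_min`, `perm_max`, `boot_min`, `boot_max`,
#'   `significant`.
#' @export
year_trend_analysis <- function(trait_table, traits = NULL,
                                schemes = c("Year01", "YearRank", "Year"),
                                n_rep = 2000, seed = 1L,
                                unit = c("seed", "genotype_year")) {
  unit <- match.arg(unit)
  if (!all(c("genotype_id", "year") %in% names(trait_table)))
    stop("trait table must have genotype_id and year columns")
  if (length(unique(trait_table$year)) < 2L) stop("need at least 2 years")
  if (is.null(traits))
    traits <- intersect(trait_names(), names(trait_table))
  if (unit == "genotype_year") {
    trait_table <- stats::aggregate(
      trait_table[traits],
      by = trait_table[c("genotype_id", "year")], FUN = mean)
  }
  study_years <- sort(unique(trait_table$year))
  enc <- lapply(schemes, year_encoding, study_years = study_years)
  names(enc) <- schemes
  out <- list()
  for (tr in traits) {
    v <- center_by_group(trait_table[[tr]], trait_table$genotype_id)
    rt <- NULL
    for (sc in schemes) {
      yv <- encode_year(trait_table$year, enc[[sc]])
      r <- if (stats::sd(v) == 0) NA_real_ else pearson_r(v, yv)
      row <- data.frame(trait = tr, scheme = sc, r = r,
                        perm_min = NA_real_, perm_max = NA_real_,
                        boot_min = NA_real_, boot_max = NA_real_,
                        significant = NA)
      if (sc == "YearRank" && !is.na(r)) {
        rt <- randomization_test(yv, v, n_rep = n_rep,
                                 seed = stable_seed(paste0("trend:", tr), seed))
        row[c("perm_min", "perm_max", "boot_min", "boot_max")] <-
          rt[c("perm_min", "perm_max", "boot_min", "boot_max")]
        row$significant <- rt$significant
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Germination correlation analysis
#'
#' Follows the germination workflow: (1) one-way ANOVA of germination on
#' genotype and on year; (2) subtraction of the year mean from every
#' germination value; (3) exclusion of whole genotype-year cells whose
#' year-centered cell mean lies outside \[-15, 15\] (boundary values are
#' retained); (4) joining the retained cells' per-seed traits, each seed
#' carrying its cell's mean germination; (5) Pearson correlation plus the
#' randomization envelope test of (year-centered) germination against every
#' trait.
#'
#' @param germ_table data frame (genotype_id, year, replicate, percent).
#' @param trait_table per-seed trait table from [compute_trait_table()].
#' @param traits trait columns to test (default all present).
#' @param n_rep randomization replicates.
#' @param seed RNG seed.
#' @param outlier_bound half-width of the retained central interval (15).
#' @return List: `anova` (list with `genotype`, `year` one-way results),
#'   `excluded_cells` (genotype-year cells dropped, with centered means),
#'   `correlations` (data frame: trait, r, envelopes, significant, n_seeds),
#'   `n_seeds`.
#' @export
germination_analysis <- function(germ_table, trait_table, traits = NULL,
                                 n_rep = 2000, seed = 1L,
                                 outlier_bound = 15) {
  if (is.null(traits))
    traits <- intersect(trait_names(), names(trait_table))
  av <- list(
    genotype = one_way_anova(germ_table$percent, germ_table$genotype_id),
    year = one_way_anova(germ_table$percent, germ_table$year))

  ym <- tapply(germ_table$percent, germ_table$year, mean)
  centered <- germ_table$percent - unname(ym[as.character(germ_table$year)])
  cells <- stats::aggregate(centered,
                            by = germ_table[c("genotype_id", "year")],
                            FUN = mean)
  names(cells)[3] <- "centered_mean"
  cells$excluded <- abs(cells$centered_mean) > outlier_bound

  keep <- cells[!cells$excluded, ]
  key <- function(g, y) paste(g, y, sep = "\r")
  tt <- trait_table[key(trait_table$genotype_id, trait_table$year) %in%
                      key(keep$genotype_id, keep$year), ]
  if (nrow(tt) == 0L)
    stop("no overlapping genotype-year cells after outlier exclusion")
  germ_seed <- keep$centered_mean[match(key(tt$genotype_id, tt$year),
                                        key(keep$genotype_id, keep$year))]
  out <- list()
  for (tr in traits) {
    v <- tt[[tr]]
    if (stats::sd(v) == 0 || stats::sd(germ_seed) == 0) {
      out[[tr]] <- data.frame(trait = tr, r = NA_real_, perm_min = NA_real_,
                              perm_max = NA_real_, boot_min = NA_real_,
                              boot_max = NA_real_, significant = NA,
                              n_seeds = nrow(tt))
      next
    }
    rt <- randomization_test(germ_seed, v, n_rep = n_rep,
                             seed = stable_seed(paste0("germ:", tr), seed))
    out[[tr]] <- data.frame(trait = tr, r = rt$r_real,
                            perm_min = rt$perm_min, perm_max = rt$perm_max,
                            boot_min = rt$boot_min, boot_max = rt$boot_max,
                            significant = rt$significant, n_seeds = nrow(tt))
  }
  list(anova = av,
       excluded_cells = cells[cells$excluded, c("genotype_id", "year",
                                                "centered_mean")],
       cells = cells,
       correlations = do.call(rbind, c(out, make.row.names = FALSE)),
       n_seeds = nrow(tt))
}
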