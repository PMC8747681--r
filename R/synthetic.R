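# Synthetic study generator. Emulates the study design the statistics are
# meant for: 44 genotypes x 4 harvest years (2003/2004/2009/2014), one image
# per genotype-year with 17-20 non-touching grains on a white background and
# a reference chart, genotype-specific size/shape/color baselines, a monotone
# year-rank trend in coat redness (Lab a) and lightness (Lab L), a per-image
# color cast, and a germination table linearly coupled to coat redness with a
# strongly depressed third year plus planted outlier cells.

# Deterministic 31-bit stream seed from a string tag and the master seed, so
# each image gets a stable RNG stream under partial regeneration.
stable_seed <- function(tag, master) {
  h <- 0
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% 2147483647
  as.integer((h + (master %% 2147483647) * 2654435) %% 2147483647)
}

#' Configuration of a synthetic grain-aging study
#'
#' Collects every knob of the generator: design shape, image geometry, the
#' genotype/year/grain variance components of size and coat color, the target
#' genotype-centered correlation between year rank and coat redness, and
#' rendering noise. Defaults emulate the bread-wheat storage study design:
#' 44 genotypes, harvest years 2003/2004/2009/2014, 17-20 grains per image.
#'
#' The year trend is parameterized by its population correlation. Writing the
#' per-seed redness as \eqn{a = a_g + \beta\,(rank - \bar{rank}) + \epsilon}
#' with \eqn{\epsilon \sim N(0, \sigma^2)}, the genotype-centered correlation
#' with year rank is \eqn{r = \beta s_{rank} / \sqrt{\beta^2 s_{rank}^2 +
#' \sigma^2}}; the slope \eqn{\beta} is solved from the requested `trend_r_redness`
#' and `redness_noise_sd` (and likewise for lightness).
#'
#' @param n_genotypes number of genotypes (inbred lines).
#' @param years strictly increasing calendar harvest years.
#' @param grains_per_image length-2 integer range (min, max) of grains drawn
#'   per image.
#' @param image_width,image_height canvas size in pixels.
#' @param mm_per_px physical scale; the chart pitch is rendered to match.
#' @param grain_length_mm,grain_length_sd_geno,grain_length_sd mean grain
#'   length (mm), genotype SD, residual per-grain SD.
#' @param width_ratio,width_ratio_sd_geno mean width/length ratio and its
#'   genotype SD.
#' @param year_size_sd SD of the random (non-monotone) per-year size shift (mm).
#' @param coat_L,coat_a,coat_b mean coat color, 8-bit Lab convention.
#' @param coat_L_sd_geno,coat_a_sd_geno,coat_b_sd_geno genotype SDs.
#' @param trend_r_redness target genotype-centered correlation between year
#'   rank and per-seed coat redness (Lab a); negative means later years are
#'   less red.
#' @param redness_noise_sd per-seed redness SD around the genotype/year mean.
#' @param trend_r_lightness,lightness_noise_sd same for Lab L.
#' @param b_noise_sd per-seed SD of Lab b (no year trend).
#' @param shading_strength relative darkening at the grain edge (radial
#'   shading that mimics the grain's 3D shape).
#' @param boundary_amp range of the low-frequency sinusoidal boundary
#'   perturbation amplitudes (fraction of the local ellipse radius).
#' @param background,background_noise_sd white background level and noise SD.
#' @param pixel_noise_sd per-pixel per-channel noise SD on grain pixels.
#' @param cast_gain_range per-image diagonal color cast gains are drawn
#'   uniformly from this range; set `cast_matrix` for a fixed 3 x 3 cast.
#'   The default stays below the gain that would saturate the chart's white
#'   patch (as a photographer adjusts lighting to avoid clipping), so the
#'   affine correction can invert the cast exactly.
#' @param cast_matrix optional fixed 3 x 3 linear cast applied to the whole
#'   image (grains and chart alike) before quantization; `NULL` = random
#'   diagonal per image, `diag(3)` = no cast.
#' @param chart a [build_chart_layout()] object; by default built to match
#'   `mm_per_px`.
#' @param seed master RNG seed for the whole study.
#' @return Object of class `study_config` (a validated list).
#' @export
study_config <- function(n_genotypes = 44,
                         years = c(2003, 2004, 2009, 2014),
                         grains_per_image = c(17, 20),
                         image_width = 900, image_height = 640,
                         mm_per_px = 0.1,
                         grain_length_mm = 6.5, grain_length_sd_geno = 0.45,
                         grain_length_sd = 0.22,
                         width_ratio = 0.48, width_ratio_sd_geno = 0.035,
                         year_size_sd = 0.25,
                         coat_L = 156, coat_a = 137, coat_b = 158,
                         coat_L_sd_geno = 5, coat_a_sd_geno = 2.5,
                         coat_b_sd_geno = 4,
                         trend_r_redness = -0.6, redness_noise_sd = 1.8,
                         trend_r_lightness = -0.2, lightness_noise_sd = 4,
                         b_noise_sd = 1.5,
                         shading_strength = 0.18,
                         boundary_amp = c(0.01, 0.05),
                         background = 250, background_noise_sd = 2,
                         pixel_noise_sd = 2,
                         cast_gain_range = c(0.92, 1.04),
                         cast_matrix = NULL,
                         chart = NULL,
                         seed = 1L) {
  cfg <- structure(as.list(environment()), class = "study_config")
  validate_study_config(cfg)
  if (is.null(chart))
    cfg$chart <- build_chart_layout(pitch_px = 4 / mm_per_px, pitch_mm = 4,
                                    patch_halfwidth_px = round(1.4 / mm_per_px))
  cfg
}

validate_study_config <- function(cfg) {
  stopifnot(cfg$n_genotypes >= 1)
  if (length(cfg$years) < 1 || is.unsorted(cfg$years, strictly = TRUE))
    stop("years must be strictly increasing")
  g <- cfg$grains_per_image
  if (length(g) != 2 || g[1] < 1 || g[2] < g[1])
    stop("grains_per_image must be a range (min, max) with min >= 1")
  if (cfg$mm_per_px <= 0) stop("mm_per_px must be positive")
  sds <- c(cfg$grain_length_sd_geno, cfg$grain_length_sd, cfg$year_size_sd,
           cfg$coat_L_sd_geno, cfg$coat_a_sd_geno, cfg$coat_b_sd_geno,
           cfg$redness_noise_sd, cfg$lightness_noise_sd, cfg$b_noise_sd,
           cfg$background_noise_sd, cfg$pixel_noise_sd, cfg$width_ratio_sd_geno)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (abs(cfg$trend_r_redness) >= 1 || abs(cfg$trend_r_lightness) >= 1)
    stop("trend correlations must lie in (-1, 1)")
  invisible(cfg)
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(paste0(
    "study_config: %d genotypes x %d years (%s), %d-%d grains/image,\n",
    "  %dx%d px at %.3g mm/px, redness trend r = %.2f, seed %d\n"),
    x$n_genotypes, length(x$years), paste(x$years, collapse = "/"),
    x$grains_per_image[1], x$grains_per_image[2],
    x$image_width, x$image_height, x$mm_per_px, x$trend_r_redness, x$seed))
  invisible(x)
}

# Trend slope per unit year rank from a target genotype-centered correlation
# and the residual SD: r^2 = b^2 s^2 / (b^2 s^2 + sigma^2).
trend_slope <- function(r, noise_sd, ranks) {
  s_rank <- sqrt(mean((ranks - mean(ranks))^2))
  if (r == 0 || s_rank == 0) return(0)
  sign(r) * abs(r) * noise_sd / (s_rank * sqrt(1 - r^2))
}

# Genotype-level baselines, drawn once from the master seed.
make_genotype_params <- function(cfg) {
  set.seed(stable_seed("genotypes", cfg$seed))
  n <- cfg$n_genotypes
  data.frame(
    genotype_id = sprintf("G%03d", seq_len(n)),
    length_mm = rnorm(n, cfg$grain_length_mm, cfg$grain_length_sd_geno),
    width_ratio = pmax(0.3, rnorm(n, cfg$width_ratio, cfg$width_ratio_sd_geno)),
    L0 = rnorm(n, cfg$coat_L, cfg$coat_L_sd_geno),
    a0 = rnorm(n, cfg$coat_a, cfg$coat_a_sd_geno),
    b0 = rnorm(n, cfg$coat_b, cfg$coat_b_sd_geno))
}

# Year-level effects: a random (non-monotone) size shift, and monotone
# rank-linear shifts of redness and lightness solved from the target r.
make_year_params <- function(cfg) {
  set.seed(stable_seed("years", cfg$seed))
  ranks <- seq_along(cfg$years)
  beta_a <- trend_slope(cfg$trend_r_redness, cfg$redness_noise_sd, ranks)
  beta_L <- trend_slope(cfg$trend_r_lightness, cfg$lightness_noise_sd, ranks)
  data.frame(
    year = cfg$years, rank = ranks,
    size_shift = rnorm(length(ranks), 0, cfg$year_size_sd),
    a_shift = beta_a * (ranks - mean(ranks)),
    L_shift = beta_L * (ranks - mean(ranks)))
}

#' Render one synthetic seed-scatter image
#'
#' Draws `n_grains` ellipse-like grains (low-frequency sinusoidal boundary
#' perturbation, radial shading) scattered without touching on a noisy white
#' background, with the reference chart at its fixed location, then applies a
#' global linear color cast to the whole image and quantizes to 8 bits.
#' Grain placement is by rejection sampling of bounding circles.
#'
#' @param genotype one row of the genotype parameter table (columns
#'   `genotype_id`, `length_mm`, `width_ratio`, `L0`, `a0`, `b0`).
#' @param yearp one row of the year parameter table (columns `year`, `rank`,
#'   `size_shift`, `a_shift`, `L_shift`).
#' @param n_grains number of grains to place (>= 1).
#' @param config a [study_config()].
#' @param seed RNG seed for this image's stream.
#' @param max_attempts placement attempts per grain before giving up.
#' @return List with `image` (H x W x 3 integer array, 0-255), `labels`
#'   (H x W integer matrix, 0 = background, i = grain i; the ground-truth
#'   masks), `grains` (data frame: grain_id, length_mm, width_mm, true_R/G/B
#'   of the unshaded coat color before cast, redness = true Lab a, lightness
#'   = true Lab L) and `cast` (the 3 x 3 matrix applied).
#' @export
render_seed_image <- function(genotype, yearp, n_grains, config,
                              seed = config$seed, max_attempts = 600) {
  stopifnot(n_grains >= 1)
  set.seed(seed)
  H <- config$image_height; W <- config$image_width
  canvas <- array(config$background +
                    rnorm(H * W * 3, 0, config$background_noise_sd),
                  dim = c(H, W, 3))
  canvas <- render_chart(canvas, config$chart)
  labels <- matrix(0L, H, W)
  bb <- config$chart$bbox
  margin <- 4
  placed <- matrix(numeric(0), 0, 3)  # cx, cy, radius
  gt <- vector("list", n_grains)

  for (i in seq_len(n_grains)) {
    len_mm <- genotype$length_mm + yearp$size_shift +
      rnorm(1, 0, config$grain_length_sd)
    wid_mm <- len_mm * genotype$width_ratio + rnorm(1, 0, 0.06)
    len_mm <- max(len_mm, 2.5); wid_mm <- min(max(wid_mm, 1.5), len_mm)
    a_px <- len_mm / 2 / config$mm_per_px
    b_px <- wid_mm / 2 / config$mm_per_px
    amp <- runif(2, config$boundary_amp[1], config$boundary_amp[2])
    phase <- runif(2, 0, 2 * pi)
    phi <- runif(1, 0, pi)
    rmax <- a_px * (1 + sum(amp)) + 1
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      cx <- runif(1, rmax + margin, W - rmax - margin)
      cy <- runif(1, rmax + margin, H - rmax - margin)
      in_chart <- cx + rmax > bb["xmin"] && cx - rmax < bb["xmax"] &&
        cy + rmax > bb["ymin"] && cy - rmax < bb["ymax"]
      if (in_chart) next
      if (nrow(placed) > 0) {
        dd <- sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2)
        if (any(dd < placed[, 3] + rmax + 6)) next
      }
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf("grain placement failed after %d attempts: placed %d of %d grains",
                   max_attempts, i - 1L, n_grains))
    placed <- rbind(placed, c(cx, cy, rmax))

    # coat color in Lab8: genotype baseline + year trend + per-seed noise
    Lv <- genotype$L0 + yearp$L_shift + rnorm(1, 0, config$lightness_noise_sd)
    av <- genotype$a0 + yearp$a_shift + rnorm(1, 0, config$redness_noise_sd)
    bv <- genotype$b0 + rnorm(1, 0, config$b_noise_sd)
    base_rgb <- as.numeric(lab8_to_rgb(cbind(Lv, av, bv)))

    # rasterize: perturbed ellipse in a local bounding box
    xs <- max(1, floor(cx - rmax)):min(W, ceiling(cx + rmax))
    ys <- max(1, floor(cy - rmax)):min(H, ceiling(cy + rmax))
    dx <- outer(rep(1, length(ys)), xs - cx)
    dy <- outer(ys - cy, rep(1, length(xs)))
    u <- dx * cos(phi) + dy * sin(phi)
    v <- -dx * sin(phi) + dy * cos(phi)
    theta <- atan2(v, u)
    re <- a_px * b_px / sqrt((b_px * cos(theta))^2 + (a_px * sin(theta))^2)
    rb <- re * (1 + amp[1] * sin(2 * theta + phase[1]) +
                  amp[2] * sin(3 * theta + phase[2]))
    rho <- sqrt(u^2 + v^2)
    inside <- rho <= rb
    shade <- 1 - config$shading_strength * (rho / rb)^2
    idx <- which(inside, arr.ind = TRUE)
    npx <- nrow(idx)
    for (ch in 1:3) {
      vals <- base_rgb[ch] * shade[inside] +
        rnorm(npx, 0, config$pixel_noise_sd)
      canvas[cbind(ys[idx[, 1]], xs[idx[, 2]], ch)] <- vals
    }
    labels[cbind(ys[idx[, 1]], xs[idx[, 2]])] <- i
    gt[[i]] <- data.frame(grain_id = i, length_mm = len_mm, width_mm = wid_mm,
                          true_R = base_rgb[1], true_G = base_rgb[2],
                          true_B = base_rgb[3], redness = av, lightness = Lv)
  }

  cast <- config$cast_matrix
  if (is.null(cast)) cast <- diag(runif(3, config$cast_gain_range[1],
                                        config$cast_gain_range[2]))
  flat <- matrix(canvas, ncol = 3)
  flat <- flat %*% t(cast)
  img <- array(as.integer(pmin(pmax(round(flat), 0), 255)), dim = c(H, W, 3))
  list(image = img, labels = labels, grains = do.call(rbind, gt), cast = cast)
}

#' Generate a full synthetic study (images, design and ground-truth tables)
#'
#' One image per genotype x year, rendered with [render_seed_image()] under a
#' per-image RNG stream derived from the master seed by stable hashing of
#' (genotype, year), so the bundle is fully reproducible and individual
#' images can be regenerated in isolation.
#'
#' @param config a [study_config()].
#' @param outdir output directory; created if needed. Images go to
#'   `images/`, tables to `design.csv` and `ground_truth.csv`.
#' @param write_masks also write the ground-truth label masks as 8-bit
#'   grayscale PNGs (`masks/`, pixel value = grain id).
#' @param keep_masks keep the label matrices in the returned object (memory
#'   permitting); used by segmentation accuracy checks.
#' @param verbose print progress.
#' @return Invisibly, a list with `design` (image_id, image_path,
#'   genotype_id, year), `ground_truth` (one row per grain, incl. true coat
#'   color and the redness scalar used for the germination link),
#'   `genotype_params`, `year_params`, `config`, `dir`, and `masks` (list of
#'   label matrices, if kept).
#' @export
generate_study <- function(config = study_config(), outdir,
                           write_masks = FALSE, keep_masks = FALSE,
                           verbose = FALSE) {
  validate_study_config(config)
  dir.create(file.path(outdir, "images"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  if (write_masks)
    dir.create(file.path(outdir, "masks"), showWarnings = FALSE)
  gp <- make_genotype_params(config)
  yp <- make_year_params(config)
  design <- list(); gt <- list(); masks <- list()
  for (gi in seq_len(nrow(gp))) {
    for (yi in seq_len(nrow(yp))) {
      image_id <- sprintf("%s_%d", gp$genotype_id[gi], yp$year[yi])
      sd_img <- stable_seed(image_id, config$seed)
      set.seed(sd_img)
      g <- config$grains_per_image
      n_grains <- if (g[1] == g[2]) g[1] else sample(g[1]:g[2], 1)
      res <- render_seed_image(gp[gi, ], yp[yi, ], n_grains, config,
                               seed = stable_seed(paste0(image_id, ":render"),
                                                  config$seed))
      path <- file.path(outdir, "images", paste0(image_id, ".png"))
      png::writePNG(aperm(res$image, c(1, 2, 3)) / 255, path)
      if (write_masks)
        png::writePNG(res$labels / 255,
                      file.path(outdir, "masks", paste0(image_id, "_mask.png")))
      if (keep_masks) masks[[image_id]] <- res$labels
      design[[image_id]] <- data.frame(
        image_id = image_id, image_path = path,
        genotype_id = gp$genotype_id[gi], year = yp$year[yi])
      gt[[image_id]] <- cbind(image_id = image_id,
                              genotype_id = gp$genotype_id[gi],
                              year = yp$year[yi], res$grains)
      if (verbose) message("rendered ", image_id, " (", n_grains, " grains)")
    }
  }
  design <- do.call(rbind, c(design, make.row.names = FALSE))
  gt <- do.call(rbind, c(gt, make.row.names = FALSE))
  utils::write.csv(design, file.path(outdir, "design.csv"), row.names = FALSE)
  utils::write.csv(gt, file.path(outdir, "ground_truth.csv"), row.names = FALSE)
  invisible(list(design = design, ground_truth = gt, genotype_params = gp,
                 year_params = yp, config = config, dir = outdir,
                 masks = if (keep_masks) masks))
}

#' Germination link parameters
#'
#' Defines how the synthetic germination table is coupled to coat redness.
#' Germination for a genotype-year cell is
#' `year_mean + slope * (cell_redness - year_mean_redness) + outlier_shift`,
#' plus per-replicate noise, clipped to \[0, 100\]. Defaults emulate the
#' observed year pattern (third year strongly depressed with outlier
#' accessions in both directions, two low outliers in the last year).
#'
#' @param year_means expected germination percent per study year, in year
#'   order; recycled/truncated to the number of years.
#' @param slope percent germination per unit coat redness (8-bit Lab a);
#'   negative = redder grains germinate worse.
#' @param noise_sd per-replicate noise SD (percent).
#' @param replicates replicate tests per genotype-year.
#' @param n_genotypes how many genotypes (the first n in the design) have
#'   germination tests.
#' @param outliers data frame with columns `year_index`, `n`, `shift_lo`,
#'   `shift_hi`: how many cells in that year get a uniform shift drawn from
#'   \[shift_lo, shift_hi\]. Set to `NULL` for no outliers.
#' @export
germination_link <- function(year_means = c(92.0, 98.6, 64.9, 88.2),
                             slope = -1.5, noise_sd = 3, replicates = 4,
                             n_genotypes = 19,
                             outliers = data.frame(
                               year_index = c(3, 3, 4),
                               n = c(5, 3, 2),
                               shift_lo = c(-30, 18, -25),
                               shift_hi = c(-20, 25, -18))) {
  stopifnot(is.finite(slope), is.finite(noise_sd), noise_sd >= 0,
            replicates >= 1)
  structure(list(year_means = year_means, slope = slope, noise_sd = noise_sd,
                 replicates = replicates, n_genotypes = n_genotypes,
                 outliers = outliers), class = "germination_link")
}

#' Generate a synthetic germination table linked to coat redness
#'
#' One row per genotype x year x replicate for the first `n_genotypes`
#' genotypes of the design. The cell mean follows the year mean plus a linear
#' effect of the cell's mean ground-truth redness (so the link operates on
#' the generator's redness scalar, independent of the imaging pipeline),
#' plus planted outlier shifts.
#'
#' @param design design table from [generate_study()].
#' @param ground_truth ground-truth grain table from [generate_study()].
#' @param link a [germination_link()].
#' @param seed RNG seed.
#' @return Data frame (genotype_id, year, replicate, percent) with attribute
#'   `"outlier_cells"` (data frame of the planted outlier genotype-years and
#'   shifts).
#' @export
generate_germination <- function(design, ground_truth,
                                 link = germination_link(), seed = 1L) {
  keys_d <- unique(paste(design$genotype_id, design$year))
  keys_g <- unique(paste(ground_truth$genotype_id, ground_truth$year))
  if (!all(keys_g %in% keys_d))
    stop("ground truth contains genotype-year cells absent from the design")
  set.seed(stable_seed("germination", seed))
  genos <- sort(unique(design$genotype_id))
  genos <- genos[seq_len(min(link$n_genotypes, length(genos)))]
  years <- sort(unique(design$year))
  ym <- rep_len(link$year_means, length(years))
  gt <- ground_truth[ground_truth$genotype_id %in% genos, ]
  cell <- stats::aggregate(redness ~ genotype_id + year, data = gt, FUN = mean)

  shift <- stats::setNames(numeric(nrow(cell)),
                           paste(cell$genotype_id, cell$year))
  planted <- NULL
  if (!is.null(link$outliers)) {
    for (k in seq_len(nrow(link$outliers))) {
      o <- link$outliers[k, ]
      if (o$year_index > length(years)) next
      yr <- years[o$year_index]
      avail <- cell$genotype_id[cell$year == yr &
                                  shift[paste(cell$genotype_id, yr)] == 0]
      pick <- sample(avail, min(o$n, length(avail)))
      for (g in pick) {
        s <- runif(1, o$shift_lo, o$shift_hi)
        shift[paste(g, yr)] <- s
        planted <- rbind(planted,
                         data.frame(genotype_id = g, year = yr, shift = s))
      }
    }
  }

  out <- list()
  for (i in seq_len(nrow(cell))) {
    g <- cell$genotype_id[i]; yr <- cell$year[i]
    yi <- match(yr, years)
    mu_red <- mean(cell$redness[cell$year == yr])
    base <- ym[yi] + link$slope * (cell$redness[i] - mu_red) +
      shift[paste(g, yr)]
    pct <- pmin(pmax(base + rnorm(link$replicates, 0, link$noise_sd), 0), 100)
    out[[i]] <- data.frame(genotype_id = g, year = yr,
                           replicate = seq_len(link$replicates), percent = pct)
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(res, "outlier_cells") <- planted
  res
}
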