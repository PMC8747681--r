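# Shared fixtures, all built in code.

# Dense regular polygon approximating a circle.
circle_polygon <- function(r = 1, n = 2000, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# Dense polygon approximating an ellipse with semi-axes a, b.
ellipse_polygon <- function(a = 2, b = 1, n = 3600) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(a * cos(th), b * sin(th))
}

# Plus-pentomino: five unit squares in a cross; 12-vertex rectilinear polygon.
plus_pentomino <- function() {
  cbind(c(1, 2, 2, 3, 3, 2, 2, 1, 1, 0, 0, 1),
        c(0, 0, 1, 1, 2, 2, 3, 3, 2, 2, 1, 1))
}

# Binary mask of a disk of radius r px (center of a square matrix).
disk_mask <- function(r = 100, pad = 20) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  xy <- expand.grid(row = 1:n, col = 1:n)
  m <- matrix(0, n, n)
  m[(xy$row - ctr)^2 + (xy$col - ctr)^2 <= r^2] <- 1
  m
}

# Pixel set with three flat color regions at the given fractions of n.
three_region_pixels <- function(colors = rbind(c(200, 60, 60),
                                               c(60, 200, 60),
                                               c(60, 60, 200)),
                                fractions = c(0.5, 0.3, 0.2), n = 1000) {
  counts <- round(fractions * n)
  do.call(rbind, lapply(seq_len(nrow(colors)), function(i)
    matrix(colors[i, ], counts[i], 3, byrow = TRUE)))
}

# Small demo study shared by the heavier end-to-end tests; generated once
# per test run and cached in a package-local environment.
.demo_cache <- new.env(parent = emptyenv())

demo_study <- function() {
  if (is.null(.demo_cache$study)) {
    cfg <- study_config(n_genotypes = 16, grains_per_image = c(8, 10),
                        image_width = 640, image_height = 460, seed = 421L)
    dir <- file.path(tempdir(), "grainpheno-demo-study")
    .demo_cache$study <- generate_study(cfg, dir, keep_masks = TRUE)
  }
  .demo_cache$study
}

demo_traits <- function() {
  if (is.null(.demo_cache$traits)) {
    st <- demo_study()
    .demo_cache$traits <- compute_trait_table(st$design, st$config$chart,
                                              seed = st$config$seed)
  }
  .demo_cache$traits
}
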