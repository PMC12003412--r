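# brute-force oracles -----------------------------------------------------

# exhaustive O(N^2) mean distance to the k' nearest other points
knn_oracle <- function(x, y, k) {
  n <- length(x)
  kp <- min(k, n - 1)
  vapply(seq_len(n), function(i) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)[-i]
    mean(sort(d)[seq_len(kp)])
  }, numeric(1))
}

# direct per-pixel evaluation of the sum of truncated renormalized Gaussians
render_oracle <- function(ann, params) {
  h <- ann$height; w <- ann$width
  grid <- matrix(0, h, w)
  if (n_points(ann) == 0) return(grid)
  sig <- adaptive_sigmas(ann$points$x, ann$points$y, params)
  for (i in seq_len(n_points(ann))) {
    x0 <- ann$points$x[i]; y0 <- ann$points$y[i]; s <- sig[i]
    r <- ceiling(params$truncation_radius * s)
    patch <- matrix(0, h, w)
    for (py in 0:(h - 1)) for (px in 0:(w - 1)) {
      if (px >= floor(x0 - r) && px <= ceiling(x0 + r) &&
          py >= floor(y0 - r) && py <= ceiling(y0 + r))
        patch[py + 1, px + 1] <- exp(-((px - x0)^2 + (py - y0)^2) / (2 * s^2))
    }
    grid <- grid + patch / sum(patch)
  }
  grid
}

test_that("mean_knn_distance matches the exhaustive oracle", {
  # pair at distance 5, k clamps to N-1
  expect_equal(mean_knn_distance(c(0, 5), c(0, 0), k = 3), c(5, 5))
  # hand case: right triangle, k = 2
  d <- mean_knn_distance(c(0, 3, 0), c(0, 0, 4), k = 2)
  expect_equal(d[1], (3 + 4) / 2)
  expect_equal(d, knn_oracle(c(0, 3, 0), c(0, 0, 4), 2))
  # random instances, several k
  set.seed(42)
  for (n in c(5, 30, 100)) {
    x <- runif(n, 0, 200); y <- runif(n, 0, 200)
    for (k in c(1, 3, 7))
      expect_equal(mean_knn_distance(x, y, k), knn_oracle(x, y, k),
                   tolerance = 1e-12)
  }
  expect_error(mean_knn_distance(1, 1, 3),
               class = "paniclecount_insufficient_points")
})

test_that("adaptive sigmas follow beta * dbar with fallback and floor", {
  p <- kernel_params(beta = 0.3, fallback_sigma = 15, sigma_floor = 0.5)
  # dbar = 10 for a pair at distance 10 -> sigma = 3
  expect_equal(adaptive_sigmas(c(0, 10), c(0, 0), p), c(3, 3))
  # single point -> fallback
  expect_equal(adaptive_sigmas(5, 5, p), 15)
  expect_equal(adaptive_sigmas(numeric(0), numeric(0), p), numeric(0))
  # coincident points floored, strictly positive
  s <- adaptive_sigmas(c(7, 7), c(3, 3), p)
  expect_equal(s, c(0.5, 0.5))
  expect_true(all(s > 0))
})

test_that("render_density_map conserves mass and matches per-pixel oracle", {
  params <- kernel_params()
  # empty annotation -> zero map
  empty <- point_annotations("e", 64, 64)
  expect_equal(density_mass(render_density_map(empty, params)), 0)

  # single interior point: unit mass, argmax at the point
  one <- point_annotations("o", 64, 64, x = 30, y = 20)
  dm <- render_density_map(one, kernel_params(fallback_sigma = 2))
  expect_equal(density_mass(dm), 1, tolerance = 1e-6)
  am <- which(dm$grid == max(dm$grid), arr.ind = TRUE)
  expect_equal(unname(am[1, ]), c(20 + 1, 30 + 1))

  # 3 arbitrary points on a small grid: equals the brute-force oracle
  ann3 <- point_annotations("t", 24, 20, x = c(3.2, 10, 18.7),
                            y = c(4.5, 12.1, 2))
  got <- render_density_map(ann3, params)
  expect_equal(got$grid, render_oracle(ann3, params), tolerance = 1e-9)

  # mass conservation including border-adjacent and duplicate points
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(20:120, 1)
    ann <- rand_annotations(n, 80, 60)
    # drive points onto the border and duplicate a few
    ann$points$x[1:3] <- c(0, 79.999, 41)
    ann$points$y[1:3] <- c(0, 59.999, 0)
    ann$points[4, ] <- ann$points[5, ]
    dm <- render_density_map(ann, params)
    expect_true(all(dm$grid >= 0))
    expect_lt(abs(density_mass(dm) - n), 1e-6 * n)
  }
})

test_that("density map is translation-equivariant away from borders", {
  params <- kernel_params()
  set.seed(9)
  x <- runif(12, 30, 50); y <- runif(12, 30, 50)
  a <- render_density_map(point_annotations("a", 96, 96, x, y), params)
  b <- render_density_map(point_annotations("b", 96, 96, x + 7, y + 5), params)
  expect_equal(b$grid[(1:80) + 5, (1:80) + 7], a$grid[1:80, 1:80],
               tolerance = 1e-12)
})

test_that("downsample_density is exact block-sum pooling", {
  # identity at factor 1
  m <- density_map(matrix(runif(64), 8, 8))
  expect_identical(downsample_density(m, 1), m)
  # uniform 8x8 of mass 1 pools to a single cell holding 1
  u <- density_map(matrix(1 / 64, 8, 8))
  p <- downsample_density(u, 8)
  expect_equal(dim(p$grid), c(1L, 1L))
  expect_equal(p$grid[1, 1], 1)
  expect_equal(p$scale, 8L)
  # random map vs naive double-loop block sums, including ragged padding
  set.seed(5)
  g <- matrix(runif(64 * 64), 64, 64)
  got <- downsample_density(density_map(g), 8)
  naive <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8)
    naive[i, j] <- sum(g[(i - 1) * 8 + 1:8, (j - 1) * 8 + 1:8])
  expect_equal(got$grid, naive, tolerance = 1e-12)
  expect_lt(abs(density_mass(got) - sum(g)), 1e-12)
  # non-divisible dims: zero padding preserves mass exactly
  g2 <- matrix(runif(37 * 61), 37, 61)
  got2 <- downsample_density(density_map(g2), 8)
  expect_equal(dim(got2$grid), c(5L, 8L))
  expect_equal(density_mass(got2), sum(g2), tolerance = 1e-12)
  expect_error(downsample_density(density_map(g2), 0),
               class = "paniclecount_value_error")
})

test_that("density maps persist through HDF5 and NPY", {
  dir <- withr::local_tempdir()
  set.seed(21)
  dm <- density_map(matrix(runif(12 * 17), 12, 17), scale = 8L,
                    image_id = "img_x")
  h5 <- file.path(dir, "d.h5")
  write_density_map(dm, h5)
  back <- read_density_map(h5)
  expect_equal(back$grid, dm$grid, tolerance = 1e-12)
  expect_equal(back$scale, 8L)
  expect_equal(back$image_id, "img_x")

  npy <- file.path(dir, "d.npy")
  write_density_map(dm, npy)
  back2 <- read_density_map(npy, scale = 8L, image_id = "img_x")
  expect_equal(back2$grid, dm$grid, tolerance = 1e-15)
})
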