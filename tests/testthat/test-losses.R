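test_that("loss components reproduce hand-computed values", {
  b <- batch_counts(c(10, 20), c(8, 25))
  # Euclidean, count mode: (1/(2*2)) * (4 + 25)
  expect_equal(euclidean_loss(b, "count"), 7.25, tolerance = 1e-9)
  # relative: ((2/8)^2 + (5/25)^2) / 2
  expect_equal(relative_loss(b), 0.05125, tolerance = 1e-9)
  # absolute: (2 + 5) / 2
  expect_equal(absolute_loss(b), 3.5, tolerance = 1e-9)
  # composite with the default balance factors
  cl <- composite_loss(b, loss_config(alpha = 0.1, beta = 0.01,
                                      euclidean_mode = "count"))
  expect_equal(cl$total, 7.290125, tolerance = 1e-9)
  expect_equal(cl$euclidean, 7.25)
  expect_equal(cl$relative, 0.05125)
  expect_equal(cl$absolute, 3.5)
})

test_that("map-mode Euclidean operates on grids", {
  p <- matrix(1, 2, 2); t <- matrix(0, 2, 2)
  b <- batch_counts(sum(p), sum(t) + 1, predicted_grids = list(p),
                    truth_grids = list(t))
  # grids differing by 1 everywhere, N=1: (1/2) * 4
  expect_equal(euclidean_loss(b, "map"), 2, tolerance = 1e-12)
  expect_error(euclidean_loss(batch_counts(1, 1), "map"),
               class = "paniclecount_value_error")
  mismatched <- batch_counts(1, 1, predicted_grids = list(matrix(0, 2, 2)),
                             truth_grids = list(matrix(0, 3, 3)))
  expect_error(euclidean_loss(mismatched, "map"),
               class = "paniclecount_value_error")
})

test_that("losses vanish iff predictions equal truth", {
  set.seed(6)
  z <- sample(80:300, 5)
  eq <- batch_counts(z, z, predicted_grids = lapply(z, function(v) matrix(v / 4, 2, 2)),
                     truth_grids = lapply(z, function(v) matrix(v / 4, 2, 2)))
  expect_equal(euclidean_loss(eq, "count"), 0)
  expect_equal(euclidean_loss(eq, "map"), 0)
  expect_equal(relative_loss(eq), 0)
  expect_equal(absolute_loss(eq), 0)
  expect_equal(composite_loss(eq, loss_config(euclidean_mode = "count"))$total, 0)
  ne <- batch_counts(z + 1, z)
  expect_gt(euclidean_loss(ne, "count"), 0)
  expect_gt(relative_loss(ne), 0)
  expect_gt(absolute_loss(ne), 0)
})

test_that("relative loss is scale-invariant and guards zero truth", {
  b1 <- batch_counts(c(10, 20), c(8, 25))
  b10 <- batch_counts(c(100, 200), c(80, 250))
  expect_equal(relative_loss(b1), relative_loss(b10), tolerance = 1e-12)
  expect_error(relative_loss(batch_counts(c(1, 2), c(3, 0))),
               class = "paniclecount_division_guard")
  # composite skips the relative term for zero-truth items
  cl <- composite_loss(batch_counts(c(1, 2), c(3, 0),
                                    predicted_grids = list(matrix(1), matrix(2)),
                                    truth_grids = list(matrix(3), matrix(0))),
                       loss_config())
  expect_true(is.finite(cl$total))
  expect_equal(cl$relative, (1 - 3 / 3)^2 + ((1 - 3) / 3)^2, tolerance = 1e-12)
})

test_that("alpha = beta = 0 reduces to the Euclidean baseline (ablation grid)", {
  set.seed(14)
  pred <- runif(6, 50, 300); truth <- runif(6, 50, 300)
  b <- batch_counts(pred, truth)
  base <- composite_loss(b, loss_config(alpha = 0, beta = 0,
                                        euclidean_mode = "count"))
  expect_identical(base$total, euclidean_loss(b, "count"))
  # monotone non-decreasing in each balance factor
  grid <- expand.grid(alpha = c(0, 0.1, 0.5), beta = c(0, 0.01, 0.1))
  totals <- mapply(function(a, bta)
    composite_loss(b, loss_config(a, bta, "count"))$total,
    grid$alpha, grid$beta)
  for (bta in unique(grid$beta)) {
    sub <- totals[grid$beta == bta]
    expect_true(all(diff(sub) >= -1e-12))
  }
  for (a in unique(grid$alpha)) {
    sub <- totals[grid$alpha == a]
    expect_true(all(diff(sub) >= -1e-12))
  }
  # the four ablation rows are distinct configurations of one function
  rows <- list(c(0, 0), c(0.1, 0), c(0, 0.01), c(0.1, 0.01))
  vals <- vapply(rows, function(r)
    composite_loss(b, loss_config(r[1], r[2], "count"))$total, numeric(1))
  expect_equal(vals[4] - vals[1],
               0.1 * relative_loss(b) + 0.01 * absolute_loss(b),
               tolerance = 1e-12)
})
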