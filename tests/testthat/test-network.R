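param_checksum <- function(model) {
  sum(vapply(model$layers, function(l)
    if (l$type == "conv") sum(l$W) + sum(l$b) else 0, numeric(1)))
}

test_that("construction is seeded and deterministic", {
  m1 <- build_network(network_config("tiny"), seed = 5)
  m2 <- build_network(network_config("tiny"), seed = 5)
  expect_identical(param_checksum(m1), param_checksum(m2))
  m3 <- build_network(network_config("tiny"), seed = 6)
  expect_false(identical(param_checksum(m1), param_checksum(m3)))
})

test_that("full variant matches the closed-form parameter count and stride", {
  model <- build_network(network_config("full"), seed = 1)
  # independent hand computation of the documented layer plan:
  # VGG-16 first 10 convs, then six dilated 3x3 convs, then a 1x1 head
  plan3x3 <- rbind(
    c(3, 64), c(64, 64), c(64, 128), c(128, 128),
    c(128, 256), c(256, 256), c(256, 256),
    c(256, 512), c(512, 512), c(512, 512),
    c(512, 512), c(512, 512), c(512, 512), c(512, 256),
    c(256, 128), c(128, 64))
  expected <- sum(9 * plan3x3[, 1] * plan3x3[, 2] + plan3x3[, 2]) +
    (1 * 64 * 1 + 1)
  expect_equal(network_num_params(model), expected)

  # forward-pass architecture arithmetic: 64x64 input -> 8x8 output
  x <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
  pred <- predict_density(model, x)
  expect_equal(dim(pred$density$grid), c(8L, 8L))
  expect_equal(pred$density$scale, 8L)
})

test_that("tiny variant is small and honors its output strides", {
  set.seed(1)
  x <- array(rnorm(40 * 56 * 3), c(40, 56, 3))
  for (stride in c(1L, 2L, 4L)) {
    m <- build_network(network_config("tiny", output_stride = stride), seed = 2)
    expect_lt(network_num_params(m), 1e5)
    p <- predict_density(m, x)
    expect_equal(dim(p$density$grid),
                 c(as.integer(ceiling(40 / stride)),
                   as.integer(ceiling(56 / stride))))
  }
  expect_error(network_config("tiny", output_stride = 3),
               class = "paniclecount_config_error")
  expect_error(network_config("full", output_stride = 4),
               class = "paniclecount_config_error")
  expect_error(network_config("full", pretrained_frontend = TRUE),
               class = "paniclecount_config_error")
})

test_that("prediction clamps negatives and is deterministic", {
  m <- build_network(network_config("tiny"), seed = 3)
  set.seed(8)
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  p1 <- predict_density(m, x, "im")
  expect_true(is.finite(p1$raw_count))
  expect_gte(p1$raw_count, 0)
  expect_true(all(p1$density$grid >= 0))
  expect_equal(p1$raw_count, sum(p1$density$grid))
  p2 <- predict_density(m, x, "im")
  expect_identical(p1$density$grid, p2$density$grid)
  # undersized input names the minimum
  expect_error(predict_density(m, array(0, c(8, 8, 3))),
               "minimum input size",
               class = "paniclecount_value_error")
})

test_that("backprop gradients match finite differences", {
  # tiny stride-1 model on a small input; map-mode Euclidean loss
  m <- build_network(network_config("tiny", output_stride = 1L), seed = 9)
  set.seed(10)
  x <- array(rnorm(9 * 9 * 3, sd = 0.5), c(9, 9, 3))
  target <- matrix(runif(81), 9, 9)
  loss_of <- function(model) {
    out <- paniclecount:::nn_forward(model, x)$out
    P <- matrix(out, 9, 9)
    0.5 * sum((P - target)^2)
  }
  fwd <- paniclecount:::nn_forward(m, x, want_cache = TRUE)
  P <- matrix(fwd$out, 9, 9)
  grads <- paniclecount:::nn_backward(m, fwd$caches,
                                      array(P - target, c(9, 9, 1)))
  eps <- 1e-5
  conv_ids <- which(vapply(m$layers, function(l) l$type == "conv", logical(1)))
  for (li in conv_ids[c(1, length(conv_ids))]) {  # first conv and head
    for (probe in list(c(1, 1), c(2, 1))) {
      mp <- m
      mp$layers[[li]]$W[probe[1], probe[2]] <-
        mp$layers[[li]]$W[probe[1], probe[2]] + eps
      mm <- m
      mm$layers[[li]]$W[probe[1], probe[2]] <-
        mm$layers[[li]]$W[probe[1], probe[2]] - eps
      fd <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      expect_equal(grads[[li]]$dW[probe[1], probe[2]], fd, tolerance = 1e-4)
    }
    # bias gradient
    mp <- m; mp$layers[[li]]$b[1] <- mp$layers[[li]]$b[1] + eps
    mm <- m; mm$layers[[li]]$b[1] <- mm$layers[[li]]$b[1] - eps
    fd <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
    expect_equal(grads[[li]]$db[1], fd, tolerance = 1e-4)
  }
})

test_that("checkpoints round-trip through disk", {
  dir <- withr::local_tempdir()
  m <- build_network(network_config("tiny"), seed = 4)
  p <- file.path(dir, "ck.rds")
  save_checkpoint(m, p)
  back <- load_checkpoint(p)
  expect_identical(param_checksum(back), param_checksum(m))
  expect_identical(back$config$output_stride, m$config$output_stride)
  expect_error(load_checkpoint(file.path(dir, "nope.rds")),
               class = "paniclecount_not_found")
  saveRDS(42, file.path(dir, "junk.rds"))
  expect_error(load_checkpoint(file.path(dir, "junk.rds")),
               class = "paniclecount_format_error")
})

test_that("training reduces the loss and is seed-reproducible", {
  tr <- gen_desk_items(8, 3100)
  m <- build_network(network_config("tiny"), seed = 11)
  r1 <- train_network(m, tr$items, loss_config(), epochs = 3, lr = 1e-3,
                      seed = 21)
  r2 <- train_network(m, tr$items, loss_config(), epochs = 3, lr = 1e-3,
                      seed = 21)
  expect_equal(r1$log$total, r2$log$total, tolerance = 1e-12)
  expect_lt(r1$log$total[3], r1$log$total[1])
})
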