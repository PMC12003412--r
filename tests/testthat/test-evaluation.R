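test_that("split sizes follow floor allocation with train-first remainder", {
  s <- split_dataset(seq_len(4000), split_spec(seed = 1))
  expect_equal(lengths(s), c(train = 3200L, test = 400L, validation = 400L))
  s10 <- split_dataset(seq_len(10), split_spec(seed = 1))
  expect_equal(lengths(s10), c(train = 8L, test = 1L, validation = 1L))
  # remainder: 11 items -> 8/1/1 leaves 1, assigned to train
  s11 <- split_dataset(seq_len(11), split_spec(seed = 1))
  expect_equal(lengths(s11), c(train = 9L, test = 1L, validation = 1L))
  # partition property for arbitrary sizes and ratios
  set.seed(2)
  for (n in c(1, 7, 97)) {
    sp <- split_spec(c(0.5, 0.25, 0.25), seed = n)
    parts <- split_dataset(seq_len(n), sp)
    expect_equal(sort(unname(unlist(parts))), seq_len(n))
    expect_equal(sum(lengths(parts)), n)
  }
  expect_error(split_spec(c(0.8, 0.1, 0.2)),
               class = "paniclecount_config_error")
  expect_error(split_dataset(list(), split_spec()),
               class = "paniclecount_value_error")
})

test_that("splitting is seed-deterministic and stratification keeps ratios", {
  items <- sprintf("img%03d", 1:100)
  a <- split_dataset(items, split_spec(seed = 7))
  b <- split_dataset(items, split_spec(seed = 7))
  expect_identical(a, b)
  c <- split_dataset(items, split_spec(seed = 8))
  expect_false(identical(a$train, c$train))
  # stratified: each stratum of 20 splits 16/2/2
  strata <- rep(c("cam1", "cam2", "cam3", "cam4", "cam5"), each = 20)
  st <- split_dataset(items, split_spec(seed = 7), stratify_by = strata)
  expect_equal(sort(unname(unlist(st))), sort(items))
  per <- table(strata[match(st$train, items)])
  expect_true(all(per == 16))
})

test_that("metrics reproduce the defining formulas", {
  # all-zero at equality
  r0 <- compute_metrics(c(5, 9), c(5, 9))
  expect_equal(c(r0$mae, r0$mse, r0$rmse, r0$mape), rep(0, 4))
  # single-pair hand case
  r <- compute_metrics(108, 109)
  expect_equal(r$mae, 1)
  expect_equal(r$mse, 1)
  expect_equal(r$rmse, 1)
  expect_equal(r$mape, 1 / 109, tolerance = 1e-12)
  # rmse^2 == mse identically; MAE <= RMSE (Cauchy-Schwarz) on random batches
  set.seed(17)
  for (i in 1:10) {
    n <- sample(3:40, 1)
    truth <- runif(n, 80, 350)
    pred <- truth + rnorm(n, 0, 12)
    rep <- compute_metrics(pred, truth)
    expect_equal(rep$rmse^2, rep$mse, tolerance = 1e-9)
    expect_lte(rep$mae, rep$rmse + 1e-12)
    expect_equal(rep$mape, mean(abs(pred - truth) / truth), tolerance = 1e-12)
  }
  expect_error(compute_metrics(1, 0), class = "paniclecount_division_guard")
  expect_error(compute_metrics(numeric(0), numeric(0)),
               class = "paniclecount_value_error")
})

test_that("relative error matches the printed verification examples", {
  expect_equal(round(100 * relative_error(276, 252), 2), 8.70)
  expect_equal(round(100 * relative_error(174, 173), 2), 0.57)
  expect_equal(relative_error(100, 100), 0)
  expect_error(relative_error(0, 5), class = "paniclecount_value_error")
})

test_that("report CSV carries per-image rows plus a summary row", {
  dir <- withr::local_tempdir()
  rep <- compute_metrics(c(100, 210), c(98, 205), c("a", "b"))
  path <- file.path(dir, "report.csv")
  write_evaluation_report(rep, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 3)
  expect_equal(df$image_id, c("a", "b", "summary"))
  expect_equal(df$mae[3], rep$mae)
  expect_equal(df$relative_error_pct[1:2],
               rep$per_image$relative_error_pct)
})
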