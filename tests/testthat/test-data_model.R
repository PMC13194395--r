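test_that("dataset constructor enforces shape and finiteness invariants", {
  ds <- observational_dataset(matrix(runif(15), 5, 3), runif(5), rnorm(5))
  expect_s3_class(ds, "observational_dataset")
  expect_equal(c(ds$n, ds$p, ds$tau), c(5L, 3L, 1L))

  expect_error(observational_dataset(matrix(1, 4, 2), runif(5), rnorm(5)),
               "row mismatch")
  X <- matrix(runif(10), 5, 2); X[3, 1] <- NA
  expect_error(observational_dataset(X, runif(5), rnorm(5)), "row 3")
  expect_error(observational_dataset(matrix(1, 3, 1), c(1, 2, Inf), rnorm(3)),
               "non-finite")
})

test_that("CSV round-trip reproduces X, T, Y bit-identically", {
  ds <- tiny_dataset(n = 12, p = 3, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  cmap <- save_dataset(ds, path)
  ds2 <- load_dataset(path, cmap)
  expect_identical(ds2$X, unname(ds$X))
  expect_identical(ds2$T, unname(ds$T))
  expect_identical(ds2$Y, ds$Y)
  expect_equal(c(ds2$n, ds2$p, ds2$tau), c(12L, 3L, 1L))
})

test_that("loading reports missing columns and bad cells by name and row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,t,y", "1,2,0.5,1.0", "3,x,0.2,0.7"), path)
  expect_error(
    load_dataset(path, list(covariates = c("a", "b"), treatment = "t",
                            outcome = "missing")),
    "missing")
  expect_error(
    load_dataset(path, list(covariates = c("a", "b"), treatment = "t",
                            outcome = "y")),
    "column 'b' at row 2")
  expect_error(load_dataset(path, list(covariates = "a", treatment = "t")),
               "outcome")
  expect_error(load_dataset("no/such/file.csv",
                            list(covariates = "a", treatment = "t", outcome = "y")),
               "not found")
})

test_that("parquet files load through the same column map", {
  skip_if_not_installed("arrow")
  ds <- tiny_dataset(n = 8, p = 2, seed = 2)
  path <- withr::local_tempfile(fileext = ".parquet")
  df <- data.frame(x1 = ds$X[, 1], x2 = ds$X[, 2], t = ds$T[, 1], y = ds$Y)
  arrow::write_parquet(df, path)
  ds2 <- load_dataset(path, list(covariates = c("x1", "x2"), treatment = "t",
                                 outcome = "y"))
  expect_equal(ds2$X, unname(ds$X))
  expect_equal(ds2$Y, ds$Y)
})

test_that("train/test split is a seed-determined exact partition", {
  ds <- tiny_dataset(n = 700, p = 2, seed = 3)
  sp <- train_test_split(ds, n_test = 200, seed = 7)
  expect_equal(sp$train$n, 500L)
  expect_equal(sp$test$n, 200L)
  # every row appears exactly once across the two parts
  all_rows <- rbind(cbind(sp$train$X, sp$train$T, sp$train$Y),
                    cbind(sp$test$X, sp$test$T, sp$test$Y))
  orig <- cbind(ds$X, ds$T, ds$Y)
  expect_equal(all_rows[order(all_rows[, 1]), ], orig[order(orig[, 1]), ],
               ignore_attr = TRUE)
  sp2 <- train_test_split(ds, n_test = 200, seed = 7)
  expect_identical(sp$test$Y, sp2$test$Y)
  sp3 <- train_test_split(ds, n_test = 200, seed = 8)
  expect_false(identical(sp$test$Y, sp3$test$Y))

  expect_error(train_test_split(ds, n_test = 700, seed = 1), "between 0 and N")
  expect_error(train_test_split(ds, n_test = 0, seed = 1), "between 0 and N")
})

test_that("dose grids must be increasing, inside support, with >= 2 points", {
  g <- dose_grid(n_points = 65)
  expect_length(g$points, 65)
  expect_true(all(diff(g$points) > 0))
  expect_error(dose_grid(points = c(0.5, 0.2)), "increasing")
  expect_error(dose_grid(points = 0.5), "at least 2")
  expect_error(dose_grid(points = c(0, 1.5)), "outside")
})

test_that("oracles are deterministic and vectorize over rows", {
  orc <- dose_response_oracle(function(t, x) 2 * t[, 1] + x[, 1])
  expect_equal(orc(0.5, matrix(1, 1, 1)), 2)
  v1 <- orc(matrix(c(0.1, 0.9)), matrix(0, 2, 1))
  expect_equal(v1, c(0.2, 1.8))
  expect_identical(v1, orc(matrix(c(0.1, 0.9)), matrix(0, 2, 1)))
  # scalar t recycled across covariate rows
  expect_equal(orc(0.5, matrix(c(0, 1), 2, 1)), c(1, 2))
})
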