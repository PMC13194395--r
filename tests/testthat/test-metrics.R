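# Function-valued predictors let the metrics be tested against closed forms
# without any model fitting.
fn_predictor <- function(f) function(X, grid)
  t(vapply(seq_len(nrow(X)), function(i) f(grid$points, X[i, ]),
           numeric(length(grid$points))))

const_oracle <- function(c) dose_response_oracle(function(t, x) rep(c, nrow(x)))

test_that("both metrics are zero iff predictions match the oracle", {
  ds <- observational_dataset(matrix(runif(20), 10, 2), runif(10), rnorm(10),
                              truth = dose_response_oracle(
                                function(t, x) t[, 1]^2 + x[, 1]))
  g <- dose_grid(n_points = 33)
  perfect <- fn_predictor(function(tt, x) tt^2 + x[1])
  expect_equal(mise(perfect, ds, g), 0)
  expect_equal(amse(perfect, ds, g), 0)
  off <- fn_predictor(function(tt, x) tt^2 + x[1] + 0.01)
  expect_gt(mise(off, ds, g), 0)
  expect_gt(amse(off, ds, g), 0)
})

test_that("constant offsets integrate to their squared value", {
  ds <- observational_dataset(matrix(runif(10), 5, 2), runif(5), rnorm(5),
                              truth = const_oracle(1))
  g <- dose_grid(n_points = 65)
  zero <- fn_predictor(function(tt, x) rep(0, length(tt)))
  expect_equal(mise(zero, ds, g), 1.0)
  expect_equal(amse(zero, ds, g), 1.0)
})

test_that("trapezoid quadrature reproduces the integral of t^2", {
  ds <- observational_dataset(matrix(runif(6), 3, 2), runif(3), rnorm(3),
                              truth = dose_response_oracle(
                                function(t, x) t[, 1]))
  g <- dose_grid(n_points = 101)
  zero <- fn_predictor(function(tt, x) rep(0, length(tt)))
  expect_lt(abs(mise(zero, ds, g) - 1 / 3), 1e-3)
})

test_that("trapezoid weights agree with an independent quadrature", {
  skip_if_not_installed("pracma")
  pts <- sort(c(0, 1, runif(20)))
  vals <- sin(3 * pts) + pts^2
  expect_equal(sum(hnet:::trapezoid_weights(pts) * vals),
               pracma::trapz(pts, vals))
})

test_that("opposite individual errors cancel in AMSE but not MISE", {
  ds <- observational_dataset(matrix(runif(4), 2, 2), runif(2), rnorm(2),
                              truth = const_oracle(0))
  g <- dose_grid(n_points = 65)
  c0 <- 0.7
  pm <- function(X, grid)
    rbind(rep(c0, length(grid$points)), rep(-c0, length(grid$points)))
  expect_equal(amse(pm, ds, g), 0)
  expect_equal(mise(pm, ds, g), c0^2)
})

test_that("AMSE never exceeds MISE (Jensen) and both ignore row order", {
  set.seed(8)
  for (i in 1:10) {
    n <- 7
    ds <- observational_dataset(matrix(runif(n * 2), n, 2), runif(n), rnorm(n),
                                truth = dose_response_oracle(
                                  function(t, x) sin(3 * t[, 1]) * x[, 1]))
    g <- dose_grid(n_points = 17)
    a <- matrix(rnorm(n), n, 1)
    pred <- function(X, grid)
      outer(X[, 1], grid$points, function(x1, tt) x1 * cos(2 * tt)) +
        matrix(rnorm(n * length(grid$points), sd = 0.2), n)
    set.seed(100 + i); P1 <- pred(ds$X, g)
    fixed_pred <- function(X, grid) P1
    expect_lte(amse(fixed_pred, ds, g), mise(fixed_pred, ds, g) + 1e-12)

    perm <- sample(n)
    ds_perm <- observational_dataset(ds$X[perm, ], ds$T[perm, , drop = FALSE],
                                     ds$Y[perm], truth = ds$truth)
    perm_pred <- function(X, grid) P1[perm, ]
    expect_equal(mise(perm_pred, ds_perm, g), mise(fixed_pred, ds, g))
    expect_equal(amse(perm_pred, ds_perm, g), amse(fixed_pred, ds, g))
  }
})

test_that("metrics converge under grid refinement for smooth curves", {
  n <- 20
  ds <- observational_dataset(matrix(runif(n * 2), n, 2), runif(n), rnorm(n),
                              truth = dose_response_oracle(
                                function(t, x) cos(2 * pi * (t[, 1] - 0.5)) * x[, 1]))
  smooth_pred <- fn_predictor(function(tt, x) sin(2 * tt) * x[2] + tt)
  m65 <- mise(smooth_pred, ds, dose_grid(n_points = 65))
  m257 <- mise(smooth_pred, ds, dose_grid(n_points = 257))
  expect_lt(abs(m65 - m257) / m257, 0.01)
})

test_that("metrics demand a ground-truth oracle", {
  ds <- observational_dataset(matrix(runif(4), 2, 2), runif(2), rnorm(2))
  expect_error(mise(fn_predictor(function(tt, x) tt), ds, dose_grid()),
               "oracle")
})

test_that("replicate aggregation returns mean and standard error", {
  expect_equal(aggregate_replicates(c(1, 1, 1)), c(mean = 1, se = 0))
  expect_equal(aggregate_replicates(c(0, 2)), c(mean = 1, se = 1))
  v <- runif(9)
  expect_equal(aggregate_replicates(v), aggregate_replicates(rev(v)))
  expect_error(aggregate_replicates(1.5), "at least 2")
})
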