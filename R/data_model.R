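#' Observational dataset for continuous-treatment causal inference
#'
#' Bundles the (Y, T, X) triple of an observational study: an `N x p` covariate
#' matrix, an `N x tau` treatment matrix (`tau = 1` for the usual scalar dose),
#' and an outcome vector of length `N`. Optionally carries a ground-truth
#' dose-response oracle (see [dose_response_oracle()]) so that counterfactual
#' error metrics can be computed on synthetic data.
#'
#' All entries must be finite; rows of `X`, `T` and `Y` are aligned by index.
#'
#' @param X numeric matrix or data.frame of covariates, `N x p`.
#' @param T numeric vector or matrix of treatments; a vector is treated as an
#'   `N x 1` matrix.
#' @param Y numeric outcome vector of length `N`.
#' @param truth optional [dose_response_oracle()] giving the noiseless outcome
#'   surface `y(t, x)`.
#' @return An object of class `observational_dataset` with elements `X`, `T`,
#'   `Y`, `truth`, and cached dimensions `n`, `p`, `tau`.
#' @examples
#' ds <- observational_dataset(matrix(runif(20), 10, 2), runif(10), rnorm(10))
#' ds$n; ds$p; ds$tau
#' @export
observational_dataset <- function(X, T, Y, truth = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(dim(T))) T <- matrix(as.numeric(T), ncol = 1L)
  T <- as.matrix(T)
  storage.mode(T) <- "double"
  Y <- as.numeric(Y)
  n <- nrow(X)
  if (n < 1L || ncol(X) < 1L)
    stop("X must have at least one row and one column", call. = FALSE)
  if (nrow(T) != n || length(Y) != n)
    stop(sprintf("row mismatch: X has %d rows, T has %d, Y has %d",
                 n, nrow(T), length(Y)), call. = FALSE)
  if (ncol(T) < 1L) stop("T must have at least one column", call. = FALSE)
  for (nm in c("X", "T", "Y")) {
    v <- switch(nm, X = X, T = T, Y = Y)
    if (!all(is.finite(v))) {
      bad <- which(!apply(matrix(is.finite(as.matrix(v)), nrow = n), 1L, all))[1L]
      stop(sprintf("non-finite value in %s at row %d", nm, bad), call. = FALSE)
    }
  }
  if (!is.null(truth) && !inherits(truth, "dose_response_oracle"))
    stop("truth must be a dose_response_oracle", call. = FALSE)
  structure(
    list(X = X, T = T, Y = Y, truth = truth,
         n = n, p = ncol(X), tau = ncol(T)),
    class = "observational_dataset")
}

#' @export
print.observational_dataset <- function(x, ...) {
  cat(sprintf("<observational_dataset> N = %d, p = %d covariates, tau = %d treatment dim%s\n",
              x$n, x$p, x$tau, if (is.null(x$truth)) "" else ", with ground-truth oracle"))
  invisible(x)
}

#' Ground-truth dose-response oracle
#'
#' Wraps a deterministic function `f(t, x)` returning the noiseless outcome at
#' treatment `t` for a unit with covariate row `x`. On synthetic data this is
#' the individual counterfactual function that MISE/AMSE compare against.
#'
#' The wrapped function must be vectorized over rows: given a numeric treatment
#' matrix `t` (`n x tau`) and covariate matrix `x` (`n x p`) it returns a
#' numeric vector of length `n`. A convenience dispatch accepts a scalar `t`
#' with a single covariate row.
#'
#' @param fn function of `(t, x)` as described above.
#' @return An object of class `dose_response_oracle`; call it like a function.
#' @examples
#' orc <- dose_response_oracle(function(t, x) 2 * t[, 1] + x[, 1])
#' orc(matrix(0.5), matrix(1, 1, 1))  # 2
#' @export
dose_response_oracle <- function(fn) {
  stopifnot(is.function(fn))
  f <- function(t, x) {
    if (is.null(dim(t))) t <- matrix(as.numeric(t), ncol = 1L)
    if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
    if (nrow(x) == 1L && nrow(t) > 1L)
      x <- x[rep(1L, nrow(t)), , drop = FALSE]
    if (nrow(t) == 1L && nrow(x) > 1L)
      t <- t[rep(1L, nrow(x)), , drop = FALSE]
    as.numeric(fn(t, x))
  }
  class(f) <- c("dose_response_oracle", "function")
  f
}

#' Evaluation grid over the treatment support
#'
#' An ordered set of treatment values at which counterfactual curves are
#' evaluated, used by [predict_curve()], [mise()] and [amse()]. Points must be
#' strictly increasing and lie within the declared support.
#'
#' @param points strictly increasing numeric vector (length >= 2), or `NULL`
#'   to build a uniform grid.
#' @param n_points number of uniform points when `points` is `NULL`.
#' @param support length-2 numeric range the grid must lie in.
#' @return Object of class `dose_grid`: list with `points`, `support`.
#' @examples
#' g <- dose_grid(n_points = 65)
#' range(g$points); length(g$points)
#' @export
dose_grid <- function(points = NULL, n_points = 65L, support = c(0, 1)) {
  support <- as.numeric(support)
  stopifnot(length(support) == 2L, support[1] < support[2])
  if (is.null(points)) points <- seq(support[1], support[2], length.out = n_points)
  points <- as.numeric(points)
  if (length(points) < 2L) stop("a dose grid needs at least 2 points", call. = FALSE)
  if (any(diff(points) <= 0)) stop("grid points must be strictly increasing", call. = FALSE)
  if (points[1] < support[1] - 1e-12 || points[length(points)] > support[2] + 1e-12)
    stop("grid points outside declared support", call. = FALSE)
  structure(list(points = points, support = support), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d points on [%g, %g]\n",
              length(x$points), x$support[1], x$support[2]))
  invisible(x)
}

#' Read an observational dataset from CSV or Parquet
#'
#' Columns are assigned roles through `column_map`, a list with character
#' entries `covariates`, `treatment` and `outcome`. Row order of the file is
#' preserved. CSV files are expected with a header row, UTF-8 encoding and
#' `.` as decimal separator; files ending in `.parquet` are read with the
#' arrow package.
#'
#' @param path path to a `.csv` or `.parquet` file.
#' @param column_map list with entries `covariates` (character vector),
#'   `treatment` (one or more column names), `outcome` (single column name).
#' @return An [observational_dataset()].
#' @seealso [save_dataset()] for the inverse operation.
#' @export
load_dataset <- function(path, column_map) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  for (role in c("covariates", "treatment", "outcome"))
    if (is.null(column_map[[role]]))
      stop(sprintf("column_map is missing the '%s' entry", role), call. = FALSE)
  df <- if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("reading parquet requires the 'arrow' package", call. = FALSE)
    as.data.frame(arrow::read_parquet(path))
  } else {
    utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  }
  wanted <- unlist(column_map[c("covariates", "treatment", "outcome")], use.names = FALSE)
  missing_cols <- setdiff(wanted, names(df))
  if (length(missing_cols))
    stop(sprintf("column(s) not present in %s: %s", basename(path),
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  grab <- function(cols) {
    m <- as.matrix(df[, cols, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "double")  # bad cells reported below
    dimnames(m) <- NULL
    bad <- which(!is.finite(m), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric or non-finite value in column '%s' at row %d",
                   cols[bad[1, 2]], bad[1, 1]), call. = FALSE)
    m
  }
  observational_dataset(
    X = grab(column_map$covariates),
    T = grab(column_map$treatment),
    Y = as.numeric(grab(column_map$outcome)))
}

#' Write an observational dataset to CSV (with a JSON column-map sidecar)
#'
#' Writes one CSV with columns `x1..xp`, `t1..ttau` (or `t` when `tau = 1`)
#' and `y`, plus `<path>.json` describing the column map so [load_dataset()]
#' can restore the object. Finite doubles round-trip bit-identically
#' (values are written with 17 significant digits).
#'
#' @param ds an [observational_dataset()].
#' @param path output CSV path.
#' @return Invisibly, the column map used.
#' @export
save_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "observational_dataset"))
  xn <- paste0("x", seq_len(ds$p))
  tn <- if (ds$tau == 1L) "t" else paste0("t", seq_len(ds$tau))
  df <- data.frame(ds$X, ds$T, y = ds$Y)
  names(df) <- c(xn, tn, "y")
  # 17 significant digits guarantee double round-trip through decimal text
  for (j in seq_along(df)) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  cmap <- list(covariates = xn, treatment = tn, outcome = "y")
  jsonlite::write_json(cmap, paste0(path, ".json"), auto_unbox = FALSE)
  invisible(cmap)
}

#' Split a dataset into train and test parts
#'
#' Draws a uniformly random partition determined by `seed`: `n_test` rows go to
#' the test set and the rest to the training set. Every row lands in exactly
#' one part and within-part row order follows the original dataset.
#'
#' @param ds an [observational_dataset()].
#' @param n_test number of test rows, `0 < n_test < N`.
#' @param seed integer seed controlling the partition.
#' @return List with elements `train` and `test`, both datasets carrying the
#'   same `truth` oracle as `ds`.
#' @export
train_test_split <- function(ds, n_test, seed) {
  stopifnot(inherits(ds, "observational_dataset"))
  n_test <- as.integer(n_test)
  if (n_test <= 0L || n_test >= ds$n)
    stop(sprintf("n_test must be strictly between 0 and N = %d", ds$n), call. = FALSE)
  idx_test <- sort(with_seed(seed, sample.int(ds$n, n_test)))
  idx_train <- setdiff(seq_len(ds$n), idx_test)
  take <- function(i) observational_dataset(
    ds$X[i, , drop = FALSE], ds$T[i, , drop = FALSE], ds$Y[i], truth = ds$truth)
  list(train = take(idx_train), test = take(idx_test))
}

# Evaluate an expression under a local RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
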