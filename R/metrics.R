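# Dose-response evaluation metrics. Both metrics compare fitted counterfactual
# curves against the noiseless ground-truth oracle on a dose grid, with the
# integral over the treatment support approximated by the trapezoid rule.

# n x G matrix of predicted curves for the rows of `test`.
curve_matrix <- function(predict, test, grid) {
  if (inherits(predict, "hnet_fit")) {
    P <- predict_curve(predict, test$X, grid)
  } else if (is.function(predict)) {
    P <- predict(test$X, grid)
  } else stop("predict must be a fitted model or a function(X, grid)", call. = FALSE)
  P <- as.matrix(P)
  if (nrow(P) != test$n || ncol(P) != length(grid$points))
    stop("curve predictor returned the wrong shape", call. = FALSE)
  P
}

truth_matrix <- function(test, grid) {
  if (is.null(test$truth))
    stop("test dataset carries no ground-truth oracle; MISE/AMSE need one",
         call. = FALSE)
  G <- length(grid$points)
  Th <- matrix(0, test$n, G)
  for (j in seq_len(G))
    Th[, j] <- test$truth(matrix(grid$points[j], test$n, 1L), test$X)
  Th
}

trapezoid_weights <- function(points) {
  G <- length(points)
  w <- numeric(G)
  d <- diff(points)
  w[1] <- d[1] / 2
  w[G] <- d[G - 1] / 2
  if (G > 2) w[2:(G - 1)] <- (d[-1] + d[-(G - 1)]) / 2
  w
}

#' Mean Integrated Squared Error of individual dose-response curves
#'
#' For each test unit `i`, the squared difference between the predicted
#' counterfactual curve and the true curve `theta_{x_i}(t)` is integrated over
#' the treatment support (trapezoid rule on `grid`); MISE is the average of
#' these integrals over units:
#' `MISE = (1/N) * sum_i int (yhat_i(t) - theta_{x_i}(t))^2 dt`.
#'
#' The oracle is evaluated noiselessly, so a perfect model scores 0.
#'
#' @param predict a fitted model ([fit_hnet()]/[fit_slearner()]) or a function
#'   `(X, grid) -> n x G` matrix of curves.
#' @param test an [observational_dataset()] whose `truth` oracle is set.
#' @param grid a [dose_grid()] spanning the treatment support.
#' @return Nonnegative scalar.
#' @export
mise <- function(predict, test, grid = dose_grid()) {
  stopifnot(inherits(test, "observational_dataset"), inherits(grid, "dose_grid"))
  P <- curve_matrix(predict, test, grid)
  Th <- truth_matrix(test, grid)
  w <- trapezoid_weights(grid$points)
  mean(as.numeric((P - Th)^2 %*% w))
}

#' Average Mean Squared Error of the average dose-response function
#'
#' Compares the estimated and true average dose-response functions (curves
#' averaged over the test units) pointwise, integrating the squared difference
#' over the treatment support:
#' `AMSE = int ( (1/N) sum_i yhat_i(t) - (1/N) sum_i theta_{x_i}(t) )^2 dt`.
#'
#' Individual errors of opposite sign cancel in the averaged curve, so AMSE
#' can be far below [mise()]; by Jensen's inequality it never exceeds it.
#'
#' @inheritParams mise
#' @return Nonnegative scalar.
#' @export
amse <- function(predict, test, grid = dose_grid()) {
  stopifnot(inherits(test, "observational_dataset"), inherits(grid, "dose_grid"))
  P <- curve_matrix(predict, test, grid)
  Th <- truth_matrix(test, grid)
  w <- trapezoid_weights(grid$points)
  sum(w * (colMeans(P) - colMeans(Th))^2)
}

#' Evaluate a fitted model on a test set with ground truth
#'
#' Computes [mise()] and [amse()] on the same grid and returns them with the
#' evaluation context.
#'
#' @inheritParams mise
#' @param model a fitted model.
#' @return Object of class `metric_report`: list with `mise`, `amse`,
#'   `grid`, `n_test`.
#' @export
evaluate_model <- function(model, test, grid = dose_grid()) {
  P <- curve_matrix(model, test, grid)
  Th <- truth_matrix(test, grid)
  w <- trapezoid_weights(grid$points)
  structure(list(mise = mean(as.numeric((P - Th)^2 %*% w)),
                 amse = sum(w * (colMeans(P) - colMeans(Th))^2),
                 grid = grid, n_test = test$n),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> MISE = %.4g, AMSE = %.4g (n_test = %d, grid G = %d)\n",
              x$mise, x$amse, x$n_test, length(x$grid$points)))
  invisible(x)
}

#' Mean and standard error across benchmark replicates
#'
#' The across-instance aggregation used for benchmark tables: arithmetic mean
#' and standard error of the mean, `sd(values) / sqrt(R)`.
#'
#' @param values numeric vector of per-replicate metric values (length >= 2).
#' @return Named numeric vector `c(mean, se)`.
#' @export
aggregate_replicates <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("need at least 2 replicate values to aggregate", call. = FALSE)
  c(mean = mean(values), se = stats::sd(values) / sqrt(length(values)))
}
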