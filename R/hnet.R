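#' Fit the hypernetwork dose-response model
#'
#' HNet estimates individualized counterfactual dose-response curves. An
#' encoder `f_phi` maps the covariates `x` to a representation
#' `z = f_phi(x)`; a hypernetwork `g_psi` maps `z` to the full weight vector
#' `omega = g_psi(z)` of a small fixed-architecture target network `h_omega`;
#' the prediction is `yhat = h_omega(t)`. Because the treatment enters only
#' through its own dedicated network — whose weights are generated per
#' instance — the treatment variable cannot be absorbed into a high-
#' dimensional covariate representation, which is the failure mode of naive
#' single-model (S-learner) fits.
#'
#' Training minimizes the mean squared error between observed and predicted
#' outcomes end-to-end over `(phi, psi)`; the target architecture itself has
#' no free parameters. All stochastic choices (initialization, validation
#' split, shuffling) derive from `seed`, so identical data, config and seed
#' reproduce the model exactly.
#'
#' @param train an [observational_dataset()].
#' @param config a [hnet_config()].
#' @param seed integer seed controlling all randomness of the fit.
#' @return Object of class `c("hnet_model", "hnet_fit")` carrying the trained
#'   encoder and hypernetwork parameters, the [target_net_spec()], and the
#'   covariate/treatment/outcome scaling maps.
#' @seealso [predict_curve()], [contrast()], [fit_slearner()] for the ablation
#'   baseline.
#' @examples
#' sim <- generate_linear_dgp(n = 200, p = 2, seed = 1)
#' m <- fit_hnet(sim$dataset, hnet_config(epochs = 50), seed = 1)
#' predict_curve(m, sim$dataset$X[1, ], dose_grid(n_points = 5))
#' @export
fit_hnet <- function(train, config = hnet_config(), seed = 1L) {
  stopifnot(inherits(config, "hnet_config"))
  tspec <- target_net_spec(train$tau, config$target_hidden, config$activation)
  engine <- hnet_engine(config, tspec)
  model <- train_engine(engine, train, config, seed, "hnet_model")
  model$target_spec <- tspec
  model
}

hnet_engine <- function(config, tspec) {
  act <- config$activation
  list(
    init = function(p, tau) {
      enc <- mlp_init(c(p, config$encoder_widths, config$repr_dim))
      hyp <- mlp_init(c(config$repr_dim, config$hyper_widths, tspec$m))
      # Stabilized hypernetwork output: shrink the final layer and center its
      # bias on a standard fan-in initialization of the target network, so the
      # generated omega starts near one sensible shared network.
      L <- length(hyp)
      hyp[[L]]$W <- hyp[[L]]$W * config$hyper_init_scale
      omega0 <- pack_weights(lapply(omega_layout(tspec), function(ly)
        list(W = matrix(stats::rnorm(ly$fi * ly$fo, sd = 1 / sqrt(ly$fi)),
                        ly$fi, ly$fo),
             b = numeric(ly$fo))), tspec)
      hyp[[L]]$b <- omega0
      list(enc = enc, hyp = hyp)
    },
    forward = function(params, Xs, Ts) {
      ef <- mlp_forward(params$enc, Xs, act, out_act = TRUE)
      hf <- mlp_forward(params$hyp, ef$out, act)
      tf <- target_forward_batch(hf$out, dose_input(Ts), tspec)
      list(pred = tf$out, ef = ef, hf = hf, tf = tf, Omega = hf$out)
    },
    backward = function(params, fw, dPred) {
      dOmega <- target_backward_batch(fw$Omega, fw$tf, dPred[, 1L], tspec)
      hb <- mlp_backward(params$hyp, fw$hf, dOmega, act)
      eb <- mlp_backward(params$enc, fw$ef, hb$dIn, act, out_act = TRUE)
      list(enc = eb$grads, hyp = hb$grads)
    })
}

# Generated target-network weights for (already scaled) covariates.
hnet_omega <- function(model, Xs) {
  ef <- mlp_forward(model$params$enc, Xs, model$config$activation, out_act = TRUE)
  mlp_forward(model$params$hyp, ef$out, model$config$activation)$out
}

#' Predict outcomes for a batch of (covariate, treatment) pairs
#'
#' Evaluates the fitted model at each row: entry `i` is the model's outcome
#' prediction for covariates `X[i, ]` under treatment `T[i, ]`, in the
#' original outcome units. Batched evaluation is numerically identical to a
#' per-sample loop.
#'
#' @param model a fitted `hnet_model` or `slearner_model`.
#' @param X covariate matrix `n x p` (model's `p`).
#' @param T treatment vector or matrix `n x tau`.
#' @return Numeric vector of `n` predictions.
#' @export
forward_batch <- function(model, X, T) {
  stopifnot(inherits(model, "hnet_fit"))
  X <- if (is.null(dim(X))) matrix(as.numeric(X), nrow = 1L) else as.matrix(X)
  if (is.null(dim(T))) T <- matrix(as.numeric(T), ncol = 1L)
  if (ncol(X) != model$p)
    stop(sprintf("X has %d columns but the model was fit with p = %d",
                 ncol(X), model$p), call. = FALSE)
  if (ncol(T) != model$tau)
    stop(sprintf("T has %d columns but the model was fit with tau = %d",
                 ncol(T), model$tau), call. = FALSE)
  if (nrow(X) != nrow(T))
    stop("X and T must have the same number of rows", call. = FALSE)
  sc <- model$scaler
  pred_s <- model_forward_scaled(model, scale_X(sc, X), scale_T(sc, T))
  unscale_Y(sc, pred_s)
}

model_forward_scaled <- function(model, Xs, Ts) {
  if (inherits(model, "hnet_model")) {
    Omega <- hnet_omega(model, Xs)
    target_forward_batch(Omega, dose_input(Ts), model$target_spec)$out
  } else {
    H <- cbind(slearner_repr(model, Xs), dose_input(Ts))
    mlp_forward(model$params$head, H, model$config$activation)$out[, 1L]
  }
}

# S-learner head input: learned representation, or raw covariates if so fit.
slearner_repr <- function(model, Xs) {
  if (isTRUE(model$raw_covariates)) return(Xs)
  mlp_forward(model$params$enc, Xs, model$config$activation, out_act = TRUE)$out
}

#' @export
predict.hnet_fit <- function(object, X, T, ...) forward_batch(object, X, T)

#' Mean squared prediction error on a dataset
#'
#' The empirical counterpart of the training objective: the mean over the
#' batch of `(y_i - yhat(x_i, t_i))^2`, computed in original outcome units.
#'
#' @param model a fitted model.
#' @param data an [observational_dataset()] (non-empty).
#' @return Nonnegative scalar.
#' @export
mse_loss <- function(model, data) {
  stopifnot(inherits(data, "observational_dataset"))
  if (data$n < 1L) stop("empty batch", call. = FALSE)
  mean((data$Y - forward_batch(model, data$X, data$T))^2)
}

#' Counterfactual dose-response curves on a grid
#'
#' For each covariate row `x`, evaluates the fitted model's counterfactual
#' prediction at every grid point — the estimated individual dose-response
#' curve. For the hypernetwork model the generated weight vector `omega` is
#' computed once per row and reused across all grid points.
#'
#' Grid points outside the treatment support seen at fit time are evaluated
#' anyway but flagged: a warning is raised and the result carries an
#' `"extrapolated"` attribute with the offending point indices.
#'
#' @param model a fitted `hnet_model` or `slearner_model` (scalar treatment).
#' @param x a single covariate row or an `n x p` matrix.
#' @param grid a [dose_grid()].
#' @return Numeric vector of length `G` for a single row, else an `n x G`
#'   matrix with one curve per row.
#' @export
predict_curve <- function(model, x, grid) {
  stopifnot(inherits(model, "hnet_fit"), inherits(grid, "dose_grid"))
  if (model$tau != 1L)
    stop("predict_curve is defined for scalar treatments (tau = 1)", call. = FALSE)
  single <- is.null(dim(x))
  X <- if (single) matrix(as.numeric(x), nrow = 1L) else as.matrix(x)
  sc <- model$scaler
  ts <- (grid$points - sc$t_lo) / sc$t_span  # scaled grid
  outside <- which(ts < -1e-9 | ts > 1 + 1e-9)
  if (length(outside))
    warning(sprintf("%d grid point(s) outside the fitted treatment support [%g, %g]: extrapolating",
                    length(outside), sc$t_lo, sc$t_lo + sc$t_span), call. = FALSE)
  curves <- predict_curve_scaled(model, scale_X(sc, X), ts)
  curves <- unscale_Y(sc, curves)
  if (length(outside)) attr(curves, "extrapolated") <- outside
  if (single) {
    dim(curves) <- NULL
    if (length(outside)) attr(curves, "extrapolated") <- outside
  }
  curves
}

# Curves for scaled covariates over scaled grid values; returns n x G matrix.
predict_curve_scaled <- function(model, Xs, ts) {
  n <- nrow(Xs); G <- length(ts)
  out <- matrix(0, n, G)
  if (inherits(model, "hnet_model")) {
    Omega <- hnet_omega(model, Xs)  # one omega per row, reused across the grid
    for (j in seq_len(G)) {
      Tj <- matrix(dose_input(ts[j]), n, 1L)
      out[, j] <- target_forward_batch(Omega, Tj, model$target_spec)$out
    }
  } else {
    Z <- slearner_repr(model, Xs)  # representation computed once per row
    for (j in seq_len(G)) {
      H <- cbind(Z, matrix(dose_input(ts[j]), n, 1L))
      out[, j] <- mlp_forward(model$params$head, H, model$config$activation)$out[, 1L]
    }
  }
  out
}

#' Conditional effect contrast between two treatment levels
#'
#' The model's estimate of the individual-level effect of moving from dose
#' `t_b` to dose `t_a` for a unit with covariates `x`:
#' `yhat(x, t_a) - yhat(x, t_b)`. Antisymmetric in its dose arguments.
#'
#' @param model a fitted model (scalar treatment).
#' @param x a single covariate row.
#' @param t_a,t_b treatment levels within the fitted support.
#' @return Scalar contrast.
#' @export
contrast <- function(model, x, t_a, t_b) {
  stopifnot(inherits(model, "hnet_fit"))
  x <- matrix(as.numeric(x), nrow = 1L)
  preds <- forward_batch(model, x[c(1L, 1L), , drop = FALSE],
                         matrix(c(t_a, t_b), ncol = 1L))
  preds[1L] - preds[2L]
}
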