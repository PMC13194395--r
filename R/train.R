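# Shared training loop for the hypernetwork model and the S-learner ablation.
# Both models are trained by exactly the same code path (Adam, identical
# scaling, validation split and stopping rule) so that benchmark differences
# isolate the architectural mechanism, not incidental training choices.

#' Training configuration
#'
#' Hyperparameters shared by [fit_hnet()] and [fit_slearner()]. Defaults:
#' encoder `p -> 50 -> k` with `k = 10` and a bounded (tanh) representation;
#' hypernetwork `k -> 50 -> m`; target network `tau -> 32 -> 1` (`m = 97`
#' when `tau = 1`); S-learner head `(k + tau) -> 50 -> 50 -> 1`; Adam with
#' learning rate `1e-3` and decoupled weight decay 10 on weight matrices
#' (biases exempt); a fixed budget of 800 epochs, full batch for `n <= 1000`
#' else mini-batches of 256.
#'
#' By default no validation split is held out: with persistent weight-decay
#' regularization the fit is self-limiting, and under confounded treatment
#' assignment the factual validation error is a poor selector for
#' counterfactual curve quality (its minimum tends to occur before the dose
#' response is learned). Set `val_frac > 0` to enable early stopping on a
#' held-out split with the given `patience` (best-epoch weights restored).
#'
#' @param repr_dim width `k` of the covariate representation.
#' @param encoder_widths hidden widths of the encoder MLP.
#' @param hyper_widths hidden widths of the hypernetwork MLP.
#' @param head_widths hidden widths of the S-learner head MLP.
#' @param target_hidden hidden widths of the target network `h_omega`.
#' @param activation hidden nonlinearity everywhere (`"tanh"` or `"relu"`).
#' @param lr Adam learning rate.
#' @param weight_decay decoupled (AdamW-style) decay coefficient applied to
#'   weight matrices each step as `W <- W * (1 - lr * weight_decay)`; biases
#'   — including the hypernetwork output bias, which carries the shared
#'   dose-response curve — are never decayed.
#' @param epochs number of training epochs (the full budget is used unless
#'   early stopping is enabled).
#' @param batch_size mini-batch size, or `NULL` for the automatic rule above.
#' @param val_frac fraction of training rows held out for early stopping;
#'   0 (default) disables the split.
#' @param patience epochs without validation improvement before stopping
#'   (only used when `val_frac > 0`).
#' @param hyper_init_scale multiplier shrinking the hypernetwork output layer
#'   at initialization (see Details).
#' @param t_support declared treatment support as `c(lo, hi)`, or `NULL` to
#'   use the observed training range. Treatments are min-max scaled to
#'   \[0, 1\] over this interval (and enter the networks as `2 t - 1`).
#' @details The hypernetwork's final layer starts with weights scaled by
#'   `hyper_init_scale / sqrt(fan_in)` and its bias set to a standard fan-in
#'   initialization of the target network, so the generated weights start near
#'   a sensible shared network instead of exploding — without this the
#'   generated `omega` has variance proportional to `k` and training
#'   diverges.
#' @return A list of class `hnet_config`.
#' @export
hnet_config <- function(repr_dim = 10L,
                        encoder_widths = 50L,
                        hyper_widths = 50L,
                        head_widths = c(50L, 50L),
                        target_hidden = 32L,
                        activation = "tanh",
                        lr = 1e-3,
                        weight_decay = 10,
                        epochs = 800L,
                        batch_size = NULL,
                        val_frac = 0,
                        patience = 50L,
                        hyper_init_scale = 0.1,
                        t_support = NULL) {
  cfg <- list(repr_dim = as.integer(repr_dim),
              encoder_widths = as.integer(encoder_widths),
              hyper_widths = as.integer(hyper_widths),
              head_widths = as.integer(head_widths),
              target_hidden = as.integer(target_hidden),
              activation = activation, lr = lr,
              weight_decay = weight_decay,
              epochs = as.integer(epochs), batch_size = batch_size,
              val_frac = val_frac, patience = as.integer(patience),
              hyper_init_scale = hyper_init_scale, t_support = t_support)
  stopifnot(cfg$repr_dim >= 1L, cfg$epochs >= 1L, cfg$lr > 0,
            cfg$weight_decay >= 0,
            cfg$val_frac >= 0, cfg$val_frac < 1, cfg$patience >= 1L)
  class(cfg) <- "hnet_config"
  cfg
}

# --- scaling ---------------------------------------------------------------
# Covariates and outcome are z-scored on training statistics; treatments are
# min-max mapped to [0, 1] over the declared (or observed) support. All maps
# are stored on the model and inverted on prediction output.

make_scaler <- function(train, t_support = NULL) {
  X <- train$X
  sds <- apply(X, 2L, stats::sd)
  keep <- which(sds > 0)
  if (length(keep) < ncol(X))
    warning(sprintf("dropping %d constant covariate column(s) before standardization",
                    ncol(X) - length(keep)), call. = FALSE)
  if (!length(keep)) stop("all covariate columns are constant", call. = FALSE)
  Xk <- X[, keep, drop = FALSE]
  if (is.null(t_support)) {
    t_lo <- apply(train$T, 2L, min); t_hi <- apply(train$T, 2L, max)
  } else {
    t_lo <- rep(t_support[1], train$tau); t_hi <- rep(t_support[2], train$tau)
  }
  t_span <- ifelse(t_hi > t_lo, t_hi - t_lo, 1)
  y_sd <- stats::sd(train$Y)
  list(keep = keep,
       x_center = colMeans(Xk), x_scale = sds[keep],
       t_lo = t_lo, t_span = t_span,
       y_center = mean(train$Y), y_scale = if (y_sd > 0) y_sd else 1)
}

scale_X <- function(sc, X) {
  X <- X[, sc$keep, drop = FALSE]
  sweep(sweep(X, 2L, sc$x_center), 2L, sc$x_scale, `/`)
}
scale_T <- function(sc, T) sweep(sweep(T, 2L, sc$t_lo), 2L, sc$t_span, `/`)
# doses enter the networks on [-1, 1]: same scale as the z-scored covariates,
# centered for tanh units
dose_input <- function(ts) 2 * ts - 1
scale_Y <- function(sc, Y) (Y - sc$y_center) / sc$y_scale
unscale_Y <- function(sc, Ys) Ys * sc$y_scale + sc$y_center

# --- generic seeded training loop ------------------------------------------
# `engine` provides init(), forward(params, Xs, Ts) -> list(pred, ...caches),
# and backward(params, fw, dPred) -> grads. All RNG draws (init, validation
# split, epoch shuffling) are consumed sequentially from one stream seeded by
# `seed`, so a fit is a pure function of (data, config, seed).
train_engine <- function(engine, train, config, seed, model_class) {
  stopifnot(inherits(train, "observational_dataset"))
  sc <- make_scaler(train, config$t_support)
  Xs <- scale_X(sc, train$X)
  Ts <- scale_T(sc, train$T)
  Ys <- scale_Y(sc, train$Y)
  n <- nrow(Xs)

  fit <- with_seed(seed, {
    params <- engine$init(p = ncol(Xs), tau = ncol(Ts))
    n_val <- if (config$val_frac > 0 && n >= 10L) floor(config$val_frac * n) else 0L
    idx_val <- if (n_val > 0L) sample.int(n, n_val) else integer(0)
    idx_tr <- setdiff(seq_len(n), idx_val)
    bs <- config$batch_size
    if (is.null(bs)) bs <- if (length(idx_tr) <= 1000L) length(idx_tr) else 256L
    opt <- adam_init(params)
    best <- list(params = params, val = Inf, epoch = 0L)
    wait <- 0L
    loss <- NA_real_
    for (epoch in seq_len(config$epochs)) {
      ord <- if (bs < length(idx_tr)) idx_tr[sample.int(length(idx_tr))] else idx_tr
      for (start in seq(1L, length(ord), by = bs)) {
        b <- ord[start:min(start + bs - 1L, length(ord))]
        fw <- engine$forward(params, Xs[b, , drop = FALSE], Ts[b, , drop = FALSE])
        resid <- fw$pred - Ys[b]
        if (!all(is.finite(resid)))
          stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
               call. = FALSE)
        grads <- engine$backward(params, fw, matrix(2 * resid / length(b), ncol = 1L))
        step <- adam_step(params, grads, opt, lr = config$lr,
                          weight_decay = config$weight_decay)
        params <- step$params; opt <- step$state
        loss <- mean(resid^2)
      }
      if (n_val > 0L) {
        # optional early stopping on the held-out split, best weights kept
        mon <- engine$forward(params, Xs[idx_val, , drop = FALSE],
                              Ts[idx_val, , drop = FALSE])
        vloss <- mean((mon$pred - Ys[idx_val])^2)
        if (!is.finite(vloss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
               call. = FALSE)
        if (vloss < best$val - 1e-9) {
          best <- list(params = params, val = vloss, epoch = epoch)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= config$patience) break
        }
      }
    }
    if (n_val == 0L) best <- list(params = params, val = loss, epoch = epoch)
    list(params = best$params, best_epoch = best$epoch, best_val = best$val,
         epochs_run = epoch)
  })

  structure(
    list(params = fit$params, scaler = sc, config = config, seed = as.integer(seed),
         p = train$p, tau = train$tau, engine_name = model_class,
         best_epoch = fit$best_epoch, val_loss = fit$best_val,
         epochs_run = fit$epochs_run),
    class = c(model_class, "hnet_fit"))
}

#' Total number of trainable parameters of a fitted model
#' @param model a fitted `hnet_model` or `slearner_model`.
#' @return Integer scalar.
#' @export
n_trainable_params <- function(model) {
  stopifnot(inherits(model, "hnet_fit"))
  length(tree_flatten(model$params))
}

#' @export
print.hnet_fit <- function(x, ...) {
  cat(sprintf("<%s> p = %d, tau = %d, %d trainable parameters\n",
              class(x)[1], x$p, x$tau, n_trainable_params(x)))
  cat(sprintf("  trained %d epochs (best at %d), monitored MSE %.4g (scaled outcome)\n",
              x$epochs_run, x$best_epoch, x$val_loss))
  invisible(x)
}
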