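#' Fit the neural S-learner ablation baseline
#'
#' The S-learner treats the dose as one more input feature: the same encoder
#' architecture as [fit_hnet()] produces a representation `z = f(x)`, and a
#' plain multi-layer perceptron head consumes the concatenation `(z, t)` to
#' predict the outcome. This is the direct ablation of the hypernetwork
#' mechanism — identical data scaling, optimizer, stopping rule and seed
#' handling, with the weight-generating pathway replaced by feature
#' concatenation — so benchmark gaps between the two isolate the mechanism.
#'
#' With `raw_covariates = TRUE` the head consumes `(x, t)` directly and no
#' encoder is used (the classic S-learner on raw inputs).
#'
#' @inheritParams fit_hnet
#' @param raw_covariates if `TRUE`, skip the learned representation.
#' @return Object of class `c("slearner_model", "hnet_fit")`.
#' @export
fit_slearner <- function(train, config = hnet_config(), seed = 1L,
                         raw_covariates = FALSE) {
  stopifnot(inherits(config, "hnet_config"))
  engine <- slearner_engine(config, raw_covariates)
  model <- train_engine(engine, train, config, seed, "slearner_model")
  model$raw_covariates <- raw_covariates
  model
}

slearner_engine <- function(config, raw_covariates = FALSE) {
  act <- config$activation
  if (raw_covariates) {
    return(list(
      init = function(p, tau)
        list(head = mlp_init(c(p + tau, config$head_widths, 1L))),
      forward = function(params, Xs, Ts) {
        hf <- mlp_forward(params$head, cbind(Xs, dose_input(Ts)), act)
        list(pred = hf$out[, 1L], hf = hf)
      },
      backward = function(params, fw, dPred)
        list(head = mlp_backward(params$head, fw$hf, dPred, act)$grads)))
  }
  list(
    init = function(p, tau) {
      list(enc = mlp_init(c(p, config$encoder_widths, config$repr_dim)),
           head = mlp_init(c(config$repr_dim + tau, config$head_widths, 1L)))
    },
    forward = function(params, Xs, Ts) {
      ef <- mlp_forward(params$enc, Xs, act, out_act = TRUE)
      hf <- mlp_forward(params$head, cbind(ef$out, dose_input(Ts)), act)
      list(pred = hf$out[, 1L], ef = ef, hf = hf)
    },
    backward = function(params, fw, dPred) {
      hb <- mlp_backward(params$head, fw$hf, dPred, act)
      k <- ncol(fw$ef$out)
      eb <- mlp_backward(params$enc, fw$ef,
                         hb$dIn[, seq_len(k), drop = FALSE], act, out_act = TRUE)
      list(enc = eb$grads, head = hb$grads)
    })
}
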