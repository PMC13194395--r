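#' Save or load a fitted model as a portable JSON archive
#'
#' The archive stores the model class, configuration, scaling maps, seed and
#' the flat parameter vector (full double precision), everything needed to
#' reconstruct predictions exactly. Plain text, so archives are portable and
#' diffable.
#'
#' @param model a fitted `hnet_model` or `slearner_model`.
#' @param path output path (conventionally `.json`).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   reconstructed model, whose predictions equal the original's.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "hnet_fit"))
  cfg <- model$config
  payload <- list(
    format = "hnet-model-1",
    class = model$engine_name,
    p = model$p, tau = model$tau,
    raw_covariates = isTRUE(model$raw_covariates),
    seed = model$seed,
    best_epoch = model$best_epoch, epochs_run = model$epochs_run,
    val_loss = model$val_loss,
    config = unclass(cfg),
    scaler = model$scaler,
    params = tree_flatten(model$params))
  jsonlite::write_json(payload, path, auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(pl$format, "hnet-model-1"))
    stop("not a model archive written by save_model()", call. = FALSE)
  cfg_args <- pl$config[!vapply(pl$config, is.null, logical(1))]
  config <- do.call(hnet_config, cfg_args)
  sc <- pl$scaler
  sc$keep <- as.integer(sc$keep)
  p_kept <- length(sc$keep)
  # zero-parameter skeleton with the right shapes, then fill from the archive
  zero_mlp <- function(widths) lapply(seq_len(length(widths) - 1L), function(l)
    list(W = matrix(0, widths[l], widths[l + 1L]), b = numeric(widths[l + 1L])))
  if (pl$class == "hnet_model") {
    tspec <- target_net_spec(pl$tau, config$target_hidden, config$activation)
    skel <- list(enc = zero_mlp(c(p_kept, config$encoder_widths, config$repr_dim)),
                 hyp = zero_mlp(c(config$repr_dim, config$hyper_widths, tspec$m)))
  } else if (isTRUE(pl$raw_covariates)) {
    skel <- list(head = zero_mlp(c(p_kept + pl$tau, config$head_widths, 1L)))
  } else {
    skel <- list(enc = zero_mlp(c(p_kept, config$encoder_widths, config$repr_dim)),
                 head = zero_mlp(c(config$repr_dim + pl$tau, config$head_widths, 1L)))
  }
  model <- structure(
    list(params = tree_unflatten(skel, as.numeric(pl$params)),
         scaler = sc, config = config, seed = as.integer(pl$seed),
         p = as.integer(pl$p), tau = as.integer(pl$tau),
         engine_name = pl$class,
         best_epoch = pl$best_epoch, val_loss = pl$val_loss,
         epochs_run = pl$epochs_run),
    class = c(pl$class, "hnet_fit"))
  if (pl$class == "hnet_model") model$target_spec <- tspec
  if (pl$class == "slearner_model") model$raw_covariates <- isTRUE(pl$raw_covariates)
  model
}
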