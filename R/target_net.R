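#' Fixed architecture of the per-instance target network
#'
#' The target network `h_omega` maps a treatment value (dimension `tau`) to a
#' predicted outcome through a small feed-forward network whose architecture is
#' fixed at model construction; only its weight vector `omega` varies, being
#' generated per instance by the hypernetwork. The total number of scalar
#' parameters is `m = sum over layers (fan_in * fan_out + fan_out)`.
#'
#' @param input_dim treatment dimensionality `tau` (>= 1).
#' @param hidden_widths integer vector of hidden-layer widths; may be empty
#'   (`integer(0)`) for a purely affine dose-response.
#' @param activation smooth hidden nonlinearity; `"tanh"` (default, zero at
#'   zero) or `"relu"`.
#' @return Object of class `target_net_spec` with fields `widths` (full layer
#'   width vector, input to output), `activation`, and the derived parameter
#'   count `m`.
#' @examples
#' target_net_spec(1, 32)$m              # 97
#' target_net_spec(1, integer(0))$m      # 2: one weight, one bias
#' @export
target_net_spec <- function(input_dim = 1L, hidden_widths = 32L,
                            activation = "tanh") {
  input_dim <- as.integer(input_dim)
  hidden_widths <- as.integer(hidden_widths)
  if (is.na(input_dim) || input_dim < 1L)
    stop("input_dim must be a positive integer", call. = FALSE)
  if (length(hidden_widths) && any(hidden_widths < 1L))
    stop("hidden widths must be positive", call. = FALSE)
  activation_fn(activation)  # validates the name
  widths <- c(input_dim, hidden_widths, 1L)
  m <- sum(widths[-length(widths)] * widths[-1] + widths[-1])
  structure(list(widths = widths, activation = activation, m = m),
            class = "target_net_spec")
}

#' @export
print.target_net_spec <- function(x, ...) {
  cat(sprintf("<target_net_spec> %s, activation %s, m = %d parameters\n",
              paste(x$widths, collapse = " -> "), x$activation, x$m))
  invisible(x)
}

#' Number of scalar parameters of a target network
#'
#' Closed form `m = sum_l (fan_in_l * fan_out_l + fan_out_l)` over consecutive
#' layer pairs — every weight plus every bias of the fixed architecture. This
#' is the length of the weight vector the hypernetwork must emit.
#'
#' @param spec a [target_net_spec()].
#' @return Integer count `m`.
#' @export
target_param_count <- function(spec) {
  stopifnot(inherits(spec, "target_net_spec"))
  spec$m
}

# Per-layer slice indices into the flat omega vector. Layout, documented and
# frozen: layers in order input->output; within a layer first the weight
# matrix in column-major order (fan_in x fan_out), then the fan_out biases.
omega_layout <- function(spec) {
  widths <- spec$widths
  out <- vector("list", length(widths) - 1L)
  pos <- 0L
  for (l in seq_along(out)) {
    fi <- widths[l]; fo <- widths[l + 1L]
    out[[l]] <- list(fi = fi, fo = fo,
                     w_idx = pos + seq_len(fi * fo),
                     b_idx = pos + fi * fo + seq_len(fo))
    pos <- pos + fi * fo + fo
  }
  out
}

#' Unpack a flat weight vector into per-layer matrices
#'
#' The layout is fixed: layers from input to output; within each layer the
#' `fan_in x fan_out` weight matrix in column-major order, followed by the
#' `fan_out` biases. [pack_weights()] is its exact inverse.
#'
#' @param omega numeric vector of length `m`.
#' @param spec a [target_net_spec()].
#' @return List of layers, each `list(W = fan_in x fan_out matrix, b = vector)`.
#' @export
unpack_weights <- function(omega, spec) {
  stopifnot(inherits(spec, "target_net_spec"))
  if (length(omega) != spec$m)
    stop(sprintf("omega has length %d but the spec requires m = %d",
                 length(omega), spec$m), call. = FALSE)
  lapply(omega_layout(spec), function(ly)
    list(W = matrix(omega[ly$w_idx], ly$fi, ly$fo), b = omega[ly$b_idx]))
}

#' @rdname unpack_weights
#' @param layers a per-layer list as returned by [unpack_weights()].
#' @export
pack_weights <- function(layers, spec) {
  stopifnot(inherits(spec, "target_net_spec"))
  omega <- numeric(spec$m)
  layout <- omega_layout(spec)
  for (l in seq_along(layout)) {
    omega[layout[[l]]$w_idx] <- as.numeric(layers[[l]]$W)
    omega[layout[[l]]$b_idx] <- layers[[l]]$b
  }
  omega
}

#' Evaluate a target network at one treatment point
#'
#' Feed-forward evaluation of the fixed-architecture network defined by `spec`
#' with weights `omega` at treatment `t`. Hidden layers use the spec's
#' activation; the output layer is linear.
#'
#' @param omega flat weight vector of length `m`.
#' @param t numeric treatment vector with `tau` entries.
#' @param spec a [target_net_spec()].
#' @return Scalar predicted outcome.
#' @export
apply_target_network <- function(omega, t, spec) {
  stopifnot(inherits(spec, "target_net_spec"))
  t <- as.numeric(t)
  if (length(t) != spec$widths[1])
    stop(sprintf("t has %d entries but the spec expects tau = %d",
                 length(t), spec$widths[1]), call. = FALSE)
  layers <- unpack_weights(omega, spec)
  act <- activation_fn(spec$activation)
  a <- matrix(t, nrow = 1L)
  for (l in seq_along(layers)) {
    z <- a %*% layers[[l]]$W + matrix(layers[[l]]$b, nrow = 1L)
    a <- if (l < length(layers)) act$f(z) else z
  }
  as.numeric(a)
}

# --- Batched evaluation with per-row weights -------------------------------
#
# Omega is n x m: row i holds the weights generated for sample i. Activations
# are carried as n x width matrices; layer l is applied row-wise:
#   pre[i, j] = sum_r A[i, r] * W_i[r, j] + b_i[j]
# implemented as a loop over output units j (widths are small) with fully
# vectorized elementwise products over the batch.

target_forward_batch <- function(Omega, Tmat, spec) {
  act <- activation_fn(spec$activation)
  layout <- omega_layout(spec)
  L <- length(layout)
  n <- nrow(Omega)
  A <- vector("list", L + 1L); pre <- vector("list", L)
  A[[1L]] <- Tmat
  for (l in seq_len(L)) {
    fi <- layout[[l]]$fi; fo <- layout[[l]]$fo
    W <- Omega[, layout[[l]]$w_idx, drop = FALSE]
    B <- Omega[, layout[[l]]$b_idx, drop = FALSE]
    z <- matrix(0, n, fo)
    for (j in seq_len(fo)) {
      cols <- (j - 1L) * fi + seq_len(fi)
      z[, j] <- rowSums(A[[l]] * W[, cols, drop = FALSE]) + B[, j]
    }
    pre[[l]] <- z
    A[[l + 1L]] <- if (l < L) act$f(z) else z
  }
  list(out = A[[L + 1L]][, 1L], A = A, pre = pre)
}

# dOut: length-n gradient of the loss w.r.t. the scalar outputs.
# Returns dOmega (n x m); the treatment input is not differentiated.
target_backward_batch <- function(Omega, cache, dOut, spec) {
  act <- activation_fn(spec$activation)
  layout <- omega_layout(spec)
  L <- length(layout)
  n <- nrow(Omega)
  dOmega <- matrix(0, n, spec$m)
  delta <- matrix(dOut, n, 1L)
  for (l in rev(seq_len(L))) {
    fi <- layout[[l]]$fi; fo <- layout[[l]]$fo
    W <- Omega[, layout[[l]]$w_idx, drop = FALSE]
    dA_prev <- matrix(0, n, fi)
    for (j in seq_len(fo)) {
      cols <- (j - 1L) * fi + seq_len(fi)
      dOmega[, layout[[l]]$w_idx[cols]] <- cache$A[[l]] * delta[, j]
      dA_prev <- dA_prev + W[, cols, drop = FALSE] * delta[, j]
    }
    dOmega[, layout[[l]]$b_idx] <- delta
    if (l > 1L)
      delta <- dA_prev * act$grad(cache$pre[[l - 1L]], cache$A[[l]])
  }
  dOmega
}
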