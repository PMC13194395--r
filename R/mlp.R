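# Internal dense-network machinery shared by the encoder, the hypernetwork and
# the S-learner head. Everything is plain matrix algebra so that training is
# exactly reproducible from a seed and gradients can be audited by finite
# differences.

activation_fn <- function(name) {
  switch(name,
    tanh = list(f = tanh, grad = function(pre, act) 1 - act * act),
    relu = list(f = function(z) pmax(z, 0),
                grad = function(pre, act) (pre > 0) * 1),
    stop(sprintf("unknown activation '%s'", name), call. = FALSE))
}

# A network is a list of layers, each list(W = fan_in x fan_out, b = fan_out).
# Weights start at N(0, 1/fan_in) (fan-in scaling, suited to tanh), biases at 0.
# Uses the current RNG state; callers fix the seed.
mlp_init <- function(widths, w_sd_scale = 1) {
  lapply(seq_len(length(widths) - 1L), function(l) {
    fi <- widths[l]; fo <- widths[l + 1L]
    list(W = matrix(stats::rnorm(fi * fo, sd = w_sd_scale / sqrt(fi)), fi, fo),
         b = numeric(fo))
  })
}

# Forward pass with caches for backprop. Hidden layers use `activation`; the
# final layer is linear unless out_act = TRUE (used by the encoder so the
# representation stays bounded). A0 is n x widths[1].
mlp_forward <- function(net, A0, activation = "tanh", out_act = FALSE) {
  act <- activation_fn(activation)
  L <- length(net)
  A <- vector("list", L + 1L); pre <- vector("list", L)
  A[[1L]] <- A0
  for (l in seq_len(L)) {
    z <- A[[l]] %*% net[[l]]$W
    z <- sweep(z, 2L, net[[l]]$b, `+`)
    pre[[l]] <- z
    A[[l + 1L]] <- if (l < L || out_act) act$f(z) else z
  }
  list(out = A[[L + 1L]], A = A, pre = pre)
}

# Backward pass: dOut is n x fan_out_last = dLoss/d(out). Returns per-layer
# gradients and the gradient w.r.t. the input matrix.
mlp_backward <- function(net, cache, dOut, activation = "tanh", out_act = FALSE) {
  act <- activation_fn(activation)
  L <- length(net)
  grads <- vector("list", L)
  delta <- if (out_act) dOut * act$grad(cache$pre[[L]], cache$A[[L + 1L]]) else dOut
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(cache$A[[l]], delta),
                       b = colSums(delta))
    dA <- delta %*% t(net[[l]]$W)
    if (l > 1L)
      delta <- dA * act$grad(cache$pre[[l - 1L]], cache$A[[l]])
    else
      dIn <- dA
  }
  list(grads = grads, dIn = dIn)
}

# --- Adam over nested parameter lists ------------------------------------

# Parameters live in nested lists of numeric arrays (networks of layers of
# W/b). tree_map applies f elementwise across parallel structures.
tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1L]])) {
    out <- lapply(seq_along(trees[[1L]]), function(i)
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i))))
    names(out) <- names(trees[[1L]])
    return(out)
  }
  do.call(f, trees)
}

adam_init <- function(params) {
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  params <- tree_map(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
                     params, state$m, state$v)
  # decoupled (AdamW-style) weight decay on weight matrices only; biases are
  # exempt — in the hypernetwork the output bias carries the shared
  # dose-response curve and must not be shrunk toward zero
  if (weight_decay > 0) params <- decay_weights(params, 1 - lr * weight_decay)
  list(params = params, state = state)
}

decay_weights <- function(tree, factor) {
  if (is.list(tree)) {
    nm <- names(tree)
    if (!is.null(nm) && setequal(nm, c("W", "b"))) {
      tree$W <- tree$W * factor
      return(tree)
    }
    return(lapply(tree, decay_weights, factor = factor))
  }
  tree
}

# Flatten/unflatten a nested parameter tree to one numeric vector (used by the
# finite-difference gradient checks and model serialization).
tree_flatten <- function(tree) {
  if (is.list(tree)) return(unlist(lapply(tree, tree_flatten), use.names = FALSE))
  as.numeric(tree)
}

tree_unflatten <- function(tree, values) {
  pos <- 0L
  rebuild <- function(node) {
    if (is.list(node)) return(lapply(node, rebuild))
    k <- length(node)
    out <- array(values[pos + seq_len(k)], dim = if (is.null(dim(node))) k else dim(node))
    pos <<- pos + k
    out
  }
  out <- rebuild(tree)
  stopifnot(pos == length(values))
  out
}
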