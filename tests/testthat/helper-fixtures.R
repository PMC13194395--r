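# Shared fixtures: everything is generated in code at test time.

# A small observational dataset with a known affine oracle.
tiny_dataset <- function(n = 30L, p = 3L, seed = 1L) {
  generate_linear_dgp(n = n, p = p, seed = seed)$dataset
}

# Fast training configuration for unit tests that only need a trained object,
# not benchmark-quality fits.
tiny_config <- function(epochs = 40L, ...) {
  hnet_config(repr_dim = 4L, encoder_widths = 8L, hyper_widths = 8L,
              head_widths = c(8L, 8L), target_hidden = 4L,
              epochs = epochs, t_support = c(0, 1), ...)
}

# Central finite-difference gradient of a scalar function at x.
numeric_gradient <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}
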