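# Synthetic confounded data-generating processes with known counterfactual
# ground truth, used for benchmarking and for oracle-based unit tests.

#' Specification of a synthetic benchmark instance
#'
#' @param name generator name; currently `"nie2021"`.
#' @param n_train,n_test sample sizes of the train and test parts.
#' @param treatment_noise_sd standard deviation of the Gaussian noise added to
#'   the confounded treatment score before the logistic squashing.
#' @param outcome_noise_sd standard deviation of the additive Gaussian outcome
#'   noise.
#' @param seed integer seed; the whole instance is a pure function of it.
#' @return List of class `dgp_spec`.
#' @export
dgp_spec <- function(name = "nie2021", n_train = 500L, n_test = 200L,
                     treatment_noise_sd = 0.5, outcome_noise_sd = 0.5,
                     seed = 1L) {
  spec <- list(name = name, n_train = as.integer(n_train),
               n_test = as.integer(n_test),
               treatment_noise_sd = treatment_noise_sd,
               outcome_noise_sd = outcome_noise_sd, seed = as.integer(seed))
  stopifnot(spec$n_train >= 1L, spec$n_test >= 1L,
            spec$treatment_noise_sd >= 0, spec$outcome_noise_sd >= 0)
  class(spec) <- "dgp_spec"
  spec
}

# Confounded treatment score and outcome surface of the fully synthetic
# benchmark (the DGP of the varying-coefficient-network literature):
#   x1..x6 ~ iid Uniform(0, 1)
#   score(x) = (10 sin(max(x1,x2,x3)) + max(x3,x4,x5)^3) / (1 + (x1+x5)^2)
#              + sin(0.5 x3) (1 + exp(x4 - 0.5 x3)) + x3^2 + 2 sin(x4)
#              + 2 x5 - 6.5
#   t = logistic(score(x) + eps_t),            eps_t ~ N(0, sd_t^2)
#   y(t, x) = cos(2 pi (t - 1/2)) (t^2 + 4 max(x1,x6)^3 sin(x4) / (1 + 2 x3^2))
#   Y = y(t, x) + eps_y,                       eps_y ~ N(0, sd_y^2)
# The treatment is confounded: the same covariates drive both the dose and the
# outcome surface. t lies strictly inside (0, 1) by construction.
nie2021_score <- function(X) {
  x1 <- X[, 1]; x2 <- X[, 2]; x3 <- X[, 3]
  x4 <- X[, 4]; x5 <- X[, 5]; x6 <- X[, 6]
  (10 * sin(pmax(x1, x2, x3)) + pmax(x3, x4, x5)^3) / (1 + (x1 + x5)^2) +
    sin(0.5 * x3) * (1 + exp(x4 - 0.5 * x3)) +
    x3^2 + 2 * sin(x4) + 2 * x5 - 6.5
}

nie2021_outcome <- function(t, X) {
  x1 <- X[, 1]; x3 <- X[, 3]; x4 <- X[, 4]; x6 <- X[, 6]
  t <- as.numeric(t)
  cos((t - 0.5) * 2 * pi) * (t^2 + (4 * pmax(x1, x6)^3) / (1 + 2 * x3^2) * sin(x4))
}

#' The fully synthetic confounded benchmark generator
#'
#' Generates one benchmark instance: 6 independent Uniform(0, 1) covariates, a
#' continuous dose produced by squashing a nonlinear confounded covariate
#' score (plus Gaussian noise) through the logistic function, and an outcome
#' that is a smooth nonlinear function of dose and covariates plus Gaussian
#' noise. The returned oracle evaluates the noiseless outcome surface
#' `y(t, x)`, so MISE/AMSE can be computed exactly. See the package source of
#' `nie2021_score()`/`nie2021_outcome()` for the transcribed formulas.
#'
#' Train and test rows are drawn from the same seeded stream: the instance is
#' fully reproducible from `spec$seed`.
#'
#' @param spec a [dgp_spec()] with `name = "nie2021"`.
#' @return List with `train` and `test` ([observational_dataset()]s, both
#'   carrying the oracle) and `oracle` (the [dose_response_oracle()]).
#' @examples
#' inst <- generate_nie2021(dgp_spec(n_train = 50, n_test = 20, seed = 3))
#' inst$train; range(inst$train$T)
#' @export
generate_nie2021 <- function(spec = dgp_spec()) {
  stopifnot(inherits(spec, "dgp_spec"))
  if (spec$name != "nie2021")
    stop(sprintf("unknown generator '%s'", spec$name), call. = FALSE)
  oracle <- dose_response_oracle(function(t, x) nie2021_outcome(t[, 1], x))
  gen <- function(n) {
    X <- matrix(stats::runif(n * 6L), n, 6L)
    score <- nie2021_score(X) + stats::rnorm(n, sd = spec$treatment_noise_sd)
    t <- stats::plogis(score)
    y0 <- nie2021_outcome(t, X)
    Y <- y0 + stats::rnorm(n, sd = spec$outcome_noise_sd)
    observational_dataset(X, t, Y, truth = oracle)
  }
  with_seed(spec$seed, {
    train <- gen(spec$n_train)
    test <- gen(spec$n_test)
    list(train = train, test = test, oracle = oracle)
  })
}

#' Linear-in-dose synthetic generator for parameter-recovery tests
#'
#' Generates `y = intercept_fn(x) + slope_fn(x) * t + eps` with covariates
#' `x ~ Uniform(0,1)^p` and dose
#' `t = logistic(confounding_strength * (mean(x) - 1/2) + eps_t)`, so
#' `confounding_strength = 0` gives a randomized design and larger values tie
#' the dose to the covariates. The oracle is the noiseless affine-in-`t`
#' function, so the true individual effect of moving from dose 0 to dose 1 is
#' exactly `slope_fn(x)`.
#'
#' @param n,p sample size and covariate dimension.
#' @param slope_fn,intercept_fn functions of the covariate matrix returning a
#'   vector of length `n`; defaults: constant slope 2, intercept 0.
#' @param confounding_strength scale of the covariate-dependent dose score.
#' @param noise_sd outcome noise standard deviation.
#' @param t_noise_sd dose-score noise standard deviation.
#' @param seed integer seed.
#' @return List with `dataset` (carrying the oracle) and `oracle`.
#' @export
generate_linear_dgp <- function(n, p = 2L,
                                slope_fn = function(X) rep(2, nrow(X)),
                                intercept_fn = function(X) rep(0, nrow(X)),
                                confounding_strength = 0,
                                noise_sd = 0.1,
                                t_noise_sd = 1,
                                seed = 1L) {
  stopifnot(n >= 1L, p >= 1L)
  oracle <- dose_response_oracle(function(t, x)
    intercept_fn(x) + slope_fn(x) * t[, 1])
  with_seed(seed, {
    X <- matrix(stats::runif(n * p), n, p)
    score <- confounding_strength * (rowMeans(X) - 0.5) +
      stats::rnorm(n, sd = t_noise_sd)
    t <- stats::plogis(score)
    Y <- intercept_fn(X) + slope_fn(X) * t + stats::rnorm(n, sd = noise_sd)
    list(dataset = observational_dataset(X, t, Y, truth = oracle),
         oracle = oracle)
  })
}

#' Derived seeds for a stream of benchmark replicates
#'
#' Maps a base seed to `R` distinct replicate seeds through a fixed affine
#' congruential scheme, `seed_r = (base_seed * 100003 + r) mod 2147483629`,
#' so replicate `r` can be regenerated in isolation and different base seeds
#' give non-overlapping streams with overwhelming probability.
#'
#' @param base_seed integer.
#' @param R number of replicates (>= 1).
#' @return Integer vector of `R` distinct seeds.
#' @export
replicate_stream <- function(base_seed, R) {
  stopifnot(R >= 1L)
  s <- (as.numeric(base_seed) %% 2147483629) * 100003 + seq_len(R)
  as.integer(s %% 2147483629)
}

#' Adapters for the semi-synthetic benchmarks (stubs)
#'
#' The continuous-IHDP and TCGA benchmarks reuse externally distributed
#' covariate tables that this package does not ship. These adapters document
#' the expected inputs and construct nothing: supply the covariate file and a
#' generator built on it. They are excluded from tests and benchmarks.
#'
#' @param covariates_path path to the user-supplied covariate table.
#' @name semi_synthetic_adapters
#' @export
generate_ihdp_continuous <- function(covariates_path) {
  stop(paste("the continuous-IHDP benchmark needs the externally distributed",
             "IHDP covariate table; download it and build an",
             "observational_dataset from it with load_dataset()"),
       call. = FALSE)
}

#' @rdname semi_synthetic_adapters
#' @export
generate_tcga <- function(covariates_path) {
  stop(paste("the TCGA benchmark needs the externally distributed 4000-dim",
             "gene-expression covariates; download them and build an",
             "observational_dataset from them with load_dataset()"),
       call. = FALSE)
}
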