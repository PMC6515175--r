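# shared helpers: independent numerical oracles and a cached trained fixture

rand_window <- function(t = 64, c = 16) matrix(rnorm(t * c), t, c)

# flatten a latent_feature into a fixed-order vector (retained, split1, split2)
latent_as_vector <- function(z) {
  c(as.vector(z$retained), as.vector(z$splits[[1]]), as.vector(z$splits[[2]]))
}

# brute-force log|det Jacobian| of the full forward map by central differences;
# independent of the analytic log-determinant accumulation under test
numeric_logdet <- function(flow, x, eps = 1e-5) {
  f <- function(v) latent_as_vector(flow_forward(flow, matrix(v, nrow(x), ncol(x))))
  v0 <- as.vector(x)
  n <- length(v0)
  jac <- matrix(0, n, n)
  for (k in seq_len(n)) {
    vp <- v0; vm <- v0
    vp[k] <- vp[k] + eps
    vm[k] <- vm[k] - eps
    jac[, k] <- (f(vp) - f(vm)) / (2 * eps)
  }
  as.numeric(determinant(jac, logarithm = TRUE)$modulus)
}

# central-difference gradient of a scalar function at selected coordinates
numeric_gradient <- function(f, v0, idx, eps = 1e-5) {
  vapply(idx, function(k) {
    vp <- v0; vm <- v0
    vp[k] <- vp[k] + eps
    vm[k] <- vm[k] - eps
    (f(vp) - f(vm)) / (2 * eps)
  }, numeric(1))
}

# one trained model on the default synthetic dataset, shared across test
# files (trained once per session)
.fixture_env <- new.env(parent = emptyenv())

trained_fixture <- function() {
  if (is.null(.fixture_env$fit)) {
    ds <- make_synthetic_dataset(synthetic_spec(seed = 5))
    parts <- split_random(ds$examples, seed = 5)
    fit <- train_model(parts$train, training_config(epochs = 15, seed = 5))
    .fixture_env$fit <- fit
    .fixture_env$train <- parts$train
    .fixture_env$test <- parts$test
    .fixture_env$truth <- ds$truth
  }
  list(fit = .fixture_env$fit, train = .fixture_env$train,
       test = .fixture_env$test, truth = .fixture_env$truth)
}
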