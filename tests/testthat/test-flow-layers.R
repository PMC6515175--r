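# individual invertible layers: forward/inverse consistency and exact
# log-determinants against finite-difference Jacobian oracles

test_that("actnorm with zero parameters is the identity with zero logdet", {
  p <- actnorm_params(4, initialized = TRUE)
  x <- rand_window(6, 4)
  r <- actnorm_apply(p, x)
  expect_equal(r$y, x)
  expect_equal(r$logdet, 0)
})

test_that("actnorm logdet matches the Jacobian of the flattened affine map", {
  # scales (2, 0.5): logdet = T * (ln 2 + ln 0.5) = 0
  p <- actnorm_params(2, log_scale = log(c(2, 0.5)), initialized = TRUE)
  x <- rand_window(4, 2)
  r <- actnorm_apply(p, x)
  expect_equal(r$logdet, 0)
  # finite-difference oracle on a non-volume-preserving case
  set.seed(3)
  p2 <- actnorm_params(2, log_scale = c(0.3, -0.7), bias = c(1, -2), initialized = TRUE)
  f <- function(v) as.vector(actnorm_apply(p2, matrix(v, 4, 2))$y)
  eps <- 1e-6
  v0 <- as.vector(x)
  jac <- sapply(seq_along(v0), function(k) {
    vp <- v0; vm <- v0; vp[k] <- vp[k] + eps; vm[k] <- vm[k] - eps
    (f(vp) - f(vm)) / (2 * eps)
  })
  expect_equal(actnorm_apply(p2, x)$logdet,
               as.numeric(determinant(jac, logarithm = TRUE)$modulus),
               tolerance = 1e-6)
})

test_that("actnorm inverse composes to the identity", {
  set.seed(4)
  p <- actnorm_params(5, log_scale = rnorm(5), bias = rnorm(5), initialized = TRUE)
  x <- rand_window(7, 5)
  y <- actnorm_apply(p, x)$y
  expect_equal(actnorm_apply(p, y, "inverse")$y, x, tolerance = 1e-6)
})

test_that("data-dependent actnorm init standardizes the batch per channel", {
  set.seed(5)
  batch <- array(rnorm(10 * 6 * 3, mean = 3, sd = 2), c(10, 6, 3))
  p <- actnorm_init_from_batch(actnorm_params(3), batch)
  expect_true(p$initialized)
  m <- matrix(aperm(batch, c(2, 1, 3)), ncol = 3)
  out <- actnorm_apply(p, m)$y
  expect_equal(colMeans(out), rep(0, 3), tolerance = 1e-10)
  expect_equal(colMeans(sweep(out, 2, colMeans(out))^2), rep(1, 3), tolerance = 1e-10)
  # near-identity params when the batch is already standardized
  p2 <- actnorm_init_from_batch(actnorm_params(3), out)
  expect_equal(p2$log_scale, rep(0, 3), tolerance = 1e-10)
  expect_equal(p2$bias, rep(0, 3), tolerance = 1e-10)
  # a constant channel cannot be standardized
  bad <- cbind(m[, 1:2], 5)
  expect_error(actnorm_init_from_batch(actnorm_params(3), bad), "zero-variance")
})

test_that("channel mixing applies the matrix per time-row with exact logdet", {
  x <- rand_window(4, 2)
  id <- inv_mix_params(2, diag(2))
  r <- inv_mix_apply(id, x)
  expect_equal(r$y, x)
  expect_equal(r$logdet, 0)
  # permutation: channels swapped, volume preserved
  perm <- inv_mix_params(2, matrix(c(0, 1, 1, 0), 2, 2))
  rp <- inv_mix_apply(perm, x)
  expect_equal(rp$y, x[, c(2, 1)])
  expect_equal(rp$logdet, 0)
  # uniform scaling: logdet = T * log|det(2I)| = 4 * log 4
  two <- inv_mix_params(2, 2 * diag(2))
  expect_equal(inv_mix_apply(two, x)$logdet, 4 * log(4))
  expect_error(inv_mix_apply(inv_mix_params(2, matrix(1, 2, 2)), x), "singular")
})

test_that("channel mixing inverse composes to the identity", {
  set.seed(6)
  p <- inv_mix_params(6)
  x <- rand_window(9, 6)
  y <- inv_mix_apply(p, x)$y
  expect_equal(inv_mix_apply(p, y, "inverse")$y, x, tolerance = 1e-8)
})

test_that("affine coupling is the exact identity at initialization", {
  set.seed(7)
  p <- coupling_params(6, hidden = 8)
  x <- rand_window(5, 6)
  r <- coupling_apply(p, x)
  expect_equal(r$y, x)
  expect_equal(r$logdet, 0)
  expect_error(coupling_apply(coupling_params(6, hidden = 8), rand_window(5, 5)), "even")
})

test_that("affine coupling round-trips and its logdet matches the numeric Jacobian", {
  set.seed(8)
  p <- coupling_params(4, hidden = 6)
  p$w2 <- matrix(rnorm(length(p$w2), sd = 0.4), nrow(p$w2), ncol(p$w2))
  p$b2 <- rnorm(length(p$b2), sd = 0.2)
  x <- rand_window(4, 4)
  r <- coupling_apply(p, x)
  expect_equal(coupling_apply(p, r$y, "inverse")$y, x, tolerance = 1e-5)
  f <- function(v) as.vector(coupling_apply(p, matrix(v, 4, 4))$y)
  v0 <- as.vector(x)
  eps <- 1e-6
  jac <- sapply(seq_along(v0), function(k) {
    vp <- v0; vm <- v0; vp[k] <- vp[k] + eps; vm[k] <- vm[k] - eps
    (f(vp) - f(vm)) / (2 * eps)
  })
  expect_equal(r$logdet, as.numeric(determinant(jac, logarithm = TRUE)$modulus),
               tolerance = 1e-4)
})

test_that("multi-scale split halves the elements and scores the Gaussian half", {
  x <- rand_window(64, 16)
  s <- multiscale_split(x, axis = "time")
  expect_equal(dim(s$retained), c(32, 16))
  expect_equal(dim(s$gaussianized), c(32, 16))
  expect_equal(s$logprob_contrib, sum(dnorm(s$gaussianized, log = TRUE)))
  # standard-normal density at zero: 512 * log(1/sqrt(2*pi))
  s0 <- multiscale_split(matrix(0, 64, 16), axis = "time")
  expect_equal(s0$logprob_contrib, 512 * log(1 / sqrt(2 * pi)))
  sc <- multiscale_split(x, axis = "channel")
  expect_equal(dim(sc$retained), c(64, 8))
})

test_that("multi-scale merge is the bit-exact inverse of split", {
  for (axis in c("time", "channel")) {
    x <- rand_window(8, 4)
    s <- multiscale_split(x, axis = axis)
    expect_identical(multiscale_merge(s$retained, s$gaussianized, axis = axis), x)
  }
  expect_equal(multiscale_merge(matrix(0, 2, 2), matrix(0, 2, 2), "time"), matrix(0, 4, 2))
  expect_error(multiscale_split(rand_window(5, 4), axis = "time"), "even")
  expect_error(multiscale_merge(matrix(0, 2, 2), matrix(0, 3, 2), "time"), "identical shapes")
})
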