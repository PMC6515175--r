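# latent interpretation: centers, correlation matrix, reverse-flow
# generation and dimension sweeps

toy_centers <- function(vectors, gestures = seq_along(vectors) - 1L) {
  out <- tibble::tibble(gesture = as.integer(gestures),
                        center = lapply(vectors, function(v) matrix(v, nrow = 1)),
                        n = 1L)
  class(out) <- c("gesture_centers", class(out))
  out
}

test_that("gesture centers are per-class arithmetic means", {
  lat <- list(matrix(c(1, 1), 1), matrix(c(3, 3), 1), matrix(c(5, 7), 1))
  ctr <- gesture_centers(lat, labels = c(2L, 2L, 4L))
  expect_equal(ctr$gesture, c(2L, 4L))
  expect_equal(ctr$center[[1]], matrix(c(2, 2), 1))
  expect_equal(ctr$center[[2]], matrix(c(5, 7), 1))
  expect_equal(ctr$n, c(2L, 1L))
  # the mean of N copies is the element itself
  z <- matrix(rnorm(8), 2, 4)
  ctr2 <- gesture_centers(rep(list(z), 5), labels = rep(1L, 5))
  expect_equal(ctr2$center[[1]], z)
  expect_error(gesture_centers(list(), labels = integer()), "no latents")
})

test_that("center computation commutes with averaging order", {
  set.seed(15)
  zs <- replicate(11, matrix(rnorm(6), 2, 3), simplify = FALSE)
  ctr <- gesture_centers(zs, labels = rep(0L, 11))
  streaming <- zs[[1]]
  for (k in 2:11) streaming <- streaming + (zs[[k]] - streaming) / k
  expect_equal(ctr$center[[1]], streaming, tolerance = 1e-9)
})

test_that("the correlation matrix holds cosines with unit diagonal and symmetry", {
  ctr <- toy_centers(list(c(1, 0), c(0, 1), c(1, 1)))
  cm <- correlation_matrix(ctr)
  expect_equal(diag(unclass(cm)), rep(1, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(unclass(cm), t(unclass(cm)))
  expect_equal(cm[1, 2], 0)
  expect_equal(cm[1, 3], cos(pi / 4), tolerance = 1e-9)
  expect_true(all(unclass(cm) >= -1 & unclass(cm) <= 1))
})

test_that("the correlation matrix is scale-invariant and flags zero centers", {
  ctr <- toy_centers(list(c(1, 2), c(2, -1), c(0.5, 0.5)))
  cm <- correlation_matrix(ctr)
  ctr_scaled <- ctr
  ctr_scaled$center[[2]] <- 7 * ctr_scaled$center[[2]]
  expect_equal(unclass(correlation_matrix(ctr_scaled)), unclass(cm), tolerance = 1e-12)
  ctr0 <- toy_centers(list(c(1, 0), c(0, 0)))
  expect_warning(cm0 <- correlation_matrix(ctr0), "zero-norm")
  expect_true(is.na(cm0[1, 2]))
  expect_equal(cm0[1, 1], 1)
})

test_that("reverse flow reconstructs a window from its own latent parts", {
  fx <- trained_fixture()
  x <- fx$train$window[[1]]
  z <- flow_forward(fx$fit$flow, x)
  rec <- generate_envelope_from_latent(fx$fit, z$retained, splits = z$splits)
  expect_equal(rec, x, tolerance = 1e-4)
  # identity flow with all-zero latent decodes to the zero window
  fl0 <- flow_init(8, 4, hidden = 6, init = "identity")
  expect_equal(generate_envelope_from_latent(fl0, matrix(0, 4, 2)), matrix(0, 8, 4))
})

test_that("the rest-gesture center decodes to a near-zero envelope", {
  fx <- trained_fixture()
  lat <- compute_latents(fx$fit, fx$train)
  centers <- gesture_centers(lat)
  strengths <- vapply(centers$center, function(z)
    envelope_strength(generate_envelope_from_latent(fx$fit, z)), numeric(1))
  rest <- strengths[centers$gesture == 0]
  active <- strengths[centers$gesture != 0]
  expect_lt(rest, 0.2 * mean(active))
})

test_that("the dimension sweep builds the full one-hot grid within the trained range", {
  fx <- trained_fixture()
  grid <- dimension_sweep_grid(fx$fit, v = 35)
  expect_equal(nrow(grid), 32 * 8)
  expect_setequal(unique(grid$row), 1:32)
  expect_setequal(unique(grid$col), 1:8)
  expect_true(all(vapply(grid$window, function(w) all(dim(w) == c(64, 16)), logical(1))))
  # opposite sweep values generate different envelopes
  gneg <- dimension_sweep_grid(fx$fit, v = -35)
  expect_gt(max(abs(grid$window[[10]] - gneg$window[[10]])), 1e-6)
  # the train-range bound is enforced unless overridden
  expect_error(dimension_sweep_grid(fx$fit, v = 80), "bound")
  expect_s3_class(dimension_sweep_grid(fx$fit, v = 80, force = TRUE), "sweep_grid")
})

test_that("sweeping v = 0 degenerates to 256 copies of the zero-latent baseline", {
  fx <- trained_fixture()
  g0 <- dimension_sweep_grid(fx$fit, v = 0)
  base <- generate_envelope_from_latent(fx$fit, matrix(0, 32, 8))
  devs <- vapply(g0$window, function(w) max(abs(w - base)), numeric(1))
  expect_lt(max(devs), 1e-12)
})

test_that("envelope strength is a homogeneous amplitude summary", {
  expect_equal(envelope_strength(matrix(0, 4, 4)), 0)
  w <- matrix(rnorm(16), 4, 4)
  expect_equal(envelope_strength(3 * w), 3 * envelope_strength(w))
  expect_equal(envelope_strength(w, "rms"), sqrt(mean(w^2)))
})

test_that("generated envelope strength grows with v for most latent dimensions", {
  fx <- trained_fixture()
  smat <- sapply(c(0, 35, 75), function(v)
    vapply(dimension_sweep_grid(fx$fit, v)$window, envelope_strength, numeric(1)))
  frac <- mean(smat[, 2] >= smat[, 1] & smat[, 3] >= smat[, 2])
  expect_gt(frac, 0.6)
})

test_that("tidiers summarize fits, correlation matrices and sweep grids", {
  fx <- trained_fixture()
  expect_identical(tidy(fx$fit), fx$fit$history)
  gl <- glance(fx$fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$epochs, 15)
  lat <- compute_latents(fx$fit, fx$train[1:40, ])
  cm <- correlation_matrix(gesture_centers(lat))
  td <- tidy(cm)
  expect_equal(nrow(td), nrow(cm)^2)
  expect_s3_class(ggplot2::autoplot(cm), "ggplot")
  expect_s3_class(ggplot2::autoplot(fx$fit), "ggplot")
  grid <- dimension_sweep_grid(fx$fit, v = 10)
  expect_s3_class(ggplot2::autoplot(grid), "ggplot")
})
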