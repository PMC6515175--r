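# classifier, compound objective, gradients, splits, joint training

test_that("the zero-initialized classifier is uniform and SoftMax behaves", {
  clf <- classifier_params(53, input_dim = 256)
  p <- classify_latent(clf, matrix(0.5, 32, 8))
  expect_equal(unname(p), rep(1 / 53, 53), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  # a row aligned with the latent wins the argmax
  z <- matrix(rnorm(256), 32, 8)
  clf$weight[17, ] <- 10 * as.numeric(z)
  expect_equal(unname(which.max(classify_latent(clf, z))), 17)
  # shift invariance of the logits
  clf2 <- clf
  clf2$bias <- clf2$bias + 5
  expect_equal(classify_latent(clf, z), classify_latent(clf2, z), tolerance = 1e-9)
  expect_error(classify_latent(clf, matrix(0, 4, 4)), "expects")
})

test_that("compound loss decomposes exactly and uniform CE equals ln(K)", {
  fl <- flow_init(8, 4, hidden = 6, init = "random", seed = 11)
  clf <- classifier_params(53, input_dim = 8)
  windows <- replicate(6, rand_window(8, 4), simplify = FALSE)
  labels <- c(0L, 5L, 12L, 52L, 1L, 0L)
  lb <- compound_loss(fl, clf, windows, labels, ce_weight = 0.37)
  expect_equal(lb$total, lb$nll + 0.37 * lb$ce, tolerance = 1e-9 * abs(lb$total))
  expect_gte(lb$ce, 0)
  # zero-parameter classifier is uniform over the 53 classes
  expect_equal(lb$ce, log(53), tolerance = 1e-12)
  # ce_weight 0 reduces the total to the NLL
  lb0 <- compound_loss(fl, clf, windows, labels, ce_weight = 0)
  expect_identical(lb0$total, lb0$nll)
  expect_error(compound_loss(fl, clf, windows, c(0L, 5L, 12L, 53L, 1L, 0L)), "labels")
})

test_that("single-sample NLL under identity flow is the Gaussian negative log-density", {
  fl <- flow_init(8, 4, hidden = 6, init = "identity", seed = 12)
  clf <- classifier_params(3, input_dim = 8)
  x <- rand_window(8, 4)
  lb <- compound_loss(fl, clf, list(x), 0L, ce_weight = 0)
  expect_equal(lb$total, -sum(dnorm(x, log = TRUE)), tolerance = 1e-10)
})

test_that("analytic gradients match central differences on a tiny model", {
  fl <- flow_init(8, 4, hidden = 6, init = "random", seed = 13)
  clf <- classifier_params(3, input_dim = 8)
  set.seed(13)
  clf$weight <- matrix(rnorm(24, sd = 0.3), 3, 8)
  clf$bias <- rnorm(3, sd = 0.1)
  windows <- replicate(5, rand_window(8, 4), simplify = FALSE)
  labels <- c(0L, 1L, 2L, 1L, 0L)
  g <- flowemg:::compound_loss_grad(fl, clf, windows, labels, ce_weight = 0.7)
  gv <- flowemg:::grads_to_vec(g$flow_grads, g$clf_grads)
  v0 <- flowemg:::params_to_vec(fl, clf)
  f <- function(v) {
    pp <- flowemg:::vec_to_params(v, fl, clf)
    compound_loss(pp$flow, pp$clf, windows, labels, ce_weight = 0.7)$total
  }
  idx <- sort(sample(length(v0), 80))
  num <- numeric_gradient(f, v0, idx)
  rel <- abs(num - gv[idx]) / pmax(abs(num), 1e-6)
  expect_lt(max(rel), 1e-4)
})

test_that("random splits are disjoint, exhaustive, sized 70/30 and seeded", {
  ex <- tibble::tibble(window = replicate(100, matrix(0, 2, 2), simplify = FALSE),
                       label = rep(0:3, 25), subject = rep(1:10, 10),
                       id = 1:100)
  sp <- split_random(ex, seed = 31)
  expect_equal(nrow(sp$train), 70)
  expect_equal(nrow(sp$test), 30)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  expect_setequal(c(sp$train$id, sp$test$id), 1:100)
  expect_identical(split_random(ex, seed = 31), sp)
  expect_false(identical(split_random(ex, seed = 32)$train$id, sp$train$id))
  expect_error(split_random(ex[1, ], seed = 1), "at least 2")
  expect_error(split_random(ex, train_fraction = 1.2), "train_fraction")
})

test_that("subject-wise splits keep subject sets disjoint (7 of 10 by default)", {
  ex <- tibble::tibble(window = replicate(100, matrix(0, 2, 2), simplify = FALSE),
                       label = rep(0:3, 25), subject = rep(1:10, each = 10))
  sp <- split_by_subject(ex, seed = 41)
  expect_length(unique(sp$train$subject), 7)
  expect_length(unique(sp$test$subject), 3)
  expect_length(intersect(unique(sp$train$subject), unique(sp$test$subject)), 0)
  expect_identical(split_by_subject(ex, seed = 41), sp)
  few <- ex[ex$subject <= 7, ]
  expect_error(split_by_subject(few, seed = 1), "at least 8")
})

test_that("training is deterministic given the seed and improves the generative fit", {
  ds <- make_synthetic_dataset(synthetic_spec(n_subjects = 2, repetitions = 3, seed = 9))
  cfg <- training_config(epochs = 3, seed = 9)
  fit1 <- train_model(ds$examples, cfg)
  fit2 <- train_model(ds$examples, cfg)
  expect_identical(fit1$history, fit2$history)
  # generative-only training decreases the NLL
  cfg0 <- training_config(epochs = 5, ce_weight = 0, seed = 9)
  fit0 <- train_model(ds$examples, cfg0)
  expect_lt(tail(fit0$history$nll, 1), fit0$history$nll[1])
  expect_identical(fit0$history$total, fit0$history$nll)
})

test_that("the cross-entropy term shapes the latent space toward class separation", {
  # joint training (ce_weight > 0) vs purely generative training (ce_weight
  # 0) at matched epochs: the classifier gradient flowing into the flow
  # should increase the between-class/within-class separation of held-out
  # retained latents on every seed
  sep_stat <- function(fit, data) {
    lat <- compute_latents(fit, data)
    z <- t(sapply(lat$latent, as.numeric))
    mu <- colMeans(z)
    between <- 0; within <- 0
    for (g in sort(unique(lat$label))) {
      zg <- z[lat$label == g, , drop = FALSE]
      mg <- colMeans(zg)
      between <- between + nrow(zg) * sum((mg - mu)^2)
      within <- within + sum(sweep(zg, 2, mg)^2)
    }
    between / within
  }
  seps <- sapply(1:3, function(s) {
    spec <- synthetic_spec(n_subjects = 5, repetitions = 3, noise_sd = 0.7,
                           subject_gain_jitter = 0.5, seed = 100 + s)
    ds <- make_synthetic_dataset(spec)
    parts <- split_by_subject(ds$examples, n_train_subjects = 3, seed = s)
    cfg <- training_config(epochs = 8, seed = s)
    joint <- train_model(parts$train, cfg)
    cfg0 <- cfg; cfg0$ce_weight <- 0
    gen <- train_model(parts$train, cfg0)
    # the jointly trained model still classifies the held-out subjects well
    expect_gte(evaluate_accuracy(joint, parts$test), 0.5)
    c(joint = sep_stat(joint, parts$test), generative = sep_stat(gen, parts$test))
  })
  expect_true(all(seps["joint", ] > seps["generative", ]))
})

test_that("accuracy is the argmax agreement rate, invariant to example order", {
  fx <- trained_fixture()
  acc <- evaluate_accuracy(fx$fit, fx$test)
  expect_gte(acc, 0)
  expect_lte(acc, 1)
  shuffled <- fx$test[rev(seq_len(nrow(fx$test))), ]
  expect_equal(evaluate_accuracy(fx$fit, shuffled), acc)
  # chance level for an untrained uniform classifier on the synthetic classes
  fl <- fx$fit$flow
  clf0 <- classifier_params(length(fx$fit$classes), input_dim = fx$fit$clf$input_dim)
  acc0 <- evaluate_accuracy(fl, clf0, fx$test)
  # uniform logits break ties to the first class; rest (label 0) prevalence
  # bounds the agreement
  expect_lte(acc0, mean(fx$test$label == 0) + 1e-9)
})
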