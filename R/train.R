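# Linear SoftMax classifier on the retained latent, and joint training of
# flow + classifier under the compound objective
#   mean_i[ -(log p_z(f(x_i)) + logdet_i) ] + ce_weight * mean_i CE(y_hat_i, y_i)
# Both terms are per-example means; with a summed reading of the negative
# log-likelihood the absolute loss differs by a factor of the batch size,
# but the minimizers coincide for fixed batch composition.

#' Linear SoftMax classifier parameters
#'
#' Logits are `weight %*% flatten(z) + bias` on the flattened (column-major)
#' retained latent; zero initialization gives the uniform classifier.
#'
#' @param n_classes number of gesture classes (53 for NinaPro DB5: rest +
#'   52 movements).
#' @param input_dim flattened retained-latent dimension (default 256 =
#'   32 * 8).
#' @return an object of class `classifier_params`.
#' @export
classifier_params <- function(n_classes = 53L, input_dim = 256L) {
  structure(list(weight = matrix(0, n_classes, input_dim),
                 bias = rep(0, n_classes),
                 n_classes = as.integer(n_classes),
                 input_dim = as.integer(input_dim)),
            class = "classifier_params")
}

softmax_rows <- function(logits) {
  m <- logits - apply(logits, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

# stacked retained latents ((n*t_final) x c_final) -> n x input_dim matrix of
# column-major flattened latents
flatten_retained <- function(m_ret, t_final) {
  n <- nrow(m_ret) / t_final
  z <- matrix(0, n, t_final * ncol(m_ret))
  for (i in seq_len(n)) {
    z[i, ] <- as.vector(m_ret[((i - 1L) * t_final + 1L):(i * t_final), ])
  }
  z
}

#' Classify a retained latent
#'
#' @param params a [classifier_params()].
#' @param z_retained retained latent matrix (e.g. 32 x 8) or a flattened
#'   vector of length `input_dim`.
#' @return named numeric vector of class probabilities (classes `0..K-1`),
#'   summing to 1.
#' @export
classify_latent <- function(params, z_retained) {
  z <- as.numeric(z_retained)
  if (length(z) != params$input_dim) {
    stop(sprintf("latent has %d elements; classifier expects %d",
                 length(z), params$input_dim), call. = FALSE)
  }
  logits <- as.numeric(params$weight %*% z + params$bias)
  p <- exp(logits - max(logits))
  p <- p / sum(p)
  names(p) <- as.character(seq_len(params$n_classes) - 1L)
  p
}

#' Compound generative-discriminative loss
#'
#' `nll` is the per-example mean negative log-likelihood of the flow, `ce`
#' the mean cross-entropy of the SoftMax predictions against the labels, and
#' `total = nll + ce_weight * ce`.
#'
#' @param flow a [flow_init()] object.
#' @param clf a [classifier_params()].
#' @param windows list of `t x c` window matrices.
#' @param labels integer labels in `0..n_classes-1`.
#' @param ce_weight nonnegative weight on the cross-entropy term (default 1).
#' @return an object of class `loss_breakdown`: list with `nll`, `ce`,
#'   `total`.
#' @export
compound_loss <- function(flow, clf, windows, labels, ce_weight = 1) {
  stopifnot(length(windows) >= 1L, length(labels) == length(windows))
  if (any(labels < 0L | labels >= clf$n_classes)) {
    stop("labels must lie in 0..", clf$n_classes - 1L, call. = FALSE)
  }
  n <- length(windows)
  out <- flow_transform_batch(flow, stack_windows(windows), n)
  fwd <- loss_from_transform(flow, clf, out, labels, ce_weight, n)
  structure(list(nll = fwd$nll, ce = fwd$ce, total = fwd$total),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss_breakdown> nll %.4f + ce %.4f -> total %.4f\n", x$nll, x$ce, x$total))
  invisible(x)
}

loss_from_transform <- function(flow, clf, out, labels, ce_weight, n) {
  tf <- out$t_final
  lp <- block_sums(rowSums(dnorm(out$retained, log = TRUE)), tf) +
    block_sums(rowSums(dnorm(out$splits[[1L]], log = TRUE)), flow$arch$t %/% 2L) +
    block_sums(rowSums(dnorm(out$splits[[2L]], log = TRUE)), tf)
  ll <- lp + out$logdet
  z <- flatten_retained(out$retained, tf)
  logits <- sweep(z %*% t(clf$weight), 2L, clf$bias, `+`)
  probs <- softmax_rows(logits)
  idx <- cbind(seq_len(n), labels + 1L)
  ce <- -mean(log(pmax(probs[idx], .Machine$double.xmin)))
  nll <- -mean(ll)
  list(nll = nll, ce = ce, total = nll + ce_weight * ce,
       z = z, probs = probs, logits = logits, loglik = ll)
}

# loss + full gradient of the compound objective wrt flow and classifier
compound_loss_grad <- function(flow, clf, windows, labels, ce_weight = 1) {
  n <- length(windows)
  out <- flow_transform_batch(flow, stack_windows(windows), n, keep_cache = TRUE)
  fwd <- loss_from_transform(flow, clf, out, labels, ce_weight, n)
  tf <- out$t_final

  # CE gradient at the logits: (p - onehot) * ce_weight / n
  g_logits <- fwd$probs
  idx <- cbind(seq_len(n), labels + 1L)
  g_logits[idx] <- g_logits[idx] - 1
  g_logits <- g_logits * (ce_weight / n)
  clf_grads <- list(weight = crossprod(g_logits, fwd$z), bias = colSums(g_logits))

  # gradient on the flattened retained latent from the classifier
  g_z <- g_logits %*% clf$weight  # n x input_dim
  g_ret_clf <- matrix(0, nrow(out$retained), ncol(out$retained))
  for (i in seq_len(n)) {
    g_ret_clf[((i - 1L) * tf + 1L):(i * tf), ] <-
      matrix(g_z[i, ], tf, ncol(out$retained))
  }

  # prior gradients: d(-logphi(v))/dv = v, scaled by 1/n for the mean
  g_ret <- out$retained / n + g_ret_clf
  g_s1 <- out$splits[[1L]] / n
  g_s2 <- out$splits[[2L]] / n

  bw <- flow_backward_batch(flow, out, n, g_ret, g_s1, g_s2, ld_coef = -1 / n)
  list(loss = structure(list(nll = fwd$nll, ce = fwd$ce, total = fwd$total),
                        class = "loss_breakdown"),
       flow_grads = bw, clf_grads = clf_grads, probs = fwd$probs)
}

## ---- dataset splits ---------------------------------------------------------

#' Random example-level train/test split
#'
#' @param examples dataset tibble (`window`, `label`, `subject`).
#' @param train_fraction fraction of examples in the train set (default
#'   0.7); the train size is `0.7 * N` rounded half away from zero.
#' @param seed integer seed for the shuffle.
#' @return list with tibbles `train` and `test` (disjoint, exhaustive).
#' @export
split_random <- function(examples, train_fraction = 0.7, seed = 1L) {
  stopifnot(is.data.frame(examples))
  n <- nrow(examples)
  if (n < 2L) stop("need at least 2 examples to split", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  n_train <- round_half_up(train_fraction * n)
  perm <- with_seed(seed, sample.int(n))
  list(train = examples[sort(perm[seq_len(n_train)]), , drop = FALSE],
       test = examples[sort(perm[(n_train + 1L):n]), , drop = FALSE])
}

#' Subject-wise train/test split
#'
#' All examples of `n_train_subjects` randomly chosen subjects go to the
#' train set; every other subject's examples form the test set, so no
#' subject appears in both.
#'
#' @param examples dataset tibble with a `subject` column.
#' @param n_train_subjects number of training subjects (default 7, the
#'   7-of-10 protocol).
#' @param seed integer seed.
#' @return list with tibbles `train` and `test`.
#' @export
split_by_subject <- function(examples, n_train_subjects = 7L, seed = 1L) {
  stopifnot(is.data.frame(examples))
  subjects <- sort(unique(examples$subject))
  if (length(subjects) < n_train_subjects + 1L) {
    stop(sprintf("need at least %d distinct subjects, got %d",
                 n_train_subjects + 1L, length(subjects)), call. = FALSE)
  }
  train_subj <- with_seed(seed, sample(subjects, n_train_subjects))
  list(train = examples[examples$subject %in% train_subj, , drop = FALSE],
       test = examples[!(examples$subject %in% train_subj), , drop = FALSE])
}

## ---- training ---------------------------------------------------------------

#' Training configuration
#'
#' @param epochs training epochs (default 15).
#' @param batch_size minibatch size (default 24).
#' @param learning_rate Adam step size (default 1e-3).
#' @param ce_weight weight of the cross-entropy term (default 1).
#' @param seed master seed for initialization and shuffling.
#' @param repeats number of repeated train/test runs in
#'   [repeat_experiment()] (default 5).
#' @param n_classes number of classes; inferred from the data if `NULL`.
#' @param hidden coupling conditioner width (default 64).
#' @param s_max coupling log-scale bound (default 2).
#' @return an object of class `training_config`.
#' @export
training_config <- function(epochs = 15L, batch_size = 24L, learning_rate = 1e-3,
                            ce_weight = 1, seed = 1L, repeats = 5L,
                            n_classes = NULL, hidden = 64L, s_max = 2) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0, ce_weight >= 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, ce_weight = ce_weight,
                 seed = as.integer(seed), repeats = as.integer(repeats),
                 n_classes = n_classes, hidden = as.integer(hidden), s_max = s_max),
            class = "training_config")
}

adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, vec, grad, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(vec = vec - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Jointly train the flow and the classifier
#'
#' Minimizes the compound objective with Adam, updating the flow parameters
#' theta and classifier parameters phi simultaneously. Actnorm layers are
#' initialized data-dependently from the first shuffled batch. Deterministic
#' given `config$seed` on a fixed platform.
#'
#' @param train dataset tibble (`window`, `label`, `subject`).
#' @param config a [training_config()].
#' @param init optional list with pre-trained `flow` (and optionally `clf`)
#'   to warm-start from.
#' @param train_flow if `FALSE`, freeze the flow and fit only the classifier
#'   head (useful for comparing joint vs two-stage training).
#' @return an object of class `gfm_fit`: `flow`, `clf`, `config`, `classes`,
#'   and a per-epoch `history` tibble (nll, ce, total, train accuracy).
#' @export
train_model <- function(train, config = training_config(), init = NULL,
                        train_flow = TRUE) {
  stopifnot(is.data.frame(train), nrow(train) >= 1L)
  labels <- as.integer(train$label)
  n_classes <- config$n_classes %||% (max(labels) + 1L)
  if (any(labels < 0L | labels >= n_classes)) {
    stop("labels must lie in 0..", n_classes - 1L, call. = FALSE)
  }
  dims <- dim(train$window[[1L]])

  flow <- if (!is.null(init$flow)) init$flow else
    flow_init(dims[1L], dims[2L], hidden = config$hidden, s_max = config$s_max,
              init = "default", seed = config$seed)
  clf <- if (!is.null(init$clf)) init$clf else
    classifier_params(n_classes, input_dim = (dims[1L] %/% 2L) * (dims[2L] %/% 2L))

  n <- nrow(train)
  n_batches <- ceiling(n / config$batch_size)
  history <- vector("list", config$epochs)

  # one bounded sub-seed per epoch (plus one for the init batch), derived
  # from the master seed
  stream <- with_seed(config$seed, sample.int(2147483646L, config$epochs + 1L))

  # data-dependent actnorm init on the first shuffled batch
  first_perm <- with_seed(stream[1L], sample.int(n))
  first_idx <- first_perm[seq_len(min(config$batch_size, n))]
  flow <- flow_init_actnorm(flow, stack_windows(train$window[first_idx]),
                            length(first_idx))

  vec <- params_to_vec(flow, clf)
  opt <- adam_state(length(vec))
  n_flow_par <- length(params_to_vec(flow))

  for (epoch in seq_len(config$epochs)) {
    perm <- with_seed(stream[epoch + 1L], sample.int(n))
    ep_nll <- ep_ce <- ep_total <- 0
    for (b in seq_len(n_batches)) {
      idx <- perm[((b - 1L) * config$batch_size + 1L):min(b * config$batch_size, n)]
      g <- compound_loss_grad(flow, clf, train$window[idx], labels[idx],
                              config$ce_weight)
      if (!is.finite(g$loss$total)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d, batch %d: nll=%g ce=%g",
                     epoch, b, g$loss$nll, g$loss$ce), call. = FALSE)
      }
      gv <- grads_to_vec(g$flow_grads, g$clf_grads)
      if (!train_flow) gv[seq_len(n_flow_par)] <- 0
      upd <- adam_step(opt, vec, gv, config$learning_rate)
      vec <- upd$vec; opt <- upd$state
      set_ <- vec_to_params(vec, flow, clf)
      flow <- set_$flow; clf <- set_$clf
      w <- length(idx) / n
      ep_nll <- ep_nll + g$loss$nll * w
      ep_ce <- ep_ce + g$loss$ce * w
      ep_total <- ep_total + g$loss$total * w
    }
    acc <- evaluate_accuracy(flow, clf, train)
    history[[epoch]] <- tibble::tibble(epoch = epoch, nll = ep_nll, ce = ep_ce,
                                       total = ep_total, train_acc = acc)
  }

  structure(list(flow = flow, clf = clf, config = config,
                 classes = seq_len(n_classes) - 1L,
                 history = dplyr::bind_rows(history)),
            class = "gfm_fit")
}

#' @export
print.gfm_fit <- function(x, ...) {
  h <- tail(x$history, 1L)
  cat(sprintf(paste0("<gfm_fit> %d classes, %d epochs (batch %d, ce_weight %g)\n",
                     "  final: nll %.3f, ce %.3f, train accuracy %.3f\n"),
              length(x$classes), x$config$epochs, x$config$batch_size,
              x$config$ce_weight, h$nll, h$ce, h$train_acc))
  invisible(x)
}

#' Classification accuracy on a dataset
#'
#' Fraction of examples whose argmax SoftMax prediction equals the label.
#'
#' @param flow a [flow_init()] object or a `gfm_fit` (then `clf` is taken
#'   from the fit and the second argument is the dataset).
#' @param clf a [classifier_params()].
#' @param test dataset tibble.
#' @return accuracy in `[0, 1]`.
#' @export
evaluate_accuracy <- function(flow, clf, test = NULL) {
  if (inherits(flow, "gfm_fit")) {
    test <- clf
    clf <- flow$clf
    flow <- flow$flow
  }
  stopifnot(is.data.frame(test), nrow(test) >= 1L)
  n <- nrow(test)
  out <- flow_transform_batch(flow, stack_windows(test$window), n)
  z <- flatten_retained(out$retained, out$t_final)
  logits <- sweep(z %*% t(clf$weight), 2L, clf$bias, `+`)
  pred <- max.col(logits, ties.method = "first") - 1L
  mean(pred == as.integer(test$label))
}

#' Repeat the train/test protocol
#'
#' Re-draws the split and re-trains `repeats` times (seeds
#' `seed + 0 .. seed + repeats - 1`), reporting per-repeat test accuracy.
#'
#' @param examples full dataset tibble.
#' @param config a [training_config()].
#' @param split `"random"` (70/30 example split) or `"subject"` (7/3
#'   subject split by default).
#' @param train_fraction,n_train_subjects split parameters.
#' @return tibble with one row per repeat: `repeat_id`, `seed`, `accuracy`.
#' @export
repeat_experiment <- function(examples, config = training_config(),
                              split = c("random", "subject"),
                              train_fraction = 0.7, n_train_subjects = 7L) {
  split <- match.arg(split)
  res <- vector("list", config$repeats)
  for (r in seq_len(config$repeats)) {
    seed_r <- config$seed + r - 1L
    parts <- if (split == "random") {
      split_random(examples, train_fraction, seed = seed_r)
    } else {
      split_by_subject(examples, n_train_subjects, seed = seed_r)
    }
    cfg <- config
    cfg$seed <- seed_r
    fit <- train_model(parts$train, cfg)
    res[[r]] <- tibble::tibble(repeat_id = r, seed = seed_r,
                               accuracy = evaluate_accuracy(fit, parts$test))
  }
  dplyr::bind_rows(res)
}
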