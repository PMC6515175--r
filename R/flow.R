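# The invertible transform f_theta: [T x C] envelope window -> factorized
# latent. The window is first squeezed along time (adjacent time pairs moved
# into the channel axis: 64 x 16 -> 32 x 32), then passed through three flow
# steps (actnorm -> invertible channel mixing -> affine coupling); steps 1
# and 2 end in a multi-scale split that routes the second half of the
# channels to the Gaussian prior (32 x 32 -> 32 x 16 -> 32 x 8), so a
# 64 x 16 window yields a retained 32 x 8 latent plus two Gaussianized
# split tensors -- 1024 elements conserved exactly. The squeeze is what
# lets the row-wise coupling layers model local time structure.

flow_arch <- function(t = 64L, c = 16L, hidden = 64L, s_max = 2) {
  t <- as.integer(t); c <- as.integer(c)
  if (t %% 2L != 0L) stop("time length must be even (time squeeze)", call. = FALSE)
  if (c %% 4L != 0L) stop("channel count must be divisible by 4 (two channel splits + coupling)",
                          call. = FALSE)
  list(t = t, c = c, n_steps = 3L, hidden = as.integer(hidden), s_max = s_max,
       scheme = "time-squeeze + channel splits")
}

# channel width seen by each step (after the initial time squeeze)
step_channels <- function(arch) c(2L * arch$c, arch$c, arch$c %/% 2L)
# rows seen by each step (time pairs)
flow_rows <- function(arch) arch$t %/% 2L

# stacked time squeeze: (n*t) x c -> (n*t/2) x 2c, row s of example i holding
# [x[2s-1, ], x[2s, ]]
squeeze_time <- function(m, n, t) {
  odd <- block_rows(n, t, seq(1L, t, by = 2L))
  cbind(m[odd, , drop = FALSE], m[odd + 1L, , drop = FALSE])
}

unsqueeze_time <- function(m, n, t) {
  c_ <- ncol(m) %/% 2L
  out <- matrix(0, n * t, c_)
  odd <- block_rows(n, t, seq(1L, t, by = 2L))
  out[odd, ] <- m[, seq_len(c_), drop = FALSE]
  out[odd + 1L, ] <- m[, c_ + seq_len(c_), drop = FALSE]
  out
}

#' Initialize flow parameters
#'
#' Builds the parameter set of the three-step invertible transform for a
#' `t x c` input window (defaults 64 x 16, giving a retained 32 x 8 latent).
#'
#' @param t,c window size: time points and channels (`t` even, `c` divisible
#'   by 4).
#' @param hidden hidden width of each coupling conditioner (default 64).
#' @param s_max coupling log-scale bound (default 2).
#' @param init `"default"` (identity coupling, rotation mixing, actnorm left
#'   for data-dependent init), `"identity"` (the exact identity transform up
#'   to the re-partition into latent parts), or `"random"` (all parameters
#'   randomized; useful for property tests).
#' @param seed optional seed for the randomized parts.
#' @return an object of class `flow_params`.
#' @export
flow_init <- function(t = 64L, c = 16L, hidden = 64L, s_max = 2,
                      init = c("default", "identity", "random"), seed = NULL) {
  init <- match.arg(init)
  arch <- flow_arch(t, c, hidden, s_max)
  build <- function() {
    chans <- step_channels(arch)
    steps <- lapply(seq_len(arch$n_steps), function(k) {
      ck <- chans[k]
      an <- switch(init,
        default  = actnorm_params(ck),
        identity = actnorm_params(ck, initialized = TRUE),
        random   = actnorm_params(ck, log_scale = rnorm(ck, sd = 0.2),
                                  bias = rnorm(ck, sd = 0.2), initialized = TRUE))
      mx <- if (init == "identity") inv_mix_params(ck, diag(ck)) else inv_mix_params(ck)
      cp <- coupling_params(ck, hidden = arch$hidden, s_max = arch$s_max)
      if (init == "random") {
        cp$w2 <- matrix(rnorm(length(cp$w2), sd = 0.3), nrow(cp$w2), ncol(cp$w2))
        cp$b2 <- rnorm(length(cp$b2), sd = 0.1)
      }
      list(actnorm = an, mix = mx, coupling = cp)
    })
    structure(list(arch = arch, steps = steps), class = "flow_params")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' @export
print.flow_params <- function(x, ...) {
  cat(sprintf("<flow_params> %d flow steps, input %d x %d -> retained %d x %d, conditioner width %d\n",
              x$arch$n_steps, x$arch$t, x$arch$c, x$arch$t %/% 2L, x$arch$c %/% 2L,
              x$arch$hidden))
  invisible(x)
}

# ---- batched core -----------------------------------------------------------

# m: example-major stacked (n * arch$t) x arch$c matrix
flow_transform_batch <- function(flow, m, n, keep_cache = FALSE) {
  arch <- flow$arch
  chans <- step_channels(arch)
  rows <- flow_rows(arch)
  logdet <- numeric(n)
  splits <- vector("list", 2L)
  cache <- if (keep_cache) vector("list", arch$n_steps) else NULL

  m <- squeeze_time(m, n, arch$t)
  for (k in seq_len(arch$n_steps)) {
    st <- flow$steps[[k]]
    if (!st$actnorm$initialized) {
      stop("actnorm of step ", k, " is not initialized; run actnorm init or use identity params",
           call. = FALSE)
    }
    x_an <- m
    r <- an_forward(st$actnorm, m, rows)
    m <- stopifnot_finite(r$y, paste0("step ", k, " actnorm"))
    logdet <- logdet + r$logdet
    x_mix <- m
    r <- mix_forward(st$mix, m, rows)
    m <- stopifnot_finite(r$y, paste0("step ", k, " channel mixing"))
    logdet <- logdet + r$logdet
    r <- cp_forward(st$coupling, m, rows)
    m <- stopifnot_finite(r$y, paste0("step ", k, " affine coupling"))
    logdet <- logdet + block_sums(r$logdet_rows, rows)
    if (keep_cache) cache[[k]] <- list(x_an = x_an, x_mix = x_mix, cp = r)
    if (k < arch$n_steps) {
      d <- chans[k] %/% 2L
      splits[[k]] <- m[, d + seq_len(d), drop = FALSE]
      m <- m[, seq_len(d), drop = FALSE]
    }
  }
  list(retained = m, splits = splits, logdet = logdet, t_final = rows, cache = cache)
}

flow_invert_batch <- function(flow, retained, splits, n) {
  arch <- flow$arch
  rows <- flow_rows(arch)
  m <- retained
  for (k in rev(seq_len(arch$n_steps))) {
    st <- flow$steps[[k]]
    if (k < arch$n_steps) m <- cbind(m, splits[[k]])
    m <- cp_inverse(st$coupling, m, rows)$y
    m <- mix_inverse(st$mix, m, rows)$y
    m <- an_inverse(st$actnorm, m, rows)$y
    stopifnot_finite(m, paste0("step ", k, " inverse"))
  }
  unsqueeze_time(m, n, arch$t)
}

# backward pass: g_ret / g_s1 / g_s2 are gradients of a scalar loss wrt the
# stacked retained latent and the two split tensors; ld_coef is
# dLoss/d(per-example logdet) (a scalar, same for every example).
flow_backward_batch <- function(flow, out, n, g_ret, g_s1, g_s2, ld_coef) {
  arch <- flow$arch
  rows <- flow_rows(arch)
  g_splits <- list(g_s1, g_s2)
  grads <- vector("list", arch$n_steps)
  g <- g_ret
  for (k in rev(seq_len(arch$n_steps))) {
    st <- flow$steps[[k]]
    cc <- out$cache[[k]]
    if (k < arch$n_steps) g <- cbind(g, g_splits[[k]])
    bc <- cp_backward(st$coupling, cc$cp, g, ld_coef)
    g <- bc$gx
    bm <- mix_backward(st$mix, cc$x_mix, g, ld_coef, n, rows)
    g <- bm$gx
    ba <- an_backward(st$actnorm, cc$x_an, g, ld_coef, n, rows)
    g <- ba$gx
    grads[[k]] <- list(actnorm = ba$g, mix = bm$g, coupling = bc$g)
  }
  list(steps = grads, gx = unsqueeze_time(g, n, arch$t))
}

# data-dependent actnorm init: walks the flow over an init batch,
# initializing each uninitialized actnorm from its own input statistics
flow_init_actnorm <- function(flow, m, n) {
  arch <- flow$arch
  chans <- step_channels(arch)
  rows <- flow_rows(arch)
  m <- squeeze_time(m, n, arch$t)
  for (k in seq_len(arch$n_steps)) {
    st <- flow$steps[[k]]
    if (!st$actnorm$initialized) {
      flow$steps[[k]]$actnorm <- actnorm_init_from_batch(st$actnorm, m)
    }
    m <- an_forward(flow$steps[[k]]$actnorm, m, rows)$y
    m <- mix_forward(st$mix, m, rows)$y
    m <- cp_forward(st$coupling, m, rows)$y
    if (k < arch$n_steps) m <- m[, seq_len(chans[k] %/% 2L), drop = FALSE]
  }
  flow
}

# ---- single-example API -----------------------------------------------------

latent_feature <- function(retained, splits, logdet) {
  structure(list(retained = retained, splits = splits, logdet = logdet),
            class = "latent_feature")
}

#' @export
print.latent_feature <- function(x, ...) {
  cat(sprintf("<latent_feature> retained %d x %d, %d Gaussianized splits, logdet %.4f\n",
              nrow(x$retained), ncol(x$retained), length(x$splits), x$logdet))
  invisible(x)
}

#' Forward flow transform
#'
#' Maps one envelope window through the invertible transform, returning the
#' retained latent, the Gaussianized split halves and the accumulated
#' log-determinant of the Jacobian. Element count is conserved exactly
#' (retained + splits == t * c elements).
#'
#' @param params a [flow_init()] object.
#' @param x numeric matrix `t x c` (default architecture: 64 x 16).
#' @return a `latent_feature`: `retained` (`t/2 x c/2`), `splits` (list of
#'   two matrices, `t/2 x c` and `t/2 x c/2`) and `logdet` (scalar).
#' @export
flow_forward <- function(params, x) {
  x <- as_window_matrix(x)
  if (nrow(x) != params$arch$t || ncol(x) != params$arch$c) {
    stop(sprintf("window must be %d x %d for this architecture",
                 params$arch$t, params$arch$c), call. = FALSE)
  }
  if (!all(is.finite(x))) stop("input window contains non-finite values", call. = FALSE)
  out <- flow_transform_batch(params, x, 1L)
  latent_feature(out$retained, out$splits, out$logdet)
}

#' Inverse (reverse) flow transform
#'
#' Exact algebraic inverse of [flow_forward()]: reconstructs the envelope
#' window from a retained latent and the split halves.
#'
#' @param params a [flow_init()] object.
#' @param z a `latent_feature`, or a list with `retained` and `splits`.
#' @return the reconstructed `t x c` window.
#' @export
flow_inverse <- function(params, z) {
  arch <- params$arch
  ret <- as_window_matrix(z$retained)
  if (nrow(ret) != arch$t %/% 2L || ncol(ret) != arch$c %/% 2L) {
    stop(sprintf("retained latent must be %d x %d", arch$t %/% 2L, arch$c %/% 2L),
         call. = FALSE)
  }
  splits <- z$splits
  if (length(splits) != 2L) stop("expected 2 split tensors", call. = FALSE)
  flow_invert_batch(params, ret, splits, 1L)
}

#' Exact log-likelihood of a window
#'
#' Change-of-variables likelihood: the standard-normal log-density of all
#' latent parts (retained and Gaussianized splits; `t*c` terms in total)
#' plus the accumulated log-determinant of the Jacobian.
#'
#' @param params a [flow_init()] object.
#' @param x numeric matrix `t x c`.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(params, x) {
  z <- flow_forward(params, x)
  sum(dnorm(z$retained, log = TRUE)) +
    sum(vapply(z$splits, function(s) sum(dnorm(s, log = TRUE)), numeric(1))) +
    z$logdet
}

# batched log-likelihood over a list of windows; returns a vector
log_likelihood_batch <- function(params, windows) {
  n <- length(windows)
  out <- flow_transform_batch(params, stack_windows(windows), n)
  tf <- out$t_final
  lp <- block_sums(rowSums(dnorm(out$retained, log = TRUE)), tf) +
    block_sums(rowSums(dnorm(out$splits[[1L]], log = TRUE)), tf) +
    block_sums(rowSums(dnorm(out$splits[[2L]], log = TRUE)), tf)
  lp + out$logdet
}

# ---- parameter flattening (optimizer + numeric gradient checks) -------------

flow_leaf_paths <- function(flow, clf = NULL) {
  paths <- list()
  for (k in seq_along(flow$steps)) {
    for (nm in c("log_scale", "bias")) paths[[length(paths) + 1L]] <- c("steps", k, "actnorm", nm)
    paths[[length(paths) + 1L]] <- c("steps", k, "mix", "weight")
    for (nm in c("w1", "b1", "w2", "b2")) paths[[length(paths) + 1L]] <- c("steps", k, "coupling", nm)
  }
  if (!is.null(clf)) {
    paths[[length(paths) + 1L]] <- c("clf", "weight")
    paths[[length(paths) + 1L]] <- c("clf", "bias")
  }
  paths
}

get_leaf <- function(obj, path) {
  for (p in path) obj <- obj[[if (grepl("^[0-9]+$", p)) as.integer(p) else p]]
  obj
}

set_leaf <- function(obj, path, value) {
  p <- if (grepl("^[0-9]+$", path[1L])) as.integer(path[1L]) else path[1L]
  if (length(path) == 1L) {
    obj[[p]] <- value
  } else {
    obj[[p]] <- set_leaf(obj[[p]], path[-1L], value)
  }
  obj
}

# flatten flow (+ optional classifier) parameters into one numeric vector
params_to_vec <- function(flow, clf = NULL) {
  holder <- list(steps = flow$steps, clf = clf)
  paths <- flow_leaf_paths(flow, clf)
  unlist(lapply(paths, function(pp) as.numeric(get_leaf(holder, pp))), use.names = FALSE)
}

vec_to_params <- function(vec, flow, clf = NULL) {
  holder <- list(steps = flow$steps, clf = clf)
  paths <- flow_leaf_paths(flow, clf)
  pos <- 0L
  for (pp in paths) {
    cur <- get_leaf(holder, pp)
    nl <- length(cur)
    repl <- vec[pos + seq_len(nl)]
    if (is.matrix(cur)) repl <- matrix(repl, nrow(cur), ncol(cur))
    holder <- set_leaf(holder, pp, repl)
    pos <- pos + nl
  }
  flow$steps <- holder$steps
  list(flow = flow, clf = holder$clf)
}

grads_to_vec <- function(flow_grads, clf_grads = NULL) {
  out <- list()
  for (k in seq_along(flow_grads$steps)) {
    g <- flow_grads$steps[[k]]
    out <- c(out, list(g$actnorm$log_scale, g$actnorm$bias, g$mix$weight,
                       g$coupling$w1, g$coupling$b1, g$coupling$w2, g$coupling$b2))
  }
  if (!is.null(clf_grads)) out <- c(out, list(clf_grads$weight, clf_grads$bias))
  unlist(lapply(out, as.numeric), use.names = FALSE)
}
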