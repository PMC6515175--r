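# Invertible flow layers. Every layer maps a [T x C] array (time x
# feature-channels) to an array of the same shape, returning the exact
# log-determinant of its Jacobian. Internally layers operate on
# example-major stacked matrices ((n*T) x C) so batches are a single
# matrix product; the exported single-example operations wrap these.

## ---- actnorm -------------------------------------------------------------

#' Actnorm parameters
#'
#' Per-channel affine layer, y = exp(log_scale) * x + bias, broadcast over
#' time. Normally initialized data-dependently so the first batch is
#' standardized per channel ([actnorm_init_from_batch()]).
#'
#' @param n_channels number of feature channels.
#' @param log_scale,bias numeric vectors of length `n_channels`.
#' @param initialized whether the parameters are ready for use (set by the
#'   data-dependent init, or `TRUE` for explicit identity parameters).
#' @return an object of class `actnorm_params`.
#' @export
actnorm_params <- function(n_channels, log_scale = rep(0, n_channels),
                           bias = rep(0, n_channels), initialized = FALSE) {
  stopifnot(length(log_scale) == n_channels, length(bias) == n_channels)
  if (!all(is.finite(log_scale)) || !all(is.finite(bias))) {
    stop("actnorm parameters must be finite", call. = FALSE)
  }
  structure(list(log_scale = as.numeric(log_scale), bias = as.numeric(bias),
                 initialized = isTRUE(initialized)),
            class = "actnorm_params")
}

an_forward <- function(p, m, t) {
  es <- exp(p$log_scale)
  y <- sweep(sweep(m, 2L, es, `*`), 2L, p$bias, `+`)
  list(y = y, logdet = t * sum(p$log_scale))
}

an_inverse <- function(p, m, t) {
  x <- sweep(sweep(m, 2L, p$bias, `-`), 2L, exp(-p$log_scale), `*`)
  list(y = x, logdet = -t * sum(p$log_scale))
}

# g: dL/dy on the stacked output; ld_coef: dL/d(per-example logdet);
# n: batch size. Returns dL/dx and parameter gradients.
an_backward <- function(p, x_in, g, ld_coef, n, t) {
  es <- exp(p$log_scale)
  gx <- sweep(g, 2L, es, `*`)
  gb <- colSums(g)
  gs <- colSums(g * sweep(x_in, 2L, es, `*`)) + ld_coef * n * t
  list(gx = gx, g = list(log_scale = gs, bias = gb))
}

#' Apply an actnorm layer
#'
#' Per-channel affine map `y = exp(log_scale) * x + bias` with exact
#' log-determinant `T * sum(log_scale)`.
#'
#' @param params an [actnorm_params()].
#' @param x numeric matrix `T x C`.
#' @param direction `"forward"` or `"inverse"`.
#' @return list with `y` (transformed matrix) and `logdet` (scalar, of the
#'   applied direction).
#' @export
actnorm_apply <- function(params, x, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  x <- as_window_matrix(x)
  if (ncol(x) != length(params$log_scale)) stop("channel-count mismatch", call. = FALSE)
  if (!all(is.finite(params$log_scale)) || !all(is.finite(params$bias))) {
    stop("actnorm parameters must be finite", call. = FALSE)
  }
  if (direction == "forward") an_forward(params, x, nrow(x)) else an_inverse(params, x, nrow(x))
}

#' Data-dependent actnorm initialization
#'
#' Sets `log_scale` and `bias` so the layer output has per-channel mean 0
#' and variance 1 (population moments) on the given batch.
#'
#' @param params an [actnorm_params()].
#' @param batch numeric array `n x T x C`, or a stacked `(n*T) x C` matrix.
#' @return an initialized `actnorm_params`.
#' @export
actnorm_init_from_batch <- function(params, batch) {
  m <- if (length(dim(batch)) == 3L) {
    matrix(aperm(batch, c(2L, 1L, 3L)), ncol = dim(batch)[3L])
  } else {
    as_window_matrix(batch)
  }
  if (nrow(m) < 2L) stop("need at least 2 rows to initialize actnorm", call. = FALSE)
  mu <- colMeans(m)
  va <- colMeans(sweep(m, 2L, mu)^2)  # population variance
  bad <- which(va <= 0)
  if (length(bad) > 0L) {
    stop("zero-variance channel(s) in actnorm init batch: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  log_scale <- -0.5 * log(va)
  actnorm_params(length(mu), log_scale = log_scale,
                 bias = -mu * exp(log_scale), initialized = TRUE)
}

## ---- invertible 1x1 channel mixing ---------------------------------------

#' Invertible channel-mixing parameters
#'
#' A learned nonsingular `C x C` matrix applied to the channel axis at every
#' time point (the "invertible 1x1 convolution" of Glow-style flows).
#' Initialized to a random rotation so `log|det| = 0`.
#'
#' @param n_channels number of feature channels.
#' @param weight optional explicit `C x C` matrix.
#' @return an object of class `inv_mix_params`.
#' @export
inv_mix_params <- function(n_channels, weight = NULL) {
  if (is.null(weight)) {
    a <- matrix(rnorm(n_channels^2), n_channels, n_channels)
    qr_ <- qr(a)
    weight <- qr.Q(qr_)
    # fix det to +1 so the init is a rotation
    if (det(weight) < 0) weight[, 1L] <- -weight[, 1L]
  }
  weight <- as.matrix(weight)
  stopifnot(nrow(weight) == n_channels, ncol(weight) == n_channels)
  structure(list(weight = weight), class = "inv_mix_params")
}

mix_logdet_unit <- function(w) {
  d <- determinant(w, logarithm = TRUE)
  ld <- as.numeric(d$modulus)
  if (!is.finite(ld)) stop("singular channel-mixing matrix", call. = FALSE)
  ld
}

mix_forward <- function(p, m, t) {
  list(y = m %*% p$weight, logdet = t * mix_logdet_unit(p$weight))
}

mix_inverse <- function(p, m, t) {
  list(y = m %*% solve(p$weight), logdet = -t * mix_logdet_unit(p$weight))
}

mix_backward <- function(p, x_in, g, ld_coef, n, t) {
  gx <- g %*% t(p$weight)
  gw <- crossprod(x_in, g) + ld_coef * n * t * t(solve(p$weight))
  list(gx = gx, g = list(weight = gw))
}

#' Apply an invertible channel-mixing layer
#'
#' Multiplies each time-row by the mixing matrix (forward) or its inverse;
#' `logdet = T * log|det(weight)|`.
#'
#' @param params an [inv_mix_params()].
#' @param x numeric matrix `T x C`.
#' @param direction `"forward"` or `"inverse"`.
#' @return list with `y` and `logdet`.
#' @export
inv_mix_apply <- function(params, x, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  x <- as_window_matrix(x)
  if (ncol(x) != ncol(params$weight)) stop("channel-count mismatch", call. = FALSE)
  if (direction == "forward") mix_forward(params, x, nrow(x)) else mix_inverse(params, x, nrow(x))
}

## ---- affine coupling ------------------------------------------------------

#' Affine coupling parameters
#'
#' Splits the channels in half; the first half passes through unchanged and
#' conditions an elementwise affine transform of the second half. The
#' conditioner is a two-layer tanh network applied per time-row whose final
#' layer is zero-initialized, so the coupling is exactly the identity at
#' initialization. The per-element log-scale is squashed to
#' `(-s_max, s_max)` via `s_max * tanh(.)`, guaranteeing invertibility.
#'
#' @param n_channels number of channels C (must be even).
#' @param hidden hidden width of the conditioner (default 64).
#' @param s_max log-scale bound (default 2).
#' @param w1_sd standard deviation of the first-layer weight init.
#' @return an object of class `coupling_params`.
#' @export
coupling_params <- function(n_channels, hidden = 64L, s_max = 2, w1_sd = 0.1) {
  if (n_channels %% 2L != 0L) stop("affine coupling requires an even channel count", call. = FALSE)
  d <- n_channels %/% 2L
  structure(list(
    w1 = matrix(rnorm(d * hidden, sd = w1_sd), d, hidden),
    b1 = rep(0, hidden),
    w2 = matrix(0, hidden, 2L * d),
    b2 = rep(0, 2L * d),
    s_max = s_max
  ), class = "coupling_params")
}

# conditioner: per-row tanh MLP from the untouched half to (log-scale, shift)
coupling_condition <- function(p, xa) {
  a <- sweep(xa %*% p$w1, 2L, p$b1, `+`)
  h <- tanh(a)
  o <- sweep(h %*% p$w2, 2L, p$b2, `+`)
  d <- ncol(xa)
  th <- tanh(o[, seq_len(d), drop = FALSE])
  list(h = h, sraw_tanh = th,
       s = p$s_max * th,
       t = o[, d + seq_len(d), drop = FALSE])
}

cp_forward <- function(p, m, t_rows) {
  c_ <- ncol(m); d <- c_ %/% 2L
  xa <- m[, seq_len(d), drop = FALSE]
  xb <- m[, d + seq_len(d), drop = FALSE]
  cond <- coupling_condition(p, xa)
  yb <- xb * exp(cond$s) + cond$t
  list(y = cbind(xa, yb), logdet_rows = rowSums(cond$s), cond = cond, xa = xa, xb = xb)
}

cp_inverse <- function(p, m, t_rows) {
  c_ <- ncol(m); d <- c_ %/% 2L
  ya <- m[, seq_len(d), drop = FALSE]
  yb <- m[, d + seq_len(d), drop = FALSE]
  cond <- coupling_condition(p, ya)
  xb <- (yb - cond$t) * exp(-cond$s)
  list(y = cbind(ya, xb), logdet_rows = -rowSums(cond$s))
}

cp_backward <- function(p, fwd, g, ld_coef) {
  d <- ncol(fwd$xa)
  ga <- g[, seq_len(d), drop = FALSE]
  gb <- g[, d + seq_len(d), drop = FALSE]
  es <- exp(fwd$cond$s)
  gxb <- gb * es
  gs <- gb * fwd$xb * es + ld_coef
  gt <- gb
  # s = s_max * tanh(sraw) => ds/dsraw = s_max * (1 - tanh^2)
  gsraw <- gs * p$s_max * (1 - fwd$cond$sraw_tanh^2)
  g_o <- cbind(gsraw, gt)
  gw2 <- crossprod(fwd$cond$h, g_o)
  gb2 <- colSums(g_o)
  gh <- g_o %*% t(p$w2)
  g_a <- gh * (1 - fwd$cond$h^2)
  gw1 <- crossprod(fwd$xa, g_a)
  gb1 <- colSums(g_a)
  gxa <- ga + g_a %*% t(p$w1)
  list(gx = cbind(gxa, gxb),
       g = list(w1 = gw1, b1 = gb1, w2 = gw2, b2 = gb2))
}

#' Apply an affine coupling layer
#'
#' @param params a [coupling_params()].
#' @param x numeric matrix `T x C`, C even.
#' @param direction `"forward"` or `"inverse"`.
#' @return list with `y` and `logdet` (sum of the per-element log-scales of
#'   the applied direction).
#' @export
coupling_apply <- function(params, x, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  x <- as_window_matrix(x)
  if (ncol(x) %% 2L != 0L) stop("affine coupling requires an even channel count", call. = FALSE)
  if (2L * nrow(params$w1) != ncol(x)) stop("channel-count mismatch", call. = FALSE)
  r <- if (direction == "forward") cp_forward(params, x, nrow(x)) else cp_inverse(params, x, nrow(x))
  list(y = r$y, logdet = sum(r$logdet_rows))
}

## ---- multi-scale split / merge --------------------------------------------

# stacked split along time: odd time indices retained, even Gaussianized,
# so both halves sample the whole window
split_time_idx <- function(t) {
  list(ret = seq(1L, t, by = 2L), gau = seq(2L, t, by = 2L))
}

#' Multi-scale split
#'
#' Routes half the variables straight to the Gaussian prior and passes the
#' other half onward, halving the dimension. The partition is
#' deterministic: along time, retained = odd time indices, Gaussianized =
#' even (interleaved, so both halves span the window); along channels, the
#' first half is retained and the second Gaussianized.
#'
#' @param x numeric matrix `T x C`.
#' @param axis `"time"` or `"channel"`; the split axis must have even length.
#' @return list with `retained`, `gaussianized` (each half the elements of
#'   `x`) and `logprob_contrib`, the standard-normal log-density of the
#'   Gaussianized half.
#' @export
multiscale_split <- function(x, axis = c("time", "channel")) {
  axis <- match.arg(axis)
  x <- as_window_matrix(x)
  if (axis == "time") {
    if (nrow(x) %% 2L != 0L) stop("time axis must have even length to split", call. = FALSE)
    idx <- split_time_idx(nrow(x))
    ret <- x[idx$ret, , drop = FALSE]
    gau <- x[idx$gau, , drop = FALSE]
  } else {
    if (ncol(x) %% 2L != 0L) stop("channel axis must have even length to split", call. = FALSE)
    d <- ncol(x) %/% 2L
    ret <- x[, seq_len(d), drop = FALSE]
    gau <- x[, d + seq_len(d), drop = FALSE]
  }
  list(retained = ret, gaussianized = gau,
       logprob_contrib = sum(dnorm(gau, log = TRUE)))
}

#' Multi-scale merge (exact inverse of [multiscale_split()])
#'
#' @param retained,gaussianized the two halves.
#' @param axis the axis they were split along.
#' @return the reconstructed matrix, bit-exact.
#' @export
multiscale_merge <- function(retained, gaussianized, axis = c("time", "channel")) {
  axis <- match.arg(axis)
  retained <- as_window_matrix(retained)
  gaussianized <- as_window_matrix(gaussianized)
  if (!all(dim(retained) == dim(gaussianized))) {
    stop("retained and gaussianized halves must have identical shapes", call. = FALSE)
  }
  if (axis == "time") {
    t_full <- 2L * nrow(retained)
    out <- matrix(0, t_full, ncol(retained))
    idx <- split_time_idx(t_full)
    out[idx$ret, ] <- retained
    out[idx$gau, ] <- gaussianized
    out
  } else {
    cbind(retained, gaussianized)
  }
}
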