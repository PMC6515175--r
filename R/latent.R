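# Interpretation machinery: per-gesture latent centers, cosine correlation
# matrix, reverse-flow envelope generation, and per-dimension latent sweeps.

#' Compute retained latents for a dataset
#'
#' @param fit a `gfm_fit` (or a `flow_params` object).
#' @param examples dataset tibble (`window`, `label`, `subject`).
#' @return the tibble with added list-column `latent` (retained `t/2 x c/2`
#'   matrices) and numeric `logdet`.
#' @export
compute_latents <- function(fit, examples) {
  flow <- if (inherits(fit, "gfm_fit")) fit$flow else fit
  stopifnot(is.data.frame(examples), nrow(examples) >= 1L)
  n <- nrow(examples)
  out <- flow_transform_batch(flow, stack_windows(examples$window), n)
  examples$latent <- unstack_windows(out$retained, out$t_final)
  examples$logdet <- out$logdet
  examples
}

#' Per-gesture latent centers
#'
#' Averages the retained latents of every example of each gesture; the
#' center is the gesture's typical feature, the basis for the correlation
#' matrix and reverse-flow generation.
#'
#' @param latents list of retained latent matrices, or a tibble with a
#'   `latent` list-column (from [compute_latents()]).
#' @param labels integer labels (ignored when `latents` is a tibble with a
#'   `label` column).
#' @return tibble of class `gesture_centers`: `gesture`, list-column
#'   `center`, and contributing count `n`.
#' @export
gesture_centers <- function(latents, labels = NULL) {
  if (is.data.frame(latents)) {
    labels <- latents$label
    latents <- latents$latent
  }
  if (length(latents) == 0L) stop("no latents supplied", call. = FALSE)
  stopifnot(length(labels) == length(latents))
  gestures <- sort(unique(as.integer(labels)))
  centers <- lapply(gestures, function(g) {
    zs <- latents[labels == g]
    Reduce(`+`, zs) / length(zs)
  })
  out <- tibble::tibble(gesture = gestures, center = centers,
                        n = as.integer(table(factor(labels, levels = gestures))))
  class(out) <- c("gesture_centers", class(out))
  out
}

#' Cosine correlation matrix of gesture centers
#'
#' Entry (i, j) is the cosine of the angle between the flattened centers of
#' gestures i and j; values near 1 flag gesture pairs the model finds hard
#' to distinguish.
#'
#' @param centers a [gesture_centers()] tibble.
#' @return a symmetric matrix of class `correlation_matrix` with gesture ids
#'   as dimnames. Zero-norm centers give `NA` rows/columns with a warning.
#' @export
correlation_matrix <- function(centers) {
  stopifnot(inherits(centers, "gesture_centers") || is.data.frame(centers))
  vecs <- lapply(centers$center, as.numeric)
  norms <- vapply(vecs, function(v) sqrt(sum(v^2)), numeric(1))
  k <- length(vecs)
  m <- matrix(NA_real_, k, k, dimnames = list(centers$gesture, centers$gesture))
  zero <- norms == 0
  if (any(zero)) {
    warning("zero-norm center(s) for gesture(s) ",
            paste(centers$gesture[zero], collapse = ", "),
            "; their cosines are undefined (NA)", call. = FALSE)
  }
  v_mat <- do.call(cbind, vecs)
  dots <- crossprod(v_mat)
  denom <- outer(norms, norms)
  ok <- !outer(zero, zero, `|`)
  m[ok] <- (dots / denom)[ok]
  m[cbind(which(!zero), which(!zero))] <- 1
  m <- pmin(pmax(m, -1), 1)
  class(m) <- c("correlation_matrix", class(m))
  m
}

#' Generate an envelope window from a latent by the reverse flow
#'
#' Runs the inverse transform from a retained latent; the Gaussianized split
#' parts default to their prior mean (zeros) unless supplied.
#'
#' @param flow a `flow_params` or `gfm_fit`.
#' @param retained retained latent matrix (`t/2 x c/2`).
#' @param splits optional list of two split matrices (defaults to zeros).
#' @return generated `t x c` envelope window.
#' @export
generate_envelope_from_latent <- function(flow, retained, splits = NULL) {
  if (inherits(flow, "gfm_fit")) flow <- flow$flow
  arch <- flow$arch
  retained <- as_window_matrix(retained)
  if (is.null(splits)) {
    splits <- list(matrix(0, arch$t %/% 2L, arch$c),
                   matrix(0, arch$t %/% 2L, arch$c %/% 2L))
  }
  flow_inverse(flow, list(retained = retained, splits = splits))
}

#' Per-dimension latent sweep grid
#'
#' For every latent position (a, b), builds the one-hot latent `z[a, b] = v`
#' (all other elements and all split parts zero) and generates the
#' corresponding envelope by the reverse flow — one cell per latent
#' dimension, 32 rows x 8 columns for the default architecture.
#'
#' @param flow a `flow_params` or `gfm_fit`.
#' @param v the swept dimension value. Bounded to `[-75, 75]` by default,
#'   the observed range of trained latent features; use `force = TRUE` to
#'   explore beyond it.
#' @param bound the allowed `|v|` bound (default 75).
#' @param force override the bound check.
#' @return tibble of class `sweep_grid` with columns `row`, `col`, `v` and
#'   list-column `window` (generated `t x c` envelopes).
#' @export
dimension_sweep_grid <- function(flow, v, bound = 75, force = FALSE) {
  if (inherits(flow, "gfm_fit")) flow <- flow$flow
  if (!force && abs(v) > bound) {
    stop(sprintf(paste0("|v| = %g exceeds the [-%g, %g] bound (the min/max of ",
                        "latent features seen in training); pass force = TRUE to override"),
                 abs(v), bound, bound), call. = FALSE)
  }
  arch <- flow$arch
  tr <- arch$t %/% 2L; cr <- arch$c %/% 2L
  grid <- tidyr::expand_grid(row = seq_len(tr), col = seq_len(cr))
  windows <- purrr::map2(grid$row, grid$col, function(a, b) {
    z <- matrix(0, tr, cr)
    z[a, b] <- v
    generate_envelope_from_latent(flow, z)
  })
  out <- tibble::tibble(row = grid$row, col = grid$col, v = v, window = windows)
  attr(out, "latent_dim") <- c(tr, cr)
  class(out) <- c("sweep_grid", class(out))
  out
}

#' Envelope strength
#'
#' Scalar summary of a generated envelope's overall amplitude: the mean
#' absolute value over all elements (default), or the root mean square.
#'
#' @param window a `t x c` envelope window.
#' @param method `"mean_abs"` (default) or `"rms"`.
#' @return nonnegative scalar.
#' @export
envelope_strength <- function(window, method = c("mean_abs", "rms")) {
  method <- match.arg(method)
  w <- as.numeric(window)
  switch(method, mean_abs = mean(abs(w)), rms = sqrt(mean(w^2)))
}

#' Write analysis outputs
#'
#' Writes the correlation matrix as a CSV with gesture ids, and gesture
#' centers as an RDS bundle keyed by gesture id.
#'
#' @param centers a [gesture_centers()] tibble.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_analysis <- function(centers, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- correlation_matrix(centers)
  cm_path <- file.path(dir, "correlation_matrix.csv")
  df <- as.data.frame(unclass(cm))
  write.csv(cbind(gesture = rownames(df), df), cm_path, row.names = FALSE)
  ct_path <- file.path(dir, "gesture_centers.rds")
  saveRDS(stats::setNames(centers$center, centers$gesture), ct_path)
  invisible(c(correlation = cm_path, centers = ct_path))
}
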