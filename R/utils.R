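# internal helpers shared across modules

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals never
#' perturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# round half away from zero (used for the 70/30 split size)
round_half_up <- function(x) floor(x + 0.5)

# row indices of a within-block selection, for example-major stacked matrices
# (row (i-1)*t + s holds time point s of example i)
block_rows <- function(n, t, sel) {
  rep((seq_len(n) - 1L) * t, each = length(sel)) + rep(sel, times = n)
}

# per-example sums of a per-row vector over example-major blocks of t rows
block_sums <- function(v, t) {
  if (t == 1L) return(as.numeric(v))
  colSums(matrix(v, nrow = t))
}

stopifnot_finite <- function(x, where) {
  if (!all(is.finite(x))) {
    stop("non-finite values produced at stage: ", where, call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_window_matrix <- function(window) {
  if (!is.matrix(window)) {
    stop("a window must be a numeric matrix", call. = FALSE)
  }
  storage.mode(window) <- "double"
  window
}

# stack a list of t x c windows into an example-major (n*t) x c matrix
stack_windows <- function(windows) {
  do.call(rbind, lapply(windows, as_window_matrix))
}

# split a stacked (n*t) x c matrix back into a list of n windows
unstack_windows <- function(m, t) {
  n <- nrow(m) / t
  lapply(seq_len(n), function(i) m[((i - 1L) * t + 1L):(i * t), , drop = FALSE])
}
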