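# Single-file JSON checkpoints. Parameter arrays are stored as decimal
# strings with 17 significant digits, which round-trip IEEE doubles exactly,
# alongside an architecture descriptor that is validated on load.

enc_array <- function(x) {
  list(dim = if (is.matrix(x)) dim(x) else length(x),
       data = sprintf("%.17g", as.numeric(x)))
}

dec_array <- function(e) {
  v <- as.numeric(e$data)
  d <- as.integer(unlist(e$dim))
  if (length(d) == 2L) matrix(v, d[1L], d[2L]) else v
}

enc_flow <- function(flow) {
  list(arch = flow$arch[c("t", "c", "n_steps", "hidden", "s_max")],
       scheme = flow$arch$scheme,
       steps = lapply(flow$steps, function(st) list(
         actnorm = list(log_scale = enc_array(st$actnorm$log_scale),
                        bias = enc_array(st$actnorm$bias),
                        initialized = st$actnorm$initialized),
         mix = list(weight = enc_array(st$mix$weight)),
         coupling = list(w1 = enc_array(st$coupling$w1), b1 = enc_array(st$coupling$b1),
                         w2 = enc_array(st$coupling$w2), b2 = enc_array(st$coupling$b2),
                         s_max = st$coupling$s_max)
       )))
}

#' Save a model checkpoint
#'
#' Writes flow and classifier parameters, the architecture descriptor and
#' the training configuration to a single JSON file. Doubles are stored at
#' 17 significant digits, so [load_checkpoint()] reproduces every parameter
#' bit-exactly.
#'
#' @param flow a `flow_params` object, or a `gfm_fit` (then `clf`/`config`
#'   are taken from the fit and `clf` is interpreted as `path`).
#' @param clf a [classifier_params()] or `NULL`.
#' @param config a [training_config()] or `NULL`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
save_checkpoint <- function(flow, clf = NULL, config = NULL, path) {
  if (inherits(flow, "gfm_fit")) {
    if (missing(path)) path <- clf
    fit <- flow
    flow <- fit$flow; clf <- fit$clf; config <- fit$config
  }
  payload <- list(
    format = "flowemg-checkpoint",
    package_version = as.character(packageVersion("flowemg")),
    flow = enc_flow(flow),
    clf = if (!is.null(clf)) list(weight = enc_array(clf$weight),
                                  bias = enc_array(clf$bias),
                                  n_classes = clf$n_classes,
                                  input_dim = clf$input_dim),
    config = if (!is.null(config)) unclass(config)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

validate_descriptor <- function(arch, flow) {
  expected <- flow_arch(arch$t, arch$c, arch$hidden, arch$s_max)
  problems <- character(0)
  chans <- step_channels(expected)
  for (k in seq_along(flow$steps)) {
    st <- flow$steps[[k]]
    ck <- chans[k]
    if (length(st$actnorm$log_scale) != ck) {
      problems <- c(problems, sprintf("step %d actnorm width %d != descriptor %d",
                                      k, length(st$actnorm$log_scale), ck))
    }
    if (!all(dim(st$mix$weight) == c(ck, ck))) {
      problems <- c(problems, sprintf("step %d mixing matrix %dx%d != descriptor %dx%d",
                                      k, nrow(st$mix$weight), ncol(st$mix$weight), ck, ck))
    }
    if (!all(dim(st$coupling$w1) == c(ck %/% 2L, expected$hidden))) {
      problems <- c(problems, sprintf("step %d conditioner input %dx%d != descriptor %dx%d",
                                      k, nrow(st$coupling$w1), ncol(st$coupling$w1),
                                      ck %/% 2L, expected$hidden))
    }
  }
  if (length(flow$steps) != expected$n_steps) {
    problems <- c(problems, sprintf("%d steps != descriptor %d",
                                    length(flow$steps), expected$n_steps))
  }
  if (length(problems) > 0L) {
    stop("checkpoint descriptor mismatch:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  expected
}

#' Load a model checkpoint
#'
#' Validates the architecture descriptor against the stored parameter
#' shapes and refuses to load on any mismatch.
#'
#' @param path path written by [save_checkpoint()].
#' @return list with `flow`, `clf` (or `NULL`), `config` (or `NULL`) and
#'   `package_version`.
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path)
  if (!identical(payload$format, "flowemg-checkpoint")) {
    stop("not a flowemg checkpoint: ", path, call. = FALSE)
  }
  fl <- payload$flow
  steps <- lapply(fl$steps, function(st) {
    cp <- structure(list(w1 = dec_array(st$coupling$w1), b1 = dec_array(st$coupling$b1),
                         w2 = dec_array(st$coupling$w2), b2 = dec_array(st$coupling$b2),
                         s_max = st$coupling$s_max), class = "coupling_params")
    list(actnorm = actnorm_params(length(st$actnorm$log_scale$data),
                                  dec_array(st$actnorm$log_scale),
                                  dec_array(st$actnorm$bias),
                                  initialized = isTRUE(st$actnorm$initialized)),
         mix = structure(list(weight = dec_array(st$mix$weight)), class = "inv_mix_params"),
         coupling = cp)
  })
  flow <- structure(list(arch = NULL, steps = steps), class = "flow_params")
  flow$arch <- validate_descriptor(fl$arch, flow)
  clf <- if (!is.null(payload$clf)) {
    structure(list(weight = dec_array(payload$clf$weight),
                   bias = dec_array(payload$clf$bias),
                   n_classes = as.integer(payload$clf$n_classes),
                   input_dim = as.integer(payload$clf$input_dim)),
              class = "classifier_params")
  }
  config <- if (!is.null(payload$config)) {
    cfg <- payload$config
    training_config(cfg$epochs, cfg$batch_size, cfg$learning_rate, cfg$ce_weight,
                    cfg$seed, cfg$repeats, cfg$n_classes, cfg$hidden, cfg$s_max)
  }
  list(flow = flow, clf = clf, config = config,
       package_version = payload$package_version)
}
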