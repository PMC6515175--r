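# Minimal MATLAB MAT v5 reader/writer for numeric matrices — enough to read
# NinaPro Database 5 recordings (fields: emg, stimulus, restimulus, subject,
# exercise) and to emit files of the same shape. Supports little-endian
# files, long and short element tags, the common numeric storage types, and
# zlib-compressed elements. Cell arrays, structs, sparse and character
# arrays are out of scope.

MAT_CLASS_DOUBLE <- 6L

mat_u32 <- function(buf, pos) {
  readBin(buf[pos:(pos + 3L)], "integer", n = 1L, size = 4L, endian = "little")
}

mat_pad8 <- function(n) as.integer(ceiling(n / 8) * 8)

# decode one subelement at pos; returns list(type, data_raw, next_pos)
mat_subelement <- function(buf, pos) {
  v <- mat_u32(buf, pos)
  small_size <- bitwAnd(bitwShiftR(v, 16L), 0xFFFFL)
  if (small_size != 0L) {
    type <- bitwAnd(v, 0xFFFFL)
    nb <- small_size
    data <- if (nb > 0L) buf[(pos + 4L):(pos + 3L + nb)] else raw(0)
    list(type = type, data = data, next_pos = pos + 8L)
  } else {
    type <- v
    nb <- mat_u32(buf, pos + 4L)
    data <- if (nb > 0L) buf[(pos + 8L):(pos + 7L + nb)] else raw(0)
    list(type = type, data = data, next_pos = pos + 8L + mat_pad8(nb))
  }
}

mat_decode_numeric <- function(type, data) {
  switch(as.character(type),
    "1" = as.numeric(readBin(data, "integer", n = length(data), size = 1L, endian = "little")),
    "2" = as.numeric(readBin(data, "integer", n = length(data), size = 1L,
                             signed = FALSE, endian = "little")),
    "3" = as.numeric(readBin(data, "integer", n = length(data) / 2L, size = 2L, endian = "little")),
    "4" = as.numeric(readBin(data, "integer", n = length(data) / 2L, size = 2L,
                             signed = FALSE, endian = "little")),
    "5" = as.numeric(readBin(data, "integer", n = length(data) / 4L, size = 4L, endian = "little")),
    "6" = as.numeric(readBin(data, "integer", n = length(data) / 4L, size = 4L, endian = "little")),
    "7" = readBin(data, "double", n = length(data) / 4L, size = 4L, endian = "little"),
    "9" = readBin(data, "double", n = length(data) / 8L, size = 8L, endian = "little"),
    "12" = ,
    "13" = mat_decode_int64(data),
    stop("unsupported MAT numeric storage type: ", type, call. = FALSE)
  )
}

# 64-bit integers as doubles (exact up to 2^53, ample for label vectors)
mat_decode_int64 <- function(data) {
  n <- length(data) / 8L
  words <- readBin(data, "integer", n = 2L * n, size = 4L, endian = "little")
  lo <- words[seq(1L, 2L * n, by = 2L)]
  hi <- words[seq(2L, 2L * n, by = 2L)]
  lo_u <- ifelse(lo < 0, lo + 2^32, lo)
  hi * 2^32 + lo_u
}

# parse a miMATRIX element body into list(name, value) or NULL if unsupported
mat_parse_matrix <- function(body) {
  pos <- 1L
  flags <- mat_subelement(body, pos); pos <- flags$next_pos
  flagword <- mat_u32(flags$data, 1L)
  klass <- bitwAnd(flagword, 0xFFL)
  if (!(klass %in% 5:15)) return(NULL)  # only numeric array classes
  dims_el <- mat_subelement(body, pos); pos <- dims_el$next_pos
  dims <- readBin(dims_el$data, "integer", n = length(dims_el$data) / 4L,
                  size = 4L, endian = "little")
  name_el <- mat_subelement(body, pos); pos <- name_el$next_pos
  name <- rawToChar(name_el$data)
  data_el <- mat_subelement(body, pos)
  values <- mat_decode_numeric(data_el$type, data_el$data)
  if (length(dims) == 2L) values <- matrix(values, dims[1L], dims[2L])
  list(name = name, value = values)
}

#' Read a MAT v5 file of numeric matrices
#'
#' @param path path to a little-endian MATLAB v5 `.mat` file.
#' @return named list of numeric matrices/vectors.
#' @export
read_mat5 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  buf <- readBin(path, "raw", n = file.info(path)$size)
  if (length(buf) < 128L) stop("not a MAT v5 file (too short): ", path, call. = FALSE)
  endian <- rawToChar(buf[127:128])
  if (endian != "IM") {
    stop("unsupported MAT file (expected little-endian v5, endian tag 'IM', got '",
         endian, "')", call. = FALSE)
  }
  out <- list()
  pos <- 129L
  while (pos + 7L <= length(buf)) {
    type <- mat_u32(buf, pos)
    nb <- mat_u32(buf, pos + 4L)
    body <- if (nb > 0L) buf[(pos + 8L):(pos + 7L + nb)] else raw(0)
    if (type == 15L) {  # zlib-compressed element
      inner <- memDecompress(body, type = "gzip")
      itype <- mat_u32(inner, 1L)
      ibody <- inner[9:length(inner)]
      if (itype == 14L) {
        el <- mat_parse_matrix(ibody)
        if (!is.null(el)) out[[el$name]] <- el$value
      }
    } else if (type == 14L) {
      el <- mat_parse_matrix(body)
      if (!is.null(el)) out[[el$name]] <- el$value
    }
    # compressed elements are stored unpadded; everything else is 8-aligned
    pos <- pos + 8L + if (type == 15L) nb else mat_pad8(nb)
  }
  out
}

mat_encode_element <- function(name, value) {
  m <- if (is.matrix(value)) value else matrix(as.numeric(value), ncol = 1L)
  storage.mode(m) <- "double"
  name_raw <- charToRaw(name)
  name_pad <- raw(mat_pad8(length(name_raw)) - length(name_raw))
  body <- c(
    writeBin(c(6L, 8L), raw(), size = 4L, endian = "little"),              # flags tag
    writeBin(c(MAT_CLASS_DOUBLE, 0L), raw(), size = 4L, endian = "little"),
    writeBin(c(5L, 8L), raw(), size = 4L, endian = "little"),              # dims tag
    writeBin(dim(m), raw(), size = 4L, endian = "little"),
    writeBin(c(1L, length(name_raw)), raw(), size = 4L, endian = "little"),# name tag
    name_raw, name_pad,
    writeBin(c(9L, 8L * length(m)), raw(), size = 4L, endian = "little"),  # data tag
    writeBin(as.numeric(m), raw(), size = 8L, endian = "little")
  )
  c(writeBin(c(14L, length(body)), raw(), size = 4L, endian = "little"), body)
}

#' Write numeric matrices to a MAT v5 file
#'
#' @param vars named list of numeric matrices/vectors (stored as doubles).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_mat5 <- function(vars, path) {
  stopifnot(is.list(vars), !is.null(names(vars)), all(nzchar(names(vars))))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by flowemg %s",
                  as.character(packageVersion("flowemg")))
  desc_raw <- charToRaw(desc)[seq_len(min(116L, nchar(desc)))]
  header <- c(desc_raw, rep(charToRaw(" "), 116L - length(desc_raw)),
              raw(8L),
              writeBin(256L, raw(), size = 2L, endian = "little"),
              charToRaw("IM"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  for (nm in names(vars)) writeBin(mat_encode_element(nm, vars[[nm]]), con)
  invisible(path)
}

# NinaPro DB5 exercise sizes: A = 12, B = 17, C = 23 movements; global
# gesture numbering is rest = 0, then exercises A, B, C in order, so
# exercise-local movement m maps to offset[exercise] + m
NINAPRO_DB5_OFFSETS <- c(0L, 12L, 29L)

#' Read a NinaPro Database 5 recording
#'
#' Reads a DB5-layout MAT file (fields `emg`, `stimulus`/`restimulus`,
#' `subject`, `exercise`) into a [raw_recording()]. The refined
#' `restimulus` labels are preferred when present; exercise-local movement
#' ids are remapped to the global 0..52 scheme (rest = 0, exercises A, B, C
#' concatenated: offsets 0, 12, 29).
#'
#' @param path path to the `.mat` file.
#' @param label_field `"restimulus"` (default, falling back to `stimulus`
#'   when absent) or `"stimulus"`.
#' @param expected_channels required channel count (default 16).
#' @param fs sampling rate in Hz (default 200).
#' @return a [raw_recording()] with globally remapped labels.
#' @export
read_ninapro_mat <- function(path, label_field = c("restimulus", "stimulus"),
                             expected_channels = 16L, fs = 200) {
  label_field <- match.arg(label_field)
  vars <- read_mat5(path)
  if (is.null(vars$emg)) stop("missing required field 'emg' in ", path, call. = FALSE)
  labels <- vars[[label_field]]
  if (is.null(labels) && label_field == "restimulus") labels <- vars$stimulus
  if (is.null(labels)) {
    stop("missing label field ('restimulus'/'stimulus') in ", path, call. = FALSE)
  }
  emg <- vars$emg
  if (ncol(emg) != expected_channels) {
    stop(sprintf("expected %d EMG channels, file has %d", expected_channels, ncol(emg)),
         call. = FALSE)
  }
  labels <- as.integer(round(as.numeric(labels)))
  if (length(labels) != nrow(emg)) {
    stop(sprintf("label length (%d) does not match sample count (%d)",
                 length(labels), nrow(emg)), call. = FALSE)
  }
  exercise <- as.integer(round(as.numeric(vars$exercise %||% 1)))[1L]
  if (!(exercise %in% 1:3)) stop("exercise id must be 1, 2 or 3", call. = FALSE)
  offset <- NINAPRO_DB5_OFFSETS[exercise]
  labels <- ifelse(labels == 0L, 0L, labels + offset)
  subject <- as.integer(round(as.numeric(vars$subject %||% 1)))[1L]
  raw_recording(emg, fs, labels, subject = subject)
}

#' Write a recording in the NinaPro DB5 file layout
#'
#' Emits the fields `emg`, `stimulus`, `restimulus`, `subject` and
#' `exercise` so DB5 readers (including [read_ninapro_mat()]) can be tested
#' without the real database. Labels are written as exercise-local ids.
#'
#' @param recording a [raw_recording()] (labels interpreted as
#'   exercise-local).
#' @param path output path.
#' @param exercise exercise id 1..3 (default 1).
#' @return invisibly, `path`.
#' @export
write_ninapro_mat <- function(recording, path, exercise = 1L) {
  stopifnot(inherits(recording, "raw_recording"))
  write_mat5(list(
    emg = recording$samples,
    stimulus = matrix(as.numeric(recording$labels), ncol = 1L),
    restimulus = matrix(as.numeric(recording$labels), ncol = 1L),
    subject = matrix(as.numeric(recording$subject), 1L, 1L),
    exercise = matrix(as.numeric(exercise), 1L, 1L)
  ), path)
}
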