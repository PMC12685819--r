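# Minimal MAT v5 (Level 5 MAT-file) subset: little-endian, uncompressed,
# double-precision numeric arrays, cell arrays and (1x1) structs -- the
# shapes a DREAMER-style nested trial container needs. Compressed elements
# (miCOMPRESSED) and big-endian files are rejected with a clear error.

.mi <- list(INT8 = 1L, UINT8 = 2L, INT16 = 3L, UINT16 = 4L, INT32 = 5L,
            UINT32 = 6L, SINGLE = 7L, DOUBLE = 9L, INT64 = 12L, UINT64 = 13L,
            MATRIX = 14L, COMPRESSED = 15L, UTF8 = 16L)
.mx <- list(CELL = 1L, STRUCT = 2L, OBJECT = 3L, CHAR = 4L, DOUBLE = 6L)

.pad8 <- function(r) {
  rem <- length(r) %% 8
  if (rem) c(r, raw(8 - rem)) else r
}

.mat_tag <- function(type, nbytes) {
  writeBin(as.integer(c(type, nbytes)), raw(), size = 4, endian = "little")
}

.mat_element <- function(type, data_raw) {
  c(.mat_tag(type, length(data_raw)), .pad8(data_raw))
}

.mat_int32 <- function(v) .mat_element(.mi$INT32, writeBin(as.integer(v), raw(), size = 4, endian = "little"))
.mat_uint32 <- function(v) .mat_element(.mi$UINT32, writeBin(as.integer(v), raw(), size = 4, endian = "little"))
.mat_name <- function(name) .mat_element(.mi$INT8, if (nchar(name)) charToRaw(name) else raw(0))

# numeric array element (double storage)
.mat_numeric <- function(x, name = "") {
  dims <- if (is.matrix(x)) dim(x) else c(1L, length(x))
  body <- c(
    .mat_element(.mi$UINT32, writeBin(as.integer(c(.mx$DOUBLE, 0L)), raw(), size = 4, endian = "little")),
    .mat_int32(dims),
    .mat_name(name),
    .mat_element(.mi$DOUBLE, writeBin(as.double(x), raw(), size = 8, endian = "little")))
  .mat_element(.mi$MATRIX, body)
}

# cell array element; cells: list of raw miMATRIX elements
.mat_cell <- function(cells, dims, name = "") {
  body <- c(
    .mat_element(.mi$UINT32, writeBin(as.integer(c(.mx$CELL, 0L)), raw(), size = 4, endian = "little")),
    .mat_int32(dims),
    .mat_name(name),
    unlist(cells))
  .mat_element(.mi$MATRIX, body)
}

# 1x1 struct element; fields: named list of raw miMATRIX elements
.mat_struct <- function(fields, name = "") {
  fn_len <- 32L
  fnames_raw <- unlist(lapply(names(fields), function(f) {
    r <- charToRaw(f)
    if (length(r) >= fn_len) stopf("field name too long: %s", f)
    c(r, raw(fn_len - length(r)))
  }))
  body <- c(
    .mat_element(.mi$UINT32, writeBin(as.integer(c(.mx$STRUCT, 0L)), raw(), size = 4, endian = "little")),
    .mat_int32(c(1L, 1L)),
    .mat_name(name),
    .mat_int32(fn_len),
    .mat_element(.mi$INT8, fnames_raw),
    unlist(unname(fields)))
  .mat_element(.mi$MATRIX, body)
}

.mat_write_file <- function(elements, path) {
  desc <- "MATLAB 5.0 MAT-file, written by affectkit"
  hdr <- charToRaw(desc)
  hdr <- c(hdr, rep(charToRaw(" "), 116 - length(hdr)))
  hdr <- c(hdr, raw(8))                                   # subsystem offset
  hdr <- c(hdr, writeBin(c(0x00L, 0x01L), raw(), size = 1))  # version 0x0100 LE
  hdr <- c(hdr, charToRaw("IM"))                          # little-endian marker
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(unlist(elements), con)
  invisible(path)
}

# ---- reading ----

.mat_read_int <- function(raw, size, signed = TRUE) {
  readBin(raw, "integer", n = length(raw) %/% size, size = size,
          endian = "little", signed = signed)
}

# parse one tagged element starting at pos (1-based); returns
# list(type, data (raw), next_pos)
.mat_parse_tag <- function(buf, pos) {
  word1 <- .mat_read_int(buf[pos:(pos + 3)], 4)
  small_size <- bitwAnd(bitwShiftR(word1, 16), 0xFFFFL)
  if (small_size > 0) {                       # small data element format
    type <- bitwAnd(word1, 0xFFFFL)
    data <- buf[(pos + 4):(pos + 3 + small_size)]
    list(type = type, data = data, next_pos = pos + 8)
  } else {
    type <- word1
    nbytes <- .mat_read_int(buf[(pos + 4):(pos + 7)], 4)
    data <- if (nbytes > 0) buf[(pos + 8):(pos + 7 + nbytes)] else raw(0)
    adv <- 8 + nbytes + ((8 - nbytes %% 8) %% 8)
    list(type = type, data = data, next_pos = pos + adv)
  }
}

.mat_numeric_from <- function(type, data) {
  switch(as.character(type),
         "1" = as.double(.mat_read_int(data, 1)),
         "2" = as.double(.mat_read_int(data, 1, signed = FALSE)),
         "3" = as.double(.mat_read_int(data, 2)),
         "4" = as.double(.mat_read_int(data, 2, signed = FALSE)),
         "5" = as.double(.mat_read_int(data, 4)),
         "6" = as.double(.mat_read_int(data, 4)),
         "7" = readBin(data, "double", n = length(data) %/% 4, size = 4, endian = "little"),
         "9" = readBin(data, "double", n = length(data) %/% 8, size = 8, endian = "little"),
         stopf("unsupported MAT numeric storage type %s", type))
}

# parse a miMATRIX body; returns list(name, value)
.mat_parse_matrix <- function(body) {
  pos <- 1
  flags <- .mat_parse_tag(body, pos); pos <- flags$next_pos
  class_id <- bitwAnd(.mat_read_int(flags$data[1:4], 4), 0xFFL)
  dims_el <- .mat_parse_tag(body, pos); pos <- dims_el$next_pos
  dims <- .mat_read_int(dims_el$data, 4)
  name_el <- .mat_parse_tag(body, pos); pos <- name_el$next_pos
  name <- if (length(name_el$data)) rawToChar(name_el$data) else ""
  if (class_id >= 6L && class_id <= 15L) {   # double/single/integer classes
    pr <- .mat_parse_tag(body, pos)
    v <- .mat_numeric_from(pr$type, pr$data)
    value <- if (length(dims) == 2 && dims[1] > 1 && dims[2] > 1)
      matrix(v, dims[1], dims[2]) else as.numeric(v)
  } else if (class_id == .mx$CELL) {
    n <- prod(dims)
    value <- vector("list", n)
    for (i in seq_len(n)) {
      el <- .mat_parse_tag(body, pos); pos <- el$next_pos
      if (el$type != .mi$MATRIX) stopf("malformed cell array")
      value[[i]] <- .mat_parse_matrix(el$data)$value
    }
  } else if (class_id == .mx$STRUCT) {
    fl <- .mat_parse_tag(body, pos); pos <- fl$next_pos
    fn_len <- .mat_read_int(fl$data, 4)[1]
    fn <- .mat_parse_tag(body, pos); pos <- fn$next_pos
    nfields <- length(fn$data) %/% fn_len
    fnames <- vapply(seq_len(nfields), function(i) {
      r <- fn$data[((i - 1) * fn_len + 1):(i * fn_len)]
      rawToChar(r[r != as.raw(0)])
    }, "")
    n_el <- prod(dims)
    value <- vector("list", nfields)
    names(value) <- fnames
    for (e in seq_len(n_el)) {
      for (f in seq_len(nfields)) {
        el <- .mat_parse_tag(body, pos); pos <- el$next_pos
        value[[f]] <- .mat_parse_matrix(el$data)$value
      }
    }
  } else if (class_id == .mx$CHAR) {
    ch <- .mat_parse_tag(body, pos)
    value <- rawToChar(ch$data[ch$data != as.raw(0)])
  } else stopf("unsupported MAT array class %d", class_id)
  list(name = name, value = value)
}

#' Read the variables of a MAT v5 file
#'
#' Minimal reader for the subset this package writes: uncompressed,
#' little-endian files holding double arrays, cell arrays and structs.
#'
#' @param path MAT file path.
#' @return named list of variables.
#' @export
read_mat <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  buf <- readBin(path, "raw", file.info(path)$size)
  if (length(buf) < 128) stopf("not a MAT v5 file (truncated header): %s", path)
  endian <- rawToChar(buf[127:128])
  if (endian != "IM") stopf("unsupported MAT file (big-endian or not v5): %s", path)
  pos <- 129
  out <- list()
  while (pos + 7 <= length(buf)) {
    el <- .mat_parse_tag(buf, pos); pos <- el$next_pos
    if (el$type == .mi$COMPRESSED)
      stopf("compressed MAT elements are not supported; write uncompressed v5")
    if (el$type != .mi$MATRIX) stopf("unexpected top-level MAT element type %d", el$type)
    parsed <- .mat_parse_matrix(el$data)
    out[[parsed$name]] <- parsed$value
  }
  out
}

#' Write a trial set as a DREAMER-style MAT v5 container
#'
#' Layout: variable `DREAMER`, a struct with field `Data`, a 1 x n_subjects
#' cell; each subject a struct with fields `ECG` (struct with field
#' `stimuli`, an n_trials x 1 cell of samples x 2 double matrices -- two
#' leads, the second an attenuated copy) and `ScoreValence`, `ScoreArousal`,
#' `ScoreDominance` (n_trials x 1 vectors on the 1-5 scale).
#'
#' @param ts a [trial_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dreamer_mat <- function(ts, path) {
  subjects <- split(ts$trials, vapply(ts$trials, function(t) t$subject_id, ""))
  subjects <- subjects[order(names(subjects))]
  subj_cells <- lapply(subjects, function(trs) {
    trs <- trs[order(vapply(trs, function(t) t$trial_id, 0L))]
    stim <- lapply(trs, function(t) .mat_numeric(cbind(t$ecg, 0.8 * t$ecg)))
    vad <- vapply(trs, function(t) t$vad_raw, numeric(3))
    .mat_struct(list(
      ECG = .mat_struct(list(stimuli = .mat_cell(stim, c(length(trs), 1L)))),
      ScoreValence = .mat_numeric(matrix(vad[1, ], ncol = 1)),
      ScoreArousal = .mat_numeric(matrix(vad[2, ], ncol = 1)),
      ScoreDominance = .mat_numeric(matrix(vad[3, ], ncol = 1))))
  })
  top <- .mat_struct(list(Data = .mat_cell(subj_cells, c(1L, length(subj_cells)))),
                     name = "DREAMER")
  .mat_write_file(list(top), path)
}

#' Read a DREAMER-style MAT container into a trial set
#'
#' Navigates `DREAMER$Data -> subject -> ECG$stimuli` and the three SAM score
#' vectors, unwrapping the nested containers into flat numeric sequences.
#' Two-lead ECG matrices are reduced to one channel: the first lead by
#' default, or the mean of both leads.
#'
#' @param path MAT file path.
#' @param lead `"first"` (default) or `"average"`.
#' @return a [trial_set].
#' @export
read_dreamer_mat <- function(path, lead = c("first", "average")) {
  lead <- match.arg(lead)
  vars <- read_mat(path)
  root <- if ("DREAMER" %in% names(vars)) vars$DREAMER else vars[[1]]
  if (is.null(root) || !is.list(root) || is.null(root$Data))
    stopf("missing field: DREAMER$Data")
  trials <- list()
  for (s in seq_along(root$Data)) {
    subj <- root$Data[[s]]
    if (is.null(subj$ECG) || is.null(subj$ECG$stimuli))
      stopf("missing field: DREAMER$Data[[%d]]$ECG$stimuli", s)
    stim <- subj$ECG$stimuli
    for (t in seq_along(stim)) {
      x <- stim[[t]]
      if (!is.numeric(x)) stopf("non-numeric ECG leaf at subject %d trial %d", s, t)
      ecg <- if (is.matrix(x)) {
        if (lead == "first") x[, 1] else rowMeans(x)
      } else as.numeric(x)
      vad <- c(subj$ScoreValence[t], subj$ScoreArousal[t], subj$ScoreDominance[t])
      if (anyNA(vad) || any(vad < 1) || any(vad > 5))
        stopf("SAM score outside [1,5] at subject %d trial %d", s, t)
      trials[[length(trials) + 1L]] <- list(
        subject_id = sprintf("S%02d", s), trial_id = t,
        ecg = ecg, vad_raw = vad)
    }
  }
  trial_set(trials)
}
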