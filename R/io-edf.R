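# Minimal EDF (European Data Format) writer and reader, sufficient for
# multichannel physiological traces: ASCII fixed-width header, 16-bit
# little-endian samples scaled between per-channel physical and digital
# ranges. The whole signal is stored as a single data record (record
# duration = n / rate), so per-channel rates may differ. Annotations, EDF+
# TAL blocks and BDF are out of scope.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

.edf_num <- function(x, width) {
  s <- formatC(x, width = 1, format = "g", digits = 8)
  if (nchar(s) > width) s <- substr(s, 1, width)
  .edf_pad(s, width)
}

#' Write channels to an EDF file
#'
#' Lower-level writer taking a list of channels, each with its own rate, so
#' mixed-rate files can be produced. Each channel's physical range is its
#' data range (widened by 1 unit if constant); digital range is -32768..32767,
#' giving 16-bit quantization.
#'
#' @param channels list of lists with fields `label`, `rate_hz`, `data`
#'   (numeric vector). All channels must span the same duration in seconds.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf_channels <- function(channels, path) {
  ns <- length(channels)
  durations <- vapply(channels, function(ch) length(ch$data) / ch$rate_hz, 0)
  if (max(durations) - min(durations) > 1e-9)
    stopf("all channels must cover the same duration")
  dur <- durations[1]
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),                              # version
    .edf_pad("synthetic affectkit recording", 80), # patient id
    .edf_pad("affectkit", 80),                     # recording id
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (1 + ns), 8),                   # header bytes
    .edf_pad("", 44),
    .edf_pad(1, 8),                                # number of data records
    .edf_num(dur, 8),                              # record duration (s)
    .edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(f, width)
    writeChar(paste0(vapply(channels, f, ""), collapse = ""), con, eos = NULL)
  pmin_ <- vapply(channels, function(ch) min(ch$data), 0)
  pmax_ <- vapply(channels, function(ch) max(ch$data), 0)
  flat <- pmax_ == pmin_
  pmax_[flat] <- pmax_[flat] + 1
  field(function(ch) .edf_pad(ch$label, 16), 16)
  field(function(ch) .edf_pad("", 80), 80)          # transducer
  field(function(ch) .edf_pad("au", 8), 8)          # physical dimension
  for (v in list(pmin_, pmax_)) {
    writeChar(paste0(vapply(v, .edf_num, "", width = 8), collapse = ""),
              con, eos = NULL)
  }
  writeChar(paste0(rep(.edf_pad(-32768, 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(.edf_pad(32767, 8), ns), collapse = ""), con, eos = NULL)
  field(function(ch) .edf_pad("", 80), 80)          # prefiltering
  field(function(ch) .edf_pad(length(ch$data), 8), 8)  # samples per record
  field(function(ch) .edf_pad("", 32), 32)          # reserved
  for (i in seq_len(ns)) {
    ch <- channels[[i]]
    scale <- (pmax_[i] - pmin_[i]) / (32767 - (-32768))
    dig <- round((ch$data - pmin_[i]) / scale) + (-32768)
    dig <- pmin(32767, pmax(-32768, dig))
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Write a signal record to an EDF file
#'
#' @param record a [signal_record] (equal-rate channels).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  channels <- lapply(seq_len(nrow(record$data)), function(i)
    list(label = record$channel_names[i], rate_hz = record$rate_hz,
         data = record$data[i, ]))
  write_edf_channels(channels, path)
}

#' Read an EDF file into a signal record
#'
#' Parses the fixed-width EDF header and 16-bit sample blocks, rescaling to
#' physical units. If channels have different sampling rates the read errors
#' unless `resample_hz` is given, in which case all channels are linearly
#' interpolated to that common rate.
#'
#' @param path EDF file path.
#' @param resample_hz optional target rate for mixed-rate files.
#' @return a [signal_record].
#' @export
read_edf <- function(path, resample_hz = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) readChar(con, width, useBytes = TRUE)
  num <- function(width) {
    s <- trimws(rd(width))
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stopf("corrupt EDF header: expected a number, got '%s'", s)
    v
  }
  version <- trimws(rd(8))
  if (version != "0") stopf("corrupt EDF header: bad version field '%s'", version)
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- num(8)
  rd(44)
  n_records <- num(8)
  rec_dur <- num(8)
  ns <- num(4)
  if (ns < 1 || header_bytes != 256 * (1 + ns))
    stopf("corrupt EDF header: inconsistent header length")
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) num(8), 0)
  pmax_ <- vapply(seq_len(ns), function(i) num(8), 0)
  dmin_ <- vapply(seq_len(ns), function(i) num(8), 0)
  dmax_ <- vapply(seq_len(ns), function(i) num(8), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) num(8), 0)
  for (i in seq_len(ns)) rd(32)
  chans <- lapply(seq_len(ns), function(i) numeric(0))
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2,
                     endian = "little", signed = TRUE)
      if (length(dig) < spr[i]) stopf("truncated EDF data record")
      phys <- pmin_[i] + (dig - dmin_[i]) * (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
      chans[[i]] <- c(chans[[i]], phys)
    }
  }
  rates <- spr / rec_dur
  if (max(rates) - min(rates) > 1e-9) {
    if (is.null(resample_hz))
      stopf(paste("mixed sampling rates (%s Hz); pass resample_hz to",
                  "interpolate to a common rate"),
            paste(signif(sort(unique(rates)), 6), collapse = ", "))
    dur <- n_records * rec_dur
    n_out <- round(dur * resample_hz)
    t_out <- (seq_len(n_out) - 1) / resample_hz
    chans <- lapply(seq_len(ns), function(i) {
      t_in <- (seq_along(chans[[i]]) - 1) / rates[i]
      stats::approx(t_in, chans[[i]], xout = t_out, rule = 2)$y
    })
    rate <- resample_hz
  } else rate <- rates[1]
  signal_record(do.call(rbind, chans), rate, labels)
}
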