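#' Read a multichannel signal from CSV
#'
#' Plain-text signal format: one column per channel, header row carrying the
#' channel ids, one sample per row.
#'
#' @param path file path.
#' @param rate sampling rate in Hz (CSV carries no rate).
#' @param t0 session start time in seconds.
#' @return a [recording()].
#' @export
read_signals_csv <- function(path, rate, t0 = 0) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (ncol(d) < 1L) stop("no channels in ", path)
  recording(t(as.matrix(d)), rate = rate, channel_ids = names(d), t0 = t0)
}

#' @rdname read_signals_csv
#' @param rec a `Recording` to write.
#' @export
write_signals_csv <- function(rec, path) {
  d <- as.data.frame(t(rec$samples))
  names(d) <- rec$channel_ids
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read ground-truth event times from TSV
#'
#' A single `time_s` column of event times in seconds.
#'
#' @param path file path.
#' @return an [event_list()].
#' @export
read_events_tsv <- function(path) {
  d <- utils::read.delim(path)
  if (!"time_s" %in% names(d)) stop("events TSV must have a `time_s` column")
  event_list(d$time_s)
}

#' @rdname read_events_tsv
#' @param ev an `EventList` to write.
#' @export
write_events_tsv <- function(ev, path) {
  utils::write.table(data.frame(time_s = as.numeric(ev)), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write detections as TSV
#'
#' Columns `time_s` and `posterior`.
#'
#' @param det a `DetectionList` (see [detect()]).
#' @param path file path.
#' @export
write_detections_tsv <- function(det, path) {
  utils::write.table(data.frame(time_s = det$times, posterior = det$posteriors),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- EDF (European Data Format) ---------------------------------------------
# Minimal EDF support: ASCII header + 2-byte little-endian integer samples,
# one data record layout with all channels at a common rate. Amplitudes are
# quantized to 16 bits on write.

edf_pad <- function(x, n) paste0(formatC(as.character(x), width = -n), collapse = "")

# numeric to at most 8 ASCII characters (EDF header field width)
edf_num8 <- function(v) {
  vapply(v, function(x) {
    for (d in 7:1) {
      s <- formatC(x, format = "g", digits = d)
      if (nchar(s) <= 8L) return(s)
    }
    stop("value ", x, " cannot be represented in 8 characters")
  }, "")
}

#' Write a recording as EDF
#'
#' European Data Format writer (continuous, all channels at the recording's
#' rate). Samples are scaled to the per-channel physical range and quantized
#' to 16-bit integers, so a round trip is exact only to quantization accuracy.
#'
#' @param rec a `Recording`.
#' @param path output path.
#' @param record_s data-record duration in seconds (default 1).
#' @export
write_edf <- function(rec, path, record_s = 1) {
  ns <- n_channels(rec)
  spr <- rec$rate * record_s
  if (spr != round(spr)) stop("rate * record_s must be an integer")
  spr <- as.integer(spr)
  n_rec <- ceiling(n_samples(rec) / spr)
  x <- rec$samples
  if (ncol(x) < n_rec * spr)  # pad final record with last sample
    x <- cbind(x, x[, rep(ncol(x), n_rec * spr - ncol(x)), drop = FALSE])
  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < .Machine$double.eps
  pmax_[flat] <- pmin_[flat] + 1
  # quantize against the 8-character header representation, so a round trip
  # reproduces the stored scaling exactly; pad the range so the header
  # rounding can never clip the data
  pad <- (pmax_ - pmin_) * 0.002
  pmin_s <- edf_num8(pmin_ - pad); pmax_s <- edf_num8(pmax_ + pad)
  pmin_ <- as.numeric(pmin_s); pmax_ <- as.numeric(pmax_s)
  dmin <- -32768L; dmax <- 32767L
  dig <- t(round((x - pmin_) / (pmax_ - pmin_) * (dmax - dmin) + dmin))
  storage.mode(dig) <- "integer"   # samples x channels

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, n) writeBin(charToRaw(edf_pad(s, n)), con)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8); wr("EDF+C", 44); wr(n_rec, 8)
  wr(format(record_s, digits = 8), 8); wr(ns, 4)
  for (s in rec$channel_ids) wr(s, 16)
  for (i in seq_len(ns)) wr("ECoG", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in pmin_s) wr(v, 8)
  for (v in pmax_s) wr(v, 8)
  wr(rep(dmin, ns), 8); wr(rep(dmax, ns), 8)
  for (i in seq_len(ns)) wr("", 80)
  wr(rep(spr, ns), 8)
  for (i in seq_len(ns)) wr("", 32)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(dig[rows, ]), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads continuous EDF files in which all channels share one sampling rate.
#'
#' @param path file path.
#' @param t0 session start time to assign (seconds).
#' @return a [recording()].
#' @export
read_edf <- function(path, t0 = 0) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  record_s <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # unit
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)           # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  if (length(unique(spr)) != 1L)
    stop("only EDF files with a single common sampling rate are supported")
  for (i in seq_len(ns)) rd(32)
  spr <- spr[1L]
  out <- matrix(0, ns, n_rec * spr)
  for (r in seq_len(n_rec)) {
    blk <- readBin(con, "integer", n = ns * spr, size = 2L,
                   endian = "little", signed = TRUE)
    blk <- matrix(blk, nrow = spr)
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    out[, cols] <- (t(blk) - dmin) / (dmax - dmin) * (pmax_ - pmin_) + pmin_
  }
  recording(out, rate = spr / record_s, channel_ids = labels, t0 = t0)
}
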