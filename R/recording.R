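#' Continuous multichannel recording
#'
#' Container for a continuous multichannel neural recording. Samples are held
#' as a channels-by-time numeric matrix; time is continuous seconds, sample
#' indices are 0-based internally, and the first sample lies at `t0`.
#'
#' @param samples numeric matrix, channels x time (a vector is treated as one
#'   channel). Volts or arbitrary units; unitless after normalization.
#' @param rate sampling rate in samples/second, > 0.
#' @param channel_ids character labels, one per channel. Defaults to
#'   `"ch1" ... "chN"`.
#' @param t0 session start time in seconds (default 0).
#' @return an object of class `Recording`.
#' @export
recording <- function(samples, rate, channel_ids = NULL, t0 = 0) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric channels x time matrix")
  if (nrow(samples) < 1L || ncol(samples) < 1L)
    stop("empty recording: need at least one channel and one sample")
  if (anyNA(samples)) stop("recording contains missing samples")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a single positive number")
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(samples)))
  if (length(channel_ids) != nrow(samples))
    stop("`channel_ids` must have one label per channel")
  structure(
    list(samples = samples, rate = rate,
         channel_ids = as.character(channel_ids), t0 = as.numeric(t0)),
    class = "Recording")
}

#' @export
print.Recording <- function(x, ...) {
  cat(sprintf("Recording: %d channel(s), %d samples @ %g Hz (%.2f s, t0 = %g s)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate, x$t0))
  invisible(x)
}

#' @rdname recording
#' @param rec a `Recording`.
#' @export
n_channels <- function(rec) nrow(rec$samples)

#' @rdname recording
#' @export
n_samples <- function(rec) ncol(rec$samples)

#' @rdname recording
#' @export
rec_duration <- function(rec) ncol(rec$samples) / rec$rate

#' Sample times of a recording
#'
#' @param rec a `Recording`.
#' @return numeric vector of sample times in seconds (`t0 + i/rate`, 0-based).
#' @export
rec_times <- function(rec) rec$t0 + (seq_len(ncol(rec$samples)) - 1L) / rec$rate

#' Ground-truth event list
#'
#' Ordered event times in seconds, relative to session start. Times must be
#' strictly increasing.
#'
#' @param times numeric vector of event times (seconds).
#' @return an object of class `EventList` (a numeric vector).
#' @export
event_list <- function(times) {
  times <- as.numeric(times)
  if (anyNA(times)) stop("event times contain NA")
  if (is.unsorted(times, strictly = TRUE))
    stop("event times must be strictly increasing")
  structure(times, class = "EventList")
}

#' @export
print.EventList <- function(x, ...) {
  cat(sprintf("EventList: %d event(s)", length(x)))
  if (length(x)) cat(sprintf(" spanning [%.3f, %.3f] s", min(x), max(x)))
  cat("\n")
  invisible(x)
}

# keep class through subsetting
#' @export
`[.EventList` <- function(x, i) event_list(unclass(x)[i])

check_events_in_span <- function(ev, rec) {
  t_end <- rec$t0 + (n_samples(rec) - 1L) / rec$rate
  if (length(ev) && (min(ev) < rec$t0 || max(ev) > t_end))
    stop("event times fall outside the recording span")
  invisible(TRUE)
}
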