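#' Common average reference
#'
#' Subtracts, at every sample, the mean across all channels present in the
#' recording. Re-referencing is done on the full montage, before any channel
#' subsetting for feature construction.
#'
#' @param rec a [recording()].
#' @return the re-referenced `Recording`; at every sample index the mean
#'   across output channels is zero.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "Recording"))
  rec$samples <- sweep(rec$samples, 2L, colMeans(rec$samples))
  rec
}

#' Per-channel normalization
#'
#' Subtracts from each channel its mean voltage over the whole session and
#' divides by its standard deviation over time, so systematic amplitude
#' differences across channels do not bias multichannel feature vectors.
#' Statistics default to the whole session; `span` restricts them to a
#' sub-interval (train-only mode) while the transform is still applied to all
#' samples.
#'
#' @param rec a [recording()].
#' @param span optional `c(t_start, t_end)` in seconds: compute mean/sd from
#'   this interval only.
#' @return the normalized `Recording`.
#' @export
normalize_channels <- function(rec, span = NULL) {
  stopifnot(inherits(rec, "Recording"))
  x <- rec$samples
  if (is.null(span)) {
    stat <- x
  } else {
    tt <- rec_times(rec)
    keep <- tt >= span[1] & tt <= span[2]
    if (!any(keep)) stop("`span` contains no samples")
    stat <- x[, keep, drop = FALSE]
  }
  mu <- rowMeans(stat)
  sd_ <- sqrt(rowMeans((stat - mu)^2))
  bad <- sd_ < .Machine$double.eps * max(1, max(abs(stat)))
  if (any(bad))
    stop("zero-variance channel(s): ",
         paste(rec$channel_ids[bad], collapse = ", "))
  rec$samples <- (x - mu) / sd_
  rec
}

#' Restrict a session to task periods
#'
#' Drops stretches of the recording that are further than 4 times the median
#' inter-event interval away from every event, returning the remaining
#' contiguous segments. Events are always retained.
#'
#' @param rec a [recording()].
#' @param ev an [event_list()] with at least 2 events.
#' @param factor multiple of the median inter-event interval (default 4).
#' @return list with `segments` (list of `Recording`, each with its own `t0`)
#'   and `events` (unchanged `EventList`).
#' @export
restrict_to_task_periods <- function(rec, ev, factor = 4) {
  stopifnot(inherits(rec, "Recording"))
  if (length(ev) < 2L)
    stop("need at least 2 events to define the median inter-event interval")
  check_events_in_span(ev, rec)
  max_dist <- factor * stats::median(diff(as.numeric(ev)))
  tt <- rec_times(rec)
  # distance from each sample to the nearest event
  idx <- findInterval(tt, as.numeric(ev))
  d_lo <- ifelse(idx >= 1L, tt - as.numeric(ev)[pmax(idx, 1L)], Inf)
  d_hi <- ifelse(idx < length(ev), as.numeric(ev)[pmin(idx + 1L, length(ev))] - tt, Inf)
  keep <- pmin(d_lo, d_hi) <= max_dist
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    segs[[length(segs) + 1L]] <- recording(
      rec$samples[, starts[j]:ends[j], drop = FALSE], rate = rec$rate,
      channel_ids = rec$channel_ids, t0 = tt[starts[j]])
  }
  list(segments = segs, events = ev)
}
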