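# Online detection: threshold crossing, bounded look-ahead towards a local
# posterior maximum, and a refractory period.

#' Detector configuration
#'
#' @param threshold posterior cutoff that opens a candidate (default 0.95).
#' @param t_advance_steps look-ahead in evaluation steps (default 3, i.e.
#'   3/64 s at the default evaluation rate).
#' @param refractory_s minimum interval between emitted detections (default
#'   1.5 s).
#' @param eval_rate evaluation rate of the posterior stream (default 64 /s).
#' @return an object of class `DetectorConfig`.
#' @export
detector_config <- function(threshold = 0.95, t_advance_steps = 3L,
                            refractory_s = 1.5, eval_rate = 64) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (t_advance_steps < 0) stop("t_advance_steps must be >= 0")
  if (refractory_s <= 0) stop("refractory_s must be > 0")
  structure(list(threshold = threshold,
                 t_advance_steps = as.integer(t_advance_steps),
                 refractory_s = refractory_s, eval_rate = eval_rate,
                 refractory_steps = as.integer(round(refractory_s * eval_rate))),
            class = "DetectorConfig")
}

#' Streaming detector state
#'
#' Creates an empty detector state. Feed uniformly sampled posterior values
#' with [detector_feed()] in chunks of any size (including empty chunks);
#' finalize with [detector_flush()]. Chunked and whole-trace processing
#' yield identical detections.
#'
#' @param cfg a [detector_config()].
#' @param t0 time of the first posterior sample (seconds).
#' @return an object of class `DetectorState`.
#' @export
detector_state <- function(cfg, t0 = 0) {
  structure(list(cfg = cfg, t0 = t0, i = 0L,
                 cand_i = NA_integer_, cand_p = NA_real_,
                 last_emit = -Inf,
                 det_i = integer(), det_p = numeric()),
            class = "DetectorState")
}

# core per-sample rule, vectorized over a chunk by fast-skipping the
# below-threshold / refractory stretches
feed_samples <- function(state, p) {
  cfg <- state$cfg
  thr <- cfg$threshold; la <- cfg$t_advance_steps; rf <- cfg$refractory_steps
  i0 <- state$i                    # global 0-based index of p[1]
  cand_i <- state$cand_i; cand_p <- state$cand_p
  last_emit <- state$last_emit
  det_i <- state$det_i; det_p <- state$det_p
  n <- length(p)
  j <- 1L
  above <- p > thr
  while (j <= n) {
    i <- i0 + j - 1L
    if (is.na(cand_i)) {
      # no candidate: jump to the next admissible threshold crossing
      j_min <- if (is.finite(last_emit))
        max(j, as.integer(last_emit + rf) - i0 + 1L) else j
      if (j_min > n) break
      nxt <- which(above[j_min:n])[1L]
      if (is.na(nxt)) break
      j <- j_min + nxt - 1L
      cand_i <- i0 + j - 1L
      cand_p <- p[j]
      j <- j + 1L
    } else {
      if (p[j] > cand_p && i - cand_i <= la) {
        cand_i <- i                # strictly higher within the window:
        cand_p <- p[j]             # shift; the window restarts
        j <- j + 1L
      } else if (i - cand_i >= la) {
        det_i <- c(det_i, cand_i)  # look-ahead exhausted: emit
        det_p <- c(det_p, cand_p)
        last_emit <- cand_i
        cand_i <- NA_integer_; cand_p <- NA_real_
      } else {
        j <- j + 1L
      }
    }
  }
  state$i <- i0 + n
  state$cand_i <- cand_i; state$cand_p <- cand_p
  state$last_emit <- last_emit
  state$det_i <- det_i; state$det_p <- det_p
  state
}

#' @rdname detector_state
#' @param state a `DetectorState`.
#' @param p numeric chunk of posterior values in \[0, 1\] (may be empty).
#' @export
detector_feed <- function(state, p) {
  stopifnot(inherits(state, "DetectorState"))
  p <- as.numeric(p)
  if (anyNA(p) || (length(p) && (min(p) < 0 || max(p) > 1)))
    stop("posterior values must lie in [0, 1]")
  if (length(p) == 0L) return(state)
  feed_samples(state, p)
}

#' @rdname detector_state
#' @export
detector_flush <- function(state) {
  stopifnot(inherits(state, "DetectorState"))
  if (!is.na(state$cand_i)) {      # end of stream: emit the open candidate
    state$det_i <- c(state$det_i, state$cand_i)
    state$det_p <- c(state$det_p, state$cand_p)
    state$last_emit <- state$cand_i
    state$cand_i <- NA_integer_; state$cand_p <- NA_real_
  }
  state
}

#' @rdname detector_state
#' @export
detector_detections <- function(state) {
  structure(list(times = state$t0 + state$det_i / state$cfg$eval_rate,
                 posteriors = state$det_p),
            class = "DetectionList")
}

#' Detect events in a posterior stream
#'
#' Turns a uniformly sampled posterior trace into discrete detection times.
#' A candidate opens when the posterior exceeds the threshold outside the
#' refractory period; it shifts to any strictly higher posterior within the
#' next `t_advance` window, recursively (the window restarts after each
#' shift), and is emitted once no higher value follows within the window.
#' Emitted detections suppress further candidates for `refractory_s`
#' (measured from the emitted detection time). On plateaus the earliest
#' sample at the maximum is kept.
#'
#' @param p numeric posterior trace in \[0, 1\], sampled at
#'   `cfg$eval_rate`.
#' @param cfg a [detector_config()].
#' @param t0 time of `p[1]` in seconds.
#' @return a `DetectionList`: `times` (strictly increasing, consecutive
#'   detections at least `refractory_s` apart) and `posteriors`.
#' @export
detect <- function(p, cfg = detector_config(), t0 = 0) {
  st <- detector_state(cfg, t0 = t0)
  st <- detector_feed(st, p)
  st <- detector_flush(st)
  detector_detections(st)
}

#' @export
print.DetectionList <- function(x, ...) {
  cat(sprintf("DetectionList: %d detection(s)\n", length(x$times)))
  invisible(x)
}
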