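# Assembly of per-time-step feature vectors from signal components, with
# configurable delay and signal history, and event/non-event training sets.

#' Feature-vector configuration
#'
#' @param delay seconds between the newest feature sample and the reference
#'   time: the newest sample entering the feature vector for time `t` is
#'   taken at `t + delay`. Negative delay means all features precede `t`
#'   (prediction); positive delay lets features extend past it.
#' @param history_s length of signal history in seconds (>= 0). History is
#'   sampled at `history_rate`, so the vector holds
#'   `history_rate * history_s + 1` samples per channel per component.
#' @param history_rate history sampling rate (default 16 /s).
#' @param eval_rate evaluation rate (default 64 /s); must be divisible by
#'   `history_rate`. Both grids are aligned to session start.
#' @return an object of class `FeatureConfig`.
#' @export
feature_config <- function(delay = 0, history_s = 1, history_rate = 16,
                           eval_rate = 64) {
  if (history_s < 0) stop("history_s must be >= 0")
  if (eval_rate %% history_rate != 0)
    stop("eval_rate must be divisible by history_rate")
  k <- history_rate * history_s
  if (abs(k - round(k)) > 1e-9)
    stop("history_rate * history_s must be an integer number of samples")
  structure(list(delay = delay, history_s = history_s,
                 history_rate = history_rate, eval_rate = eval_rate,
                 n_hist = as.integer(round(k))),
            class = "FeatureConfig")
}

#' Feature-vector length
#'
#' `n_channels * n_components * (history_rate * history_s + 1)`.
#'
#' @param compset a [extract_components()] result.
#' @param cfg a [feature_config()].
#' @return integer vector length.
#' @export
n_features <- function(compset, cfg) {
  compset$n_channels * length(compset$values) * (cfg$n_hist + 1L)
}

# 1-based evaluation index of a time on the evaluation grid
eval_index <- function(compset, t) {
  as.integer(round((t - compset$t0) * compset$eval_rate)) + 1L
}

eval_time <- function(compset, idx) compset$t0 + (idx - 1L) / compset$eval_rate

# per-row sample indices (newest first), given reference evaluation indices
feature_sample_index <- function(idx, cfg) {
  dstep <- as.integer(round(cfg$delay * cfg$eval_rate))
  hstep <- as.integer(cfg$eval_rate / cfg$history_rate)
  newest <- idx + dstep
  outer(newest, hstep * (0:cfg$n_hist), "-")   # n x (n_hist + 1)
}

# logical: rows fully inside valid (post-warm-up, in-range) data
feature_index_valid <- function(compset, idx, cfg) {
  si <- feature_sample_index(idx, cfg)
  si[, ncol(si)] >= compset$valid_from & si[, 1L] <= compset$n_eval
}

#' Build feature rows for given evaluation times
#'
#' One row per reference index; per component and channel, the samples at
#' `t + delay - k / history_rate` for `k = 0 .. history_rate * history_s`,
#' newest first, concatenated over channels within each component and over
#' components (component-major, then channel, then history).
#'
#' @param compset a [extract_components()] result.
#' @param idx 1-based evaluation indices (rows must be valid, see errors).
#' @param cfg a [feature_config()].
#' @return numeric matrix `length(idx)` x [n_features()].
#' @export
feature_rows <- function(compset, idx, cfg) {
  if (!all(feature_index_valid(compset, idx, cfg)))
    stop("some rows have insufficient history (window outside valid data)")
  si <- feature_sample_index(idx, cfg)
  k1 <- cfg$n_hist + 1L
  nch <- compset$n_channels
  X <- matrix(0, length(idx), n_features(compset, cfg))
  col0 <- 0L
  for (ci in seq_along(compset$values)) {
    v <- compset$values[[ci]]
    for (ch in seq_len(nch)) {
      X[, col0 + seq_len(k1)] <- v[ch, ][si]
      col0 <- col0 + k1
    }
  }
  X
}

#' Single feature vector at a time point
#'
#' @param compset a [extract_components()] result.
#' @param t reference time in seconds (snapped to the evaluation grid).
#' @param cfg a [feature_config()].
#' @return numeric feature vector.
#' @export
feature_vector <- function(compset, t, cfg) {
  drop(feature_rows(compset, eval_index(compset, t), cfg))
}

# membership of closed interval [lo, hi] in spans (2-column matrix)
in_some_span <- function(lo, hi, spans) {
  ok <- rep(FALSE, length(lo))
  for (r in seq_len(nrow(spans)))
    ok <- ok | (lo >= spans[r, 1] - 1e-9 & hi <= spans[r, 2] + 1e-9)
  ok
}

#' Build an event / non-event training set
#'
#' One event-class row per usable event (feature window referenced to the
#' event time under `cfg$delay`, fully inside one span interval and past
#' warm-up). Non-event rows are drawn at evenly spaced evaluation times over
#' the eligible remainder of the span -- all times closer than 0.3 s to any
#' event are excluded -- and truncated to exactly `ratio` times the number
#' of event rows.
#'
#' @param compset a [extract_components()] result.
#' @param events an [event_list()].
#' @param cfg a [feature_config()].
#' @param span `c(t_start, t_end)` or a 2-column matrix of intervals
#'   (seconds) delimiting the training data.
#' @param ratio non-event rows per event row (default 16).
#' @param exclusion_s non-event exclusion zone around events (default 0.3 s).
#' @return an object of class `FeatureMatrix`: `X`, `t` (row times), `y`
#'   (factor event/nonevent), `cfg`.
#' @export
build_training_set <- function(compset, events, cfg, span, ratio = 16L,
                               exclusion_s = 0.3) {
  if (!is.matrix(span)) span <- matrix(span, ncol = 2L, byrow = TRUE)
  ev <- as.numeric(events)
  hstep_s <- cfg$history_s
  win_lo <- function(t) t + cfg$delay - hstep_s
  win_hi <- function(t) t + cfg$delay

  ev_idx <- eval_index(compset, ev)
  usable <- in_some_span(pmin(win_lo(ev), ev), pmax(win_hi(ev), ev), span) &
    feature_index_valid(compset, ev_idx, cfg)
  if (!any(usable)) stop("no usable events inside the training span")
  ev_idx <- ev_idx[usable]

  all_idx <- seq_len(compset$n_eval)
  tt <- eval_time(compset, all_idx)
  elig <- in_some_span(pmin(win_lo(tt), tt), pmax(win_hi(tt), tt), span) &
    feature_index_valid(compset, all_idx, cfg)
  if (length(ev)) {
    near <- findInterval(tt, ev)
    d_lo <- ifelse(near >= 1L, tt - ev[pmax(near, 1L)], Inf)
    d_hi <- ifelse(near < length(ev), ev[pmin(near + 1L, length(ev))] - tt, Inf)
    elig <- elig & pmin(d_lo, d_hi) >= exclusion_s
  }
  elig_idx <- all_idx[elig]
  quota <- ratio * length(ev_idx)
  if (length(elig_idx) < quota)
    stop("span too short: only ", length(elig_idx),
         " eligible non-event times for a quota of ", quota)
  spacing <- max(1L, floor(length(elig_idx) / quota))
  ne_idx <- elig_idx[seq(1L, length(elig_idx), by = spacing)][seq_len(quota)]

  idx <- c(ev_idx, ne_idx)
  structure(list(
    X = feature_rows(compset, idx, cfg),
    t = eval_time(compset, idx),
    y = factor(rep(c("event", "nonevent"), c(length(ev_idx), length(ne_idx))),
               levels = c("event", "nonevent")),
    cfg = cfg), class = "FeatureMatrix")
}
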