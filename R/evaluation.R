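# Scoring detections against ground truth: tolerance-dependent sensitivity
# and specificity, temporal precision, and the random-predictor baseline.

# Resolve nearest event-detection pairs (no tolerance): each event claims its
# nearest detection; a detection claimed by several events goes to the
# closest one, the other events stay undetected.
nearest_pairs <- function(det_times, event_times) {
  ev <- as.numeric(event_times); dt_ <- sort(as.numeric(det_times))
  if (length(ev) == 0L || length(dt_) == 0L)
    return(data.frame(event = numeric(), detection = numeric(),
                      de = numeric()))
  pos <- findInterval(ev, dt_)
  lo <- pmax(pos, 1L); hi <- pmin(pos + 1L, length(dt_))
  d_lo <- abs(ev - dt_[lo]); d_hi <- abs(dt_[hi] - ev)
  pick <- ifelse(pos < 1L, hi, ifelse(pos >= length(dt_), lo,
                                      ifelse(d_lo <= d_hi, lo, hi)))
  pairs <- data.frame(event = ev, detection = dt_[pick],
                      de = dt_[pick] - ev, idx = pick)
  keep <- unlist(lapply(split(seq_len(nrow(pairs)), pairs$idx), function(rows)
    rows[which.min(abs(pairs$de[rows]))]), use.names = FALSE)
  pairs <- pairs[sort(keep), c("event", "detection", "de")]
  rownames(pairs) <- NULL
  pairs
}

#' Match detections to events under a tolerance
#'
#' One-to-one matching: each event is matched to its nearest detection if
#' that lies within `tau` seconds; a detection claimed by two events goes to
#' the closer event (the farther event stays undetected). True positives are
#' matched events; false positives are unmatched detections.
#'
#' @param detections a `DetectionList` (see [detect()]) or numeric vector of
#'   detection times.
#' @param events an [event_list()] or numeric vector of event times.
#' @param tau tolerance in seconds (>= 0).
#' @return list with `n_tp`, `n_fp`, `n_events`, `n_det` and the matched
#'   `pairs` (columns `event`, `detection`, `de`).
#' @export
match_detections <- function(detections, events, tau) {
  if (tau < 0) stop("`tau` must be >= 0")
  dt_ <- if (is.list(detections)) detections$times else as.numeric(detections)
  ev <- as.numeric(events)
  pairs <- nearest_pairs(dt_, ev)
  pairs <- pairs[abs(pairs$de) <= tau, , drop = FALSE]
  list(n_tp = nrow(pairs), n_fp = length(dt_) - nrow(pairs),
       n_events = length(ev), n_det = length(dt_), pairs = pairs)
}

#' Detection errors of the closest detections
#'
#' Signed differences (detection minus event) between each event and its
#' nearest detection, after resolving detections claimed by several events
#' in favour of the closest event. Independent of any tolerance.
#'
#' @inheritParams match_detections
#' @return numeric vector of detection errors in seconds (one per detected
#'   event; possibly shorter than the event list).
#' @export
detection_errors <- function(detections, events) {
  dt_ <- if (is.list(detections)) detections$times else as.numeric(detections)
  nearest_pairs(dt_, as.numeric(events))$de
}

#' Sensitivity and specificity ratios
#'
#' `TPR = N_TP / N_events` (fraction of real events detected) and
#' `FPR = N_FP / N_det` (fraction of detections that are false); `FPR` is 0
#' by convention when there are no detections.
#'
#' @param n_tp,n_fp,n_events,n_det counts from [match_detections()].
#' @return list with `tpr` and `fpr`.
#' @export
tpr_fpr <- function(n_tp, n_fp, n_events, n_det) {
  if (n_events <= 0) stop("`n_events` must be > 0")
  list(tpr = n_tp / n_events,
       fpr = if (n_det == 0) 0 else n_fp / n_det)
}

#' Temporal bias and deviation
#'
#' `bias` is the median detection error; the temporal deviation `TD` is the
#' root mean squared detection error (equal to the standard deviation only
#' when the mean error is zero, larger under a systematic bias).
#'
#' @param de numeric vector of detection errors (seconds), non-empty.
#' @return list with `bias` and `td` in seconds.
#' @export
temporal_stats <- function(de) {
  if (length(de) == 0L) stop("no detection errors supplied")
  list(bias = stats::median(de), td = sqrt(mean(de^2)))
}

#' False positive rate per minute
#'
#' @param n_fp number of false positives.
#' @param T_s evaluated duration in seconds (> 0).
#' @return false positives per minute.
#' @export
fp_rate <- function(n_fp, T_s) {
  if (T_s <= 0) stop("`T_s` must be > 0")
  60 * n_fp / T_s
}

#' Expected performance of the random predictor
#'
#' Closed-form expected `TPR` and `FPR` of a chance detector: a stationary
#' renewal process emitting detections at the true event rate
#' `N_events / T`, with a minimal inter-occurrence interval equal to the
#' refractory period, deciding on a grid of step `dt`. For tolerances below
#' half the refractory period at most one detection can fall inside an
#' event's tolerance window, so the expected number of detections in the
#' window -- rate times the `2 tau + dt` span covered by the window's grid
#' points -- equals the probability of detecting the event:
#' \deqn{TPR_{rand}(\tau) = \frac{N_{events}}{T} (2\tau + \Delta t), \qquad
#'       FPR_{rand}(\tau) = 1 - TPR_{rand}(\tau),}
#' the latter because the matched rate makes the expected number of
#' detections equal `N_events`. Both are linear in `tau`.
#'
#' @param n_events number of true events.
#' @param T_s session length in seconds.
#' @param tau tolerance in seconds, `0 <= tau < refractory_s / 2`.
#' @param refractory_s refractory period (default 1.5 s).
#' @param dt decision grid step (default 1/64 s).
#' @return list with `tpr` and `fpr`.
#' @export
random_predictor <- function(n_events, T_s, tau, refractory_s = 1.5,
                             dt = 1 / 64) {
  if (tau < 0) stop("`tau` must be >= 0")
  if (tau >= refractory_s / 2)
    stop("closed form invalid: `tau` must be below refractory_s / 2 = ",
         refractory_s / 2)
  tpr <- min(1, (n_events / T_s) * (2 * tau + dt))
  list(tpr = tpr, fpr = 1 - tpr)
}

#' Monte-Carlo simulation of the random predictor
#'
#' Simulates the refractory renewal detector (shifted-exponential intervals:
#' refractory period plus an exponential with mean chosen so the detection
#' rate matches `n_events / T_s`), and scores it against the given events.
#' Decisions are made in steps of `dt`, so both detections and events are
#' compared at the grid resolution -- the process the closed form in
#' [random_predictor()] describes. A burn-in before session start brings
#' the process to stationarity.
#'
#' @param events event times in seconds.
#' @param T_s session length in seconds.
#' @param tau tolerance in seconds.
#' @param refractory_s refractory period (default 1.5 s).
#' @param dt decision grid step (default 1/64 s).
#' @param n_sim number of simulated sessions.
#' @return list with `tpr`, `fpr` (means over simulations), `tpr_se`,
#'   `fpr_se` (standard errors of those means), and the per-simulation
#'   draws `tpr_draws`, `fpr_draws`.
#' @export
random_predictor_mc <- function(events, T_s, tau, refractory_s = 1.5,
                                dt = 1 / 64, n_sim = 1000L) {
  ev <- round(as.numeric(events) / dt) * dt
  mean_iv <- T_s / length(ev)
  if (mean_iv <= refractory_s)
    stop("event rate too high: mean interval must exceed the refractory period")
  exp_mean <- mean_iv - refractory_s
  burn <- 5 * mean_iv
  tprs <- numeric(n_sim); fprs <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    n_max <- ceiling((T_s + burn) / mean_iv * 3 + 20)
    iv <- refractory_s + stats::rexp(n_max, rate = 1 / exp_mean)
    det <- cumsum(iv) - burn
    while (det[length(det)] < T_s) {   # rare: extend until span covered
      iv <- refractory_s + stats::rexp(n_max, rate = 1 / exp_mean)
      det <- c(det, det[length(det)] + cumsum(iv))
    }
    det <- det[det >= 0 & det <= T_s]
    det <- round(det / dt) * dt
    m <- match_detections(det, ev, tau)
    r <- tpr_fpr(m$n_tp, m$n_fp, m$n_events, m$n_det)
    tprs[s] <- r$tpr; fprs[s] <- r$fpr
  }
  list(tpr = mean(tprs), fpr = mean(fprs),
       tpr_se = stats::sd(tprs) / sqrt(n_sim),
       fpr_se = stats::sd(fprs) / sqrt(n_sim),
       tpr_draws = tprs, fpr_draws = fprs)
}

#' Evaluation report for a set of detections
#'
#' Tolerance-resolved counts and ratios, false positive rate per minute, the
#' random-predictor baseline at each tolerance (where defined), and
#' tolerance-free temporal precision (bias and temporal deviation of the
#' nearest-detection errors).
#'
#' @param detections a `DetectionList` or numeric detection times.
#' @param events an [event_list()] or numeric event times.
#' @param T_s evaluated duration in seconds.
#' @param taus tolerances in seconds (default 0.125 to 0.75 by 0.125).
#' @param refractory_s refractory period for the baseline (default 1.5 s).
#' @param dt decision grid step for the baseline (default 1/64 s).
#' @return an object of class `EvalReport`: `by_tau` data frame (`tau`,
#'   `n_tp`, `n_fp`, `tpr`, `fpr`, `fp_rate_per_min`, `tpr_rand`,
#'   `fpr_rand`), `de` (detection errors), `bias`, `td`, `n_events`,
#'   `n_det`, `T_s`.
#' @export
eval_report <- function(detections, events, T_s,
                        taus = seq(0.125, 0.75, by = 0.125),
                        refractory_s = 1.5, dt = 1 / 64) {
  dt_times <- if (is.list(detections)) detections$times else as.numeric(detections)
  ev <- as.numeric(events)
  rows <- lapply(taus, function(tau) {
    m <- match_detections(dt_times, ev, tau)
    r <- tpr_fpr(m$n_tp, m$n_fp, m$n_events, m$n_det)
    base <- if (tau < refractory_s / 2)
      random_predictor(length(ev), T_s, tau, refractory_s, dt)
    else list(tpr = NA_real_, fpr = NA_real_)
    data.frame(tau = tau, n_tp = m$n_tp, n_fp = m$n_fp,
               tpr = r$tpr, fpr = r$fpr,
               fp_rate_per_min = fp_rate(m$n_fp, T_s),
               tpr_rand = base$tpr, fpr_rand = base$fpr)
  })
  de <- detection_errors(dt_times, ev)
  ts <- if (length(de)) temporal_stats(de) else list(bias = NA_real_, td = NA_real_)
  structure(list(by_tau = do.call(rbind, rows), de = de,
                 bias = ts$bias, td = ts$td,
                 n_events = length(ev), n_det = length(dt_times), T_s = T_s),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport: %d events, %d detections over %.1f s\n",
              x$n_events, x$n_det, x$T_s))
  print(x$by_tau, row.names = FALSE, digits = 3)
  cat(sprintf("bias = %.0f ms, TD = %.0f ms\n", 1000 * x$bias, 1000 * x$td))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' @param report an [eval_report()].
#' @param path output path (`.json` for the full report, `.tsv` for the
#'   per-tolerance table).
#' @export
write_eval_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_eval_json
#' @export
write_eval_tsv <- function(report, path) {
  utils::write.table(report$by_tau, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
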