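# Blocked ten-fold cross-validation with nested regularization selection,
# and the frequency-band scan.

#' Default regularization grid
#' @export
LAMBDA_GRID <- c(0.0001, 0.001, 0.01, 0.1, 0.5, 1)

#' Blocked contiguous folds
#'
#' Splits a session into `k` contiguous periods of equal length (to within
#' one evaluation step): mutually exclusive and jointly exhaustive.
#'
#' @param session_length_s session length in seconds.
#' @param k number of folds (default 10, must be >= 2).
#' @param t0 session start time (default 0).
#' @param eval_rate evaluation rate used to snap boundaries (default 64).
#' @return an object of class `CvPlan`: data frame with `fold`, `t_start`,
#'   `t_end`.
#' @export
blocked_folds <- function(session_length_s, k = 10L, t0 = 0, eval_rate = 64) {
  if (k < 2L) stop("k must be >= 2 (k = 1 leaves no held-out data)")
  n_steps <- floor(session_length_s * eval_rate)
  if (n_steps < k) stop("session too short: fewer evaluation steps than folds")
  cuts <- t0 + round(seq(0, n_steps, length.out = k + 1)) / eval_rate
  plan <- data.frame(fold = seq_len(k), t_start = cuts[-(k + 1)],
                     t_end = cuts[-1])
  class(plan) <- c("CvPlan", "data.frame")
  plan
}

# merge the spans of all folds except `exclude` into a 2-column matrix of
# maximal contiguous intervals
fold_spans <- function(plan, exclude = integer()) {
  keep <- plan[!plan$fold %in% exclude, , drop = FALSE]
  if (nrow(keep) == 0L) return(matrix(numeric(), ncol = 2L))
  out <- matrix(c(keep$t_start[1L], keep$t_end[1L]), ncol = 2L)
  for (r in seq_len(nrow(keep))[-1L]) {
    if (abs(keep$t_start[r] - out[nrow(out), 2L]) < 1e-9)
      out[nrow(out), 2L] <- keep$t_end[r]
    else
      out <- rbind(out, c(keep$t_start[r], keep$t_end[r]))
  }
  out
}

# posterior over a set of evaluation indices without materializing the
# feature matrix: the RLDA log-odds is affine, so the trace is a sum of
# weighted, shifted component rows
rlda_score_trace <- function(compset, model, cfg, idx) {
  dstep <- as.integer(round(cfg$delay * cfg$eval_rate))
  hstep <- as.integer(cfg$eval_rate / cfg$history_rate)
  s <- rep(model$b, length(idx))
  pos <- 0L
  for (ci in seq_along(compset$values)) {
    v <- compset$values[[ci]]
    for (ch in seq_len(compset$n_channels)) {
      for (k in 0:cfg$n_hist) {
        s <- s + model$w[pos + k + 1L] * v[ch, idx + dstep - hstep * k]
      }
      pos <- pos + cfg$n_hist + 1L
    }
  }
  stats::plogis(s)
}

# full posterior trace over `spans` (invalid/warm-up rows get posterior 0);
# returns list(idx, p) on the evaluation grid
posterior_over_spans <- function(compset, model, cfg, spans) {
  idx_all <- integer(); p_all <- numeric()
  for (r in seq_len(nrow(spans))) {
    lo <- eval_index(compset, spans[r, 1L])
    hi <- eval_index(compset, spans[r, 2L]) - 1L
    lo <- max(lo, 1L); hi <- min(hi, compset$n_eval)
    if (lo > hi) next
    idx <- lo:hi
    p <- numeric(length(idx))
    ok <- feature_index_valid(compset, idx, cfg)
    if (any(ok)) p[ok] <- rlda_score_trace(compset, model, cfg, idx[ok])
    idx_all <- c(idx_all, idx); p_all <- c(p_all, p)
  }
  list(idx = idx_all, p = p_all)
}

events_in_spans <- function(events, spans) {
  ev <- as.numeric(events)
  keep <- rep(FALSE, length(ev))
  for (r in seq_len(nrow(spans)))
    keep <- keep | (ev >= spans[r, 1L] & ev < spans[r, 2L])
  ev[keep]
}

# detect over each contiguous span separately and pool the detections
detect_over_spans <- function(compset, model, fcfg, dcfg, spans) {
  times <- numeric(); post <- numeric()
  for (r in seq_len(nrow(spans))) {
    tr <- posterior_over_spans(compset, model, fcfg,
                               spans[r, , drop = FALSE])
    if (!length(tr$idx)) next
    d <- detect(tr$p, dcfg, t0 = eval_time(compset, tr$idx[1L]))
    times <- c(times, d$times); post <- c(post, d$posteriors)
  }
  list(times = times, posteriors = post)
}

#' Select the regularization weight by inner cross-validation
#'
#' Splits the training time into `inner_k` contiguous blocks; for each
#' candidate lambda, trains on the complement of each block, detects on the
#' block, pools counts, and scores `TPR - FPR` at tolerance `tau`. Returns
#' the lambda with the best pooled score; ties break towards the smallest
#' lambda.
#'
#' @param compset a [extract_components()] result.
#' @param events an [event_list()].
#' @param fcfg a [feature_config()].
#' @param dcfg a [detector_config()].
#' @param train_spans 2-column matrix of training intervals (seconds).
#' @param lambda_grid candidate values (default [LAMBDA_GRID]).
#' @param inner_k number of inner folds (default 10).
#' @param tau tolerance for the inner objective (default 0.5 s).
#' @return the selected lambda (scalar), with the per-lambda scores attached
#'   as attribute `"scores"`.
#' @export
select_lambda <- function(compset, events, fcfg, dcfg, train_spans,
                          lambda_grid = LAMBDA_GRID, inner_k = 10L,
                          tau = 0.5) {
  # cut the training time into inner_k contiguous blocks by cumulative length
  lens <- train_spans[, 2L] - train_spans[, 1L]
  total <- sum(lens)
  cuts <- seq(0, total, length.out = inner_k + 1L)
  cum0 <- cumsum(c(0, lens))
  to_abs <- function(u) {  # position in training-time -> absolute time
    r <- findInterval(u, cum0, rightmost.closed = TRUE)
    r <- pmin(pmax(r, 1L), length(lens))
    train_spans[r, 1L] + (u - cum0[r])
  }
  inner <- vector("list", inner_k)
  for (f in seq_len(inner_k)) {
    pieces <- list()
    for (r in seq_along(lens)) {
      lo <- max(cuts[f], cum0[r]); hi <- min(cuts[f + 1L], cum0[r + 1L])
      if (hi - lo > 1e-9) pieces[[length(pieces) + 1L]] <- c(to_abs(lo), to_abs(hi))
    }
    inner[[f]] <- do.call(rbind, pieces)
  }
  ev_counts <- vapply(inner, function(sp) length(events_in_spans(events, sp)), 0L)
  if (sum(ev_counts > 0L) < 2L)
    stop("degenerate inner folds: event counts per fold are ",
         paste(ev_counts, collapse = ", "))

  scores <- numeric(length(lambda_grid))
  # training sets per inner fold are shared across lambdas
  train_sets <- vector("list", inner_k)
  for (f in seq_len(inner_k)) {
    tr_spans <- do.call(rbind, inner[-f])
    train_sets[[f]] <- list(
      fm = build_training_set(compset, events, fcfg, tr_spans),
      test_spans = inner[[f]],
      test_events = events_in_spans(events, inner[[f]]))
  }
  for (li in seq_along(lambda_grid)) {
    n_tp <- 0L; n_fp <- 0L; n_ev <- 0L; n_det <- 0L
    for (f in seq_len(inner_k)) {
      ts <- train_sets[[f]]
      model <- rlda_fit(ts$fm$X, ts$fm$y, lambda_grid[li])
      det <- detect_over_spans(compset, model, fcfg, dcfg, ts$test_spans)
      m <- match_detections(det$times, ts$test_events, tau)
      n_tp <- n_tp + m$n_tp; n_fp <- n_fp + m$n_fp
      n_ev <- n_ev + m$n_events; n_det <- n_det + m$n_det
    }
    scores[li] <- n_tp / max(1L, n_ev) - n_fp / max(1L, n_det)
  }
  best <- lambda_grid[which.max(scores)]   # which.max takes the first maximum
  attr(best, "scores") <- data.frame(lambda = lambda_grid, score = scores)
  best
}

run_cv_compset <- function(compset, events, fcfg, dcfg, k = 10L,
                           lambda = NULL, lambda_grid = LAMBDA_GRID,
                           inner_k = 10L, inner_tau = 0.5,
                           taus = seq(0.125, 0.75, by = 0.125)) {
  T_s <- compset$n_eval / compset$eval_rate
  plan <- blocked_folds(T_s, k = k, t0 = compset$t0,
                        eval_rate = compset$eval_rate)
  p_session <- numeric(compset$n_eval)
  lambdas <- numeric(k)
  for (f in seq_len(k)) {
    tr_spans <- fold_spans(plan, exclude = f)
    if (length(events_in_spans(events, tr_spans)) == 0L)
      stop("fold ", f, " leaves no events in its training set")
    lam <- if (!is.null(lambda)) lambda else
      select_lambda(compset, events, fcfg, dcfg, tr_spans,
                    lambda_grid = lambda_grid, inner_k = inner_k,
                    tau = inner_tau)
    fm <- build_training_set(compset, events, fcfg, tr_spans)
    model <- rlda_fit(fm$X, fm$y, as.numeric(lam))
    te_span <- matrix(c(plan$t_start[f], plan$t_end[f]), ncol = 2L)
    tr <- posterior_over_spans(compset, model, fcfg, te_span)
    p_session[tr$idx] <- tr$p
    lambdas[f] <- as.numeric(lam)
  }
  det <- detect(p_session, dcfg, t0 = compset$t0)
  rep_ <- eval_report(det, events, T_s, taus = taus,
                      refractory_s = dcfg$refractory_s,
                      dt = 1 / compset$eval_rate)
  structure(list(report = rep_, detections = det, posterior = p_session,
                 eval_rate = compset$eval_rate, t0 = compset$t0,
                 lambdas = lambdas, plan = plan),
            class = "CvResult")
}

#' Cross-validated event detection over a session
#'
#' Full pipeline: common average reference and per-channel normalization,
#' component extraction on the evaluation grid, blocked `k`-fold
#' cross-validation with per-fold training (and, unless `lambda` is fixed,
#' nested selection of the regularization weight on each training set),
#' posterior computation over each held-out fold, a single detection pass
#' over the pooled session posterior, and evaluation against the ground
#' truth.
#'
#' @param rec a [recording()].
#' @param events an [event_list()].
#' @param components list of [comp_lfc()] / [comp_band()] specifications
#'   (default LFC + 16-28 Hz + 56-128 Hz).
#' @param fcfg a [feature_config()].
#' @param dcfg a [detector_config()].
#' @param k number of outer folds (default 10).
#' @param lambda fixed regularization weight, or `NULL` (default) for nested
#'   selection from `lambda_grid`.
#' @param lambda_grid candidate weights for nested selection.
#' @param inner_k inner folds for nested selection (default 10).
#' @param inner_tau tolerance of the inner objective (default 0.5 s).
#' @param taus evaluation tolerances.
#' @param preprocess apply [common_average_reference()] and
#'   [normalize_channels()] first (default TRUE).
#' @return an object of class `CvResult`: `report` (an [eval_report()]),
#'   `detections`, the pooled 64 Hz `posterior` trace, per-fold `lambdas`
#'   and the fold `plan`.
#' @export
run_cv <- function(rec, events,
                   components = list(comp_lfc(), comp_band(16, 28),
                                     comp_band(56, 128)),
                   fcfg = feature_config(), dcfg = detector_config(),
                   k = 10L, lambda = NULL, lambda_grid = LAMBDA_GRID,
                   inner_k = 10L, inner_tau = 0.5,
                   taus = seq(0.125, 0.75, by = 0.125), preprocess = TRUE) {
  check_events_in_span(events, rec)
  if (preprocess) rec <- normalize_channels(common_average_reference(rec))
  compset <- extract_components(rec, components, eval_rate = dcfg$eval_rate)
  run_cv_compset(compset, events, fcfg, dcfg, k = k, lambda = lambda,
                 lambda_grid = lambda_grid, inner_k = inner_k,
                 inner_tau = inner_tau, taus = taus)
}

#' @export
print.CvResult <- function(x, ...) {
  cat(sprintf("CvResult: %d folds, lambda(s) %s\n", nrow(x$plan),
              paste(unique(x$lambdas), collapse = ", ")))
  print(x$report)
  invisible(x)
}

#' Frequency-band scan
#'
#' Runs cross-validated detection on every contiguous frequency band that
#' can be formed between consecutive edges of `band_edges` (each a multiple
#' of 4 Hz), scoring each band by `TPR - FPR` averaged over the given delays
#' and tolerances.
#'
#' @param rec a [recording()].
#' @param events an [event_list()].
#' @param band_edges increasing vector of band edges in Hz, multiples of 4
#'   within \[0, 128\] (default the full 4 Hz grid, 528 band pairs).
#' @param delays feature delays in seconds to average over (default
#'   -0.25, 0, +0.25).
#' @param taus tolerances to average over (default 0.125 to 0.75 by 0.125).
#' @param history_s signal history in seconds (default 1).
#' @param k outer folds (default 10).
#' @param lambda fixed regularization weight (default 0.1), or `NULL` for
#'   nested selection per band (slow).
#' @param dcfg a [detector_config()].
#' @param preprocess apply referencing/normalization first (default TRUE).
#' @return an object of class `BandScan`: `grid` (data frame `f_lo`, `f_hi`,
#'   `score`), `band_edges`, and `best` (the top-scoring row).
#' @export
band_scan <- function(rec, events, band_edges = seq(0, 128, by = 4),
                      delays = c(-0.25, 0, 0.25),
                      taus = seq(0.125, 0.75, by = 0.125),
                      history_s = 1, k = 10L, lambda = 0.1,
                      dcfg = detector_config(), preprocess = TRUE) {
  if (any(band_edges %% 4 != 0) || is.unsorted(band_edges, strictly = TRUE) ||
      min(band_edges) < 0 || max(band_edges) > 128)
    stop("band_edges must be strictly increasing multiples of 4 in [0, 128]")
  if (preprocess) rec <- normalize_channels(common_average_reference(rec))
  # cache all constituent 4 Hz bands once
  sub_lo <- seq(min(band_edges), max(band_edges) - 4, by = 4)
  cache <- extract_components(
    rec, lapply(sub_lo, function(l) comp_band(l, l + 4)),
    eval_rate = dcfg$eval_rate)
  make_compset <- function(f_lo, f_hi) {
    pick <- which(sub_lo >= f_lo & sub_lo <= f_hi - 4)
    acc <- cache$values[[pick[1L]]]
    for (pi in pick[-1L]) acc <- acc + cache$values[[pi]]
    out <- cache
    out$values <- list(acc / length(pick))
    out$components <- list(comp_band(f_lo, f_hi))
    out
  }
  rows <- list()
  for (i in seq_len(length(band_edges) - 1L)) {
    for (j in (i + 1L):length(band_edges)) {
      f_lo <- band_edges[i]; f_hi <- band_edges[j]
      cs <- make_compset(f_lo, f_hi)
      sc <- vapply(delays, function(d) {
        fcfg <- feature_config(delay = d, history_s = history_s)
        res <- run_cv_compset(cs, events, fcfg, dcfg, k = k, lambda = lambda,
                              taus = taus)
        mean(res$report$by_tau$tpr - res$report$by_tau$fpr)
      }, 0)
      rows[[length(rows) + 1L]] <- data.frame(f_lo = f_lo, f_hi = f_hi,
                                              score = mean(sc))
    }
  }
  grid <- do.call(rbind, rows)
  structure(list(grid = grid, band_edges = band_edges,
                 best = grid[which.max(grid$score), ]),
            class = "BandScan")
}

#' @export
print.BandScan <- function(x, ...) {
  cat(sprintf("BandScan: %d band pairs; best %g-%g Hz (TPR-FPR = %.3f)\n",
              nrow(x$grid), x$best$f_lo, x$best$f_hi, x$best$score))
  invisible(x)
}
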