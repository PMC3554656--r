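# Shared fixtures and independent brute-force oracles.

# small synthetic session (defaults keep unit tests fast)
make_session <- function(seed = 1, duration_s = 60, n_channels = 2, ...) {
  cfg <- synth_config(n_channels = n_channels, duration_s = duration_s, ...)
  generate_session(cfg, seed)
}

# exhaustive application of the detection rule to a full posterior trace:
# open the first admissible above-threshold candidate, repeatedly move to
# the first strictly higher value within the next t_advance steps, emit
# when none follows, then skip the refractory span.
oracle_detect <- function(p, threshold = 0.95, la = 3L, refr_steps = 96L,
                          eval_rate = 64, t0 = 0) {
  n <- length(p)
  det <- integer()
  i <- 1L
  allowed_from <- 1L
  while (i <= n) {
    if (i < allowed_from || p[i] <= threshold) { i <- i + 1L; next }
    c0 <- i
    repeat {
      win <- seq(c0 + 1L, min(n, c0 + la))
      if (length(win) == 0L || c0 + 1L > n) break
      higher <- win[p[win] > p[c0]]
      if (length(higher) == 0L) break
      c0 <- higher[1L]
    }
    det <- c(det, c0)
    allowed_from <- c0 + refr_steps
    i <- max(c0 + 1L, allowed_from)
  }
  list(times = t0 + (det - 1L) / eval_rate, idx = det)
}

# brute-force optimal one-to-one matching: maximize the number of
# event-detection pairs within tau over all assignments (instances <= 6x6)
oracle_match_tp <- function(det, ev, tau) {
  nd <- length(det); ne <- length(ev)
  if (nd == 0L || ne == 0L) return(0L)
  ok <- abs(outer(ev, det, "-")) <= tau
  best <- 0L
  rec <- function(e, used) {
    if (e > ne) return(0L)
    most <- rec(e + 1L, used)             # leave event e unmatched
    for (d in which(ok[e, ] & !used)) {
      used2 <- used; used2[d] <- TRUE
      most <- max(most, 1L + rec(e + 1L, used2))
    }
    most
  }
  rec(1L, rep(FALSE, nd))
}

# independent Monte-Carlo of the refractory renewal detector: shifted
# exponential intervals at the event rate, scored against fixed events
oracle_random_predictor_mc <- function(events, T_s, tau, refractory_s = 1.5,
                                       dt = 1 / 64, n_sim = 500L) {
  ev <- round(as.numeric(events) / dt) * dt   # decisions in steps of dt
  mean_iv <- T_s / length(ev)
  tprs <- numeric(n_sim); fprs <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    t <- -10 * mean_iv
    det <- numeric()
    while (t < T_s) {
      t <- t + refractory_s + rexp(1L, 1 / (mean_iv - refractory_s))
      if (t >= 0 && t <= T_s) det <- c(det, round(t / dt) * dt)
    }
    # nearest-detection matching, closest-event rule, written out directly
    n_tp <- 0L
    if (length(det)) {
      claimed <- sapply(ev, function(e) {
        d <- abs(det - e)
        if (min(d) <= tau) which.min(d) else NA_integer_
      })
      for (d in unique(stats::na.omit(claimed))) {
        n_tp <- n_tp + 1L   # one event per claimed detection
      }
    }
    tprs[s] <- n_tp / length(ev)
    fprs[s] <- if (length(det)) (length(det) - n_tp) / length(det) else 0
  }
  list(tpr = mean(tprs), fpr = mean(fprs),
       tpr_sd = sd(tprs), fpr_sd = sd(fprs),
       tpr_se = sd(tprs) / sqrt(n_sim), fpr_se = sd(fprs) / sqrt(n_sim))
}

# hand-built ComponentSet whose values are fully controlled
make_compset <- function(values_list, eval_rate = 64, t0 = 0,
                         valid_from = 1L) {
  structure(list(values = values_list,
                 components = rep(list(structure(list(kind = "LFC"),
                                                 class = "comp_spec")),
                                  length(values_list)),
                 eval_rate = eval_rate, t0 = t0,
                 valid_from = as.integer(valid_from),
                 n_eval = ncol(values_list[[1L]]),
                 n_channels = nrow(values_list[[1L]]),
                 channel_ids = paste0("ch", seq_len(nrow(values_list[[1L]])))),
            class = "ComponentSet")
}
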