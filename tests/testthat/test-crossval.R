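test_that("blocked folds partition the session into equal contiguous periods", {
  plan <- blocked_folds(100, k = 10)
  expect_equal(nrow(plan), 10)
  expect_equal(plan$t_end - plan$t_start, rep(10, 10))
  expect_equal(plan$t_start[-1], plan$t_end[-10])   # contiguous
  expect_equal(plan$t_start[1], 0)
  expect_equal(plan$t_end[10], 100)

  expect_error(blocked_folds(100, k = 1), "k = 1")
  expect_error(blocked_folds(0.1, k = 10), "too short")

  # non-divisible lengths still partition exactly (within one step)
  plan2 <- blocked_folds(99.7, k = 7)
  expect_equal(plan2$t_start[-1], plan2$t_end[-7])
  widths <- plan2$t_end - plan2$t_start
  expect_lt(max(widths) - min(widths), 2 / 64 + 1e-12)
})

test_that("lambda selection returns a grid member and breaks ties low", {
  ss <- make_session(seed = 71, duration_s = 120, n_channels = 3)
  rec <- normalize_channels(common_average_reference(ss$recording))
  cs <- extract_components(rec, list(comp_lfc(), comp_band(56, 128)))
  fcfg <- feature_config()
  dcfg <- detector_config()
  spans <- matrix(c(0, 120), 1)
  grid <- c(0.01, 0.1, 0.5)
  lam <- select_lambda(cs, ss$events, fcfg, dcfg, spans,
                       lambda_grid = grid, inner_k = 5)
  expect_true(as.numeric(lam) %in% grid)
  sc <- attr(lam, "scores")
  expect_equal(sc$lambda, grid)
  # reported winner is the first maximum (ties break to smaller lambda)
  expect_equal(as.numeric(lam), grid[which.max(sc$score)])

  # degenerate inner folds are reported with event counts
  few <- event_list(c(50, 51))
  expect_error(select_lambda(cs, few, fcfg, dcfg, matrix(c(40, 60), 1),
                             lambda_grid = grid, inner_k = 5),
               "degenerate inner folds")
})

test_that("cross-validated detection is deterministic", {
  ss <- make_session(seed = 72, duration_s = 90, n_channels = 2)
  r1 <- run_cv(ss$recording, ss$events, k = 3, lambda = 0.1,
               components = list(comp_lfc(), comp_band(56, 128)))
  r2 <- run_cv(ss$recording, ss$events, k = 3, lambda = 0.1,
               components = list(comp_lfc(), comp_band(56, 128)))
  expect_identical(r1$report$by_tau, r2$report$by_tau)
  expect_identical(r1$detections$times, r2$detections$times)
})

test_that("channel order does not change detection results", {
  ss <- make_session(seed = 73, duration_s = 90, n_channels = 3)
  perm <- c(3, 1, 2)
  rec_p <- recording(ss$recording$samples[perm, ], ss$recording$rate,
                     ss$recording$channel_ids[perm])
  args <- list(events = ss$events, k = 3, lambda = 0.1,
               components = list(comp_lfc(), comp_band(56, 128)))
  r1 <- do.call(run_cv, c(list(ss$recording), args))
  r2 <- do.call(run_cv, c(list(rec_p), args))
  expect_equal(r1$detections$times, r2$detections$times, tolerance = 1e-9)
  expect_equal(r1$report$by_tau$tpr, r2$report$by_tau$tpr)
  expect_equal(r1$report$by_tau$fpr, r2$report$by_tau$fpr)
})

test_that("training rows never touch the held-out fold", {
  ss <- make_session(seed = 74, duration_s = 120, n_channels = 2)
  rec <- normalize_channels(common_average_reference(ss$recording))
  cs <- extract_components(rec, list(comp_lfc()))
  fcfg <- feature_config(delay = 0.25, history_s = 1)
  plan <- blocked_folds(120, k = 4)
  for (f in c(1, 2, 4)) {
    spans <- graspdetect:::fold_spans(plan, exclude = f)
    fm <- build_training_set(cs, ss$events, fcfg, spans)
    lo <- fm$t + fcfg$delay - fcfg$history_s
    hi <- fm$t + fcfg$delay
    inside <- (hi > plan$t_start[f] + 1e-9) & (lo < plan$t_end[f] - 1e-9)
    expect_false(any(inside))
  }
})

test_that("a single-pair band scan matches running CV on that band", {
  ss <- make_session(seed = 75, duration_s = 90, n_channels = 2)
  sc <- band_scan(ss$recording, ss$events, band_edges = c(56, 128),
                  delays = 0, taus = 0.5, history_s = 1, k = 3, lambda = 0.1)
  expect_equal(nrow(sc$grid), 1)
  direct <- run_cv(ss$recording, ss$events,
                   components = list(comp_band(56, 128)),
                   fcfg = feature_config(delay = 0, history_s = 1),
                   k = 3, lambda = 0.1, taus = 0.5)
  expect_equal(sc$grid$score,
               direct$report$by_tau$tpr - direct$report$by_tau$fpr,
               tolerance = 1e-9)
})
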