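test_that("feature-vector length follows the count formula", {
  # 17 samples per channel per component for 1 s of history at 16 /s
  cs1 <- make_compset(list(matrix(rnorm(640), 1)))
  expect_equal(n_features(cs1, feature_config(history_s = 1)), 17L)
  expect_equal(n_features(cs1, feature_config(history_s = 0)), 1L)

  # 3 channels x 2 components x (16 * 1.25 + 1) = 126
  cs <- make_compset(list(matrix(rnorm(3 * 640), 3), matrix(rnorm(3 * 640), 3)))
  expect_equal(n_features(cs, feature_config(history_s = 1.25)), 126L)
  expect_length(feature_vector(cs, 5, feature_config(history_s = 1.25)), 126L)
})

test_that("feature vectors pick the documented sample times", {
  # values equal to their evaluation index makes indexing transparent
  v <- matrix(seq_len(640), 1)
  cs <- make_compset(list(v))
  cfg <- feature_config(delay = 0, history_s = 0.5)   # 9 samples
  x <- feature_vector(cs, t = 5, cfg)                 # index 321
  expect_equal(x, 321 - 4 * (0:8))

  # negative delay: all samples precede the reference time
  cfg2 <- feature_config(delay = -0.25, history_s = 0.5)
  x2 <- feature_vector(cs, t = 5, cfg2)
  expect_equal(x2, 321 - 16 - 4 * (0:8))
  expect_true(all(x2 < 321))

  # positive delay reaches past the reference time
  cfg3 <- feature_config(delay = 0.25, history_s = 0.5)
  expect_equal(feature_vector(cs, t = 5, cfg3)[1], 321 + 16)

  expect_error(feature_vector(cs, t = 0.1, cfg), "history")
})

test_that("channel reordering permutes feature blocks predictably", {
  set.seed(31)
  v <- matrix(rnorm(3 * 640), 3)
  cfg <- feature_config(history_s = 0.5)
  x <- feature_vector(make_compset(list(v)), 6, cfg)
  xp <- feature_vector(make_compset(list(v[c(3, 1, 2), ])), 6, cfg)
  blk <- function(x, i) x[((i - 1) * 9 + 1):(i * 9)]
  expect_equal(blk(xp, 1), blk(x, 3))
  expect_equal(blk(xp, 2), blk(x, 1))
  expect_equal(blk(xp, 3), blk(x, 2))
})

test_that("features are invariant to data after t + delay", {
  set.seed(32)
  v <- matrix(rnorm(640), 1)
  cfg <- feature_config(delay = -0.25, history_s = 1)
  cs1 <- make_compset(list(v))
  v2 <- v
  cut <- 321 - 16   # newest sample index at t = 5 with delay -0.25
  v2[, (cut + 1):640] <- 999
  cs2 <- make_compset(list(v2))
  expect_equal(feature_vector(cs1, 5, cfg), feature_vector(cs2, 5, cfg))
})

test_that("training sets have the exact 16:1 class ratio and exclusion zone", {
  ss <- make_session(seed = 33, duration_s = 90, n_channels = 2)
  rec <- normalize_channels(common_average_reference(ss$recording))
  cs <- extract_components(rec, list(comp_lfc()))
  cfg <- feature_config()
  fm <- build_training_set(cs, ss$events, cfg, c(0, 90))
  n_ev <- sum(fm$y == "event")
  expect_gt(n_ev, 0)
  expect_equal(sum(fm$y == "nonevent"), 16L * n_ev)

  ne_t <- fm$t[fm$y == "nonevent"]
  dmin <- vapply(ne_t, function(t) min(abs(t - as.numeric(ss$events))), 0)
  expect_true(all(dmin >= 0.3 - 1e-9))
})

test_that("event rows sit at event times; quota errors are informative", {
  set.seed(34)
  v <- matrix(rnorm(2 * 64 * 60), 2)
  cs <- make_compset(list(v))
  cfg <- feature_config(delay = 0, history_s = 1)
  ev <- event_list(c(5, 10))
  fm <- build_training_set(cs, ev, cfg, c(0, 60))
  expect_equal(fm$t[fm$y == "event"], c(5, 10))
  expect_equal(sum(fm$y == "nonevent"), 32L)
  ne_t <- fm$t[fm$y == "nonevent"]
  expect_true(all(vapply(ne_t, function(t)
    min(abs(t - c(5, 10))), 0) >= 0.3 - 1e-9))

  # a span too short for the 16x quota reports the achievable count
  expect_error(build_training_set(cs, event_list(5), cfg, c(4, 5.5)),
               "eligible")
  expect_error(build_training_set(cs, event_list(100), cfg, c(0, 60)),
               "usable events")
})
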