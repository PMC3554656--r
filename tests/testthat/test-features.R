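test_that("causal Savitzky-Golay reproduces constants and ramps", {
  x <- rep(3.7, 500)
  y <- savgol_causal(x, 256)
  expect_equal(as.numeric(y), x, tolerance = 1e-9)

  tt <- seq_len(500) / 256
  ramp <- 2.5 * tt - 1
  y2 <- savgol_causal(ramp, 256)
  expect_equal(as.numeric(y2), ramp, tolerance = 1e-8)

  expect_error(savgol_causal(rnorm(100), rate = 8, window_s = 0.25),
               "order \\+ 1")
  expect_equal(attr(savgol_causal(rnorm(300), 256), "warmup"), 63L)
})

test_that("causal filters never use future samples", {
  set.seed(21)
  x <- rnorm(1000)
  y <- savgol_causal(x, 256)
  k <- 400
  y2 <- savgol_causal(x[1:k], 256)
  expect_equal(as.numeric(y2), as.numeric(y)[1:k])

  e <- band_amplitude(x, 256, 16, 20)
  e2 <- band_amplitude(x[1:k], 256, 16, 20)
  expect_equal(as.numeric(e2), as.numeric(e)[1:k])
})

test_that("the smoother's magnitude response decays above cutoff", {
  # the causal endpoint fit has a rippled stopband, so low-pass behaviour
  # is checked on the coarse scale: binned response maxima fall steadily
  h <- savgol_causal_coeffs(2, 64)
  nfft <- 2^14
  H <- Mod(fft(c(rev(h), rep(0, nfft - 64))))
  f <- (0:(nfft - 1)) * 256 / nfft
  cutoff <- f[which(H[1:(nfft / 2)] < H[1] / sqrt(2))[1]]
  bins <- seq(cutoff, 3 * cutoff, length.out = 5)
  mx <- vapply(1:4, function(b) max(H[f >= bins[b] & f < bins[b + 1]]), 0)
  expect_true(all(diff(mx) < 0))
  expect_lt(mx[4], H[1] / 2)
})

test_that("band amplitude tracks a sinusoid's rectified mean", {
  rate <- 256
  tt <- seq_len(20 * rate) / rate
  for (band in list(c(16, 20), c(56, 60))) {
    f0 <- mean(band)
    A <- 1.8
    env <- band_amplitude(A * sin(2 * pi * f0 * tt), rate, band[1], band[2])
    steady <- as.numeric(env)[(5 * rate):(20 * rate)]
    expect_lt(abs(mean(steady) - 2 * A / pi) / (2 * A / pi), 0.15)
  }
})

test_that("out-of-band sinusoids are attenuated by the stopband spec", {
  rate <- 256
  tt <- seq_len(20 * rate) / rate
  inband <- band_amplitude(sin(2 * pi * 18 * tt), rate, 16, 20)
  out <- band_amplitude(sin(2 * pi * 80 * tt), rate, 16, 20)  # 2 octaves up
  steady <- (5 * rate):(20 * rate)
  ratio <- mean(as.numeric(out)[steady]) / mean(as.numeric(inband)[steady])
  expect_lt(ratio, 10^(-50 / 20) * 2)
})

test_that("zero input yields a zero envelope", {
  env <- band_amplitude(numeric(512), 256, 16, 20)
  expect_equal(as.numeric(env), numeric(512))
})

test_that("band amplitude agrees with an acausal analytic envelope", {
  # slowly amplitude-modulated sinusoid; oracle = |analytic signal| of the
  # ideal band content, compared after aligning for the causal group delay
  rate <- 256
  tt <- seq_len(30 * rate) / rate
  am <- 1 + 0.5 * sin(2 * pi * 0.3 * tt)
  x <- am * sin(2 * pi * 22 * tt)
  env <- as.numeric(band_amplitude(x, rate, 20, 24)) * pi / 2  # undo 2A/pi
  oracle <- am                                 # true instantaneous amplitude
  steady <- (5 * rate):(28 * rate)
  lags <- 0:64
  cors <- vapply(lags, function(L)
    cor(env[steady], oracle[steady - L]), 0)
  best <- lags[which.max(cors)]
  expect_gt(max(cors), 0.97)
  rel <- abs(env[steady] - oracle[steady - best]) / oracle[steady - best]
  expect_lt(mean(rel), 0.1)
})

test_that("band edges above Nyquist and sub-256 Hz stacks are rejected", {
  expect_error(band_amplitude(rnorm(100), 256, 100, 130), "Nyquist")
  expect_error(band_amplitude(rnorm(100), 256, -4, 8), "f_lo")
  rec <- recording(matrix(rnorm(1000), 1), 128)
  expect_error(band_stack(rec), "256")
})

test_that("band stack is normalized to unit time-average per band", {
  set.seed(23)
  rec <- recording(matrix(rnorm(2 * 2048), 2), 256)
  bs <- band_stack(rec)
  expect_equal(dim(bs$values), c(2L, 32L, 2048L))
  means <- apply(bs$values, c(1, 2), mean)
  expect_lt(max(abs(means - 1)), 1e-9)
})

test_that("an injected 60 Hz burst raises the 56-60 Hz band near its time", {
  set.seed(24)
  rate <- 256
  n <- 20 * rate
  x <- rnorm(n)
  t_star <- 12
  idx <- round((t_star - 0.25) * rate):round((t_star + 0.25) * rate)
  x[idx] <- x[idx] + 4 * sin(2 * pi * 60 * seq_along(idx) / rate)
  bs <- band_stack(recording(matrix(x, 1), rate))
  b <- bs$values[1, 15, ]                      # 56-60 Hz band
  around <- round((t_star) * rate):round((t_star + 0.5) * rate)
  expect_gt(mean(b[around]), 1.5)
})

test_that("averaging bands takes the unweighted mean of constituents", {
  set.seed(25)
  rec <- recording(matrix(rnorm(1024), 1), 256)
  bs <- band_stack(rec)
  beta <- average_bands(bs, 16, 28)
  manual <- (bs$values[1, 5, ] + bs$values[1, 6, ] + bs$values[1, 7, ]) / 3
  expect_equal(beta$values[1, ], manual)
  expect_equal(beta$band, c(16, 28))

  single <- average_bands(bs, 56, 60)
  expect_equal(single$values[1, ], bs$values[1, 15, ])

  gamma <- average_bands(bs, 56, 128)
  manual_g <- colMeans(bs$values[1, 15:32, ])
  expect_equal(gamma$values[1, ], manual_g)

  expect_error(average_bands(bs, 14, 28), "multiples of 4")
})
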