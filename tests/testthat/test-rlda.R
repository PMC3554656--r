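make_two_class <- function(seed = 1, n1 = 30, n2 = 60, N = 5) {
  set.seed(seed)
  mu1 <- rnorm(N); mu2 <- rnorm(N)
  A <- matrix(rnorm(N * N), N)
  X <- rbind(matrix(rnorm(n1 * N), n1) %*% A + rep(mu1, each = n1),
             matrix(rnorm(n2 * N), n2) %*% A + rep(mu2, each = n2))
  list(X = X, y = factor(rep(c("event", "nonevent"), c(n1, n2)),
                         levels = c("event", "nonevent")))
}

test_that("regularization interpolates between pooled and spherical", {
  d <- make_two_class(41)
  m0 <- rlda_fit(d$X, d$y, 0)
  expect_equal(m0$sigma_reg, m0$sigma)

  m1 <- rlda_fit(d$X, d$y, 1)
  N <- ncol(d$X)
  expect_equal(m1$sigma_reg, diag(sum(diag(m1$sigma)) / N, N))

  for (lam in c(0.001, 0.1, 0.5))
    expect_equal(sum(diag(rlda_fit(d$X, d$y, lam)$sigma_reg)),
                 sum(diag(m0$sigma)))

  expect_error(rlda_fit(d$X, d$y, -0.1), "lambda")
  expect_error(rlda_fit(d$X, d$y, 1.5), "lambda")
  expect_error(rlda_fit(d$X, factor(rep("event", nrow(d$X)),
                                    levels = c("event", "nonevent")), 0.1),
               "0 samples")
})

test_that("the pooled covariance uses the maximum-likelihood normalization", {
  d <- make_two_class(42, n1 = 10, n2 = 20, N = 3)
  m <- rlda_fit(d$X, d$y, 0)
  X1 <- d$X[d$y == "event", ]; X2 <- d$X[d$y == "nonevent", ]
  manual <- (crossprod(scale(X1, scale = FALSE)) +
               crossprod(scale(X2, scale = FALSE))) / nrow(d$X)
  expect_equal(m$sigma, manual, ignore_attr = TRUE)
  expect_equal(m$priors, c(10, 20) / 30)
})

test_that("posterior matches a brute-force Gaussian-Bayes oracle", {
  for (seed in 1:5) {
    d <- make_two_class(seed, n1 = 40, n2 = 70, N = 5)
    for (lam in c(0.01, 0.3, 1)) {
      m <- rlda_fit(d$X, d$y, lam)
      Sinv <- solve(m$sigma_reg)
      logdet <- as.numeric(determinant(m$sigma_reg)$modulus)
      dens <- function(x, mu) {
        q <- drop(t(x - mu) %*% Sinv %*% (x - mu))
        exp(-0.5 * q - 0.5 * logdet - length(x) / 2 * log(2 * pi))
      }
      set.seed(seed + 100)
      for (r in 1:8) {
        x <- rnorm(5, sd = 2)
        p1 <- dens(x, m$mu[1, ]) * m$priors[1]
        p2 <- dens(x, m$mu[2, ]) * m$priors[2]
        expect_equal(rlda_posterior(m, x), p1 / (p1 + p2), tolerance = 1e-10)
      }
    }
  }
})

test_that("posterior is 0.5 at the midpoint under equal priors", {
  d <- make_two_class(43, n1 = 50, n2 = 50)
  m <- rlda_fit(d$X, d$y, 0.2)
  expect_equal(rlda_posterior(m, (m$mu[1, ] + m$mu[2, ]) / 2), 0.5)
})

test_that("posterior increases along the discriminant direction", {
  d <- make_two_class(44)
  m <- rlda_fit(d$X, d$y, 0.1)
  alphas <- seq(-0.5, 1.5, length.out = 30)
  p <- vapply(alphas, function(a)
    rlda_posterior(m, m$mu[2, ] + a * (m$mu[1, ] - m$mu[2, ])), 0)
  expect_true(all(diff(p) > 0))
})

test_that("log posterior odds is affine in the features", {
  d <- make_two_class(45)
  m <- rlda_fit(d$X, d$y, 0.2)
  set.seed(46)
  Xs <- matrix(rnorm(40 * 5), 40)
  p <- rlda_posterior(m, Xs)
  lo <- qlogis(p)
  fit <- lm(lo ~ Xs)
  expect_lt(max(abs(residuals(fit))), 1e-8)
})

test_that("classical LDA is affine-invariant; regularized is not", {
  d <- make_two_class(47)
  set.seed(48)
  A <- matrix(rnorm(25), 5) + diag(5)
  shift <- rnorm(5)
  X2 <- d$X %*% A + rep(shift, each = nrow(d$X))
  xs <- matrix(rnorm(10 * 5), 10)
  xs2 <- xs %*% A + rep(shift, each = 10)

  m0 <- rlda_fit(d$X, d$y, 0); m0t <- rlda_fit(X2, d$y, 0)
  expect_equal(rlda_posterior(m0, xs), rlda_posterior(m0t, xs2),
               tolerance = 1e-6)

  mr <- rlda_fit(d$X, d$y, 0.5); mrt <- rlda_fit(X2, d$y, 0.5)
  expect_gt(max(abs(rlda_posterior(mr, xs) - rlda_posterior(mrt, xs2))),
            1e-4)
})

test_that("fitted parameters recover the truth on model-generated data", {
  set.seed(49)
  N <- 4; n <- 1e4
  mu1 <- c(1, -1, 0.5, 2); mu2 <- c(-0.5, 0.3, 1, -1)
  A <- matrix(rnorm(N * N, sd = 0.4), N) + diag(N)
  n1 <- round(n / 17); n2 <- n - n1
  X <- rbind(matrix(rnorm(n1 * N), n1) %*% A + rep(mu1, each = n1),
             matrix(rnorm(n2 * N), n2) %*% A + rep(mu2, each = n2))
  y <- factor(rep(c("event", "nonevent"), c(n1, n2)),
              levels = c("event", "nonevent"))
  m <- rlda_fit(X, y, 0)
  expect_lt(max(abs(m$mu[1, ] - mu1)), 0.05 * max(abs(mu1)) + 0.1)
  expect_lt(max(abs(m$mu[2, ] - mu2)), 0.05 * max(abs(mu2)) + 0.1)
  expect_lt(abs(m$priors[1] - n1 / n), 0.05)
  expect_lt(max(abs(m$sigma - crossprod(A))), 0.15)
})

test_that("models survive a serialization round trip", {
  d <- make_two_class(50)
  m <- rlda_fit(d$X, d$y, 0.1)
  f <- tempfile(fileext = ".json")
  write_rlda(m, f)
  back <- read_rlda(f)
  set.seed(51)
  xs <- matrix(rnorm(20 * 5), 20)
  expect_equal(rlda_posterior(back, xs), rlda_posterior(m, xs),
               tolerance = 1e-12)
  expect_error(rlda_posterior(m, rnorm(4)), "entries")
})
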