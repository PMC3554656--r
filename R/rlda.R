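# Two-class regularized linear discriminant analysis (RLDA).

#' Fit a regularized linear discriminant model
#'
#' Two-class Gaussian model with shared covariance. Class priors are the
#' training-class frequencies, class means the sample means, and the common
#' covariance the pooled (within-class) maximum-likelihood estimate (1/n
#' normalization). The covariance is shrunk towards a scaled identity,
#' \deqn{\Sigma_{reg} = (1-\lambda)\,\Sigma + \lambda\,\frac{tr(\Sigma)}{N} I,}
#' which preserves the trace; \eqn{\lambda = 0} is classical LDA,
#' \eqn{\lambda = 1} assumes spherical class distributions.
#'
#' @param X numeric matrix, samples x features.
#' @param y two-level factor (or vector coercible to one); the first level is
#'   the event class.
#' @param lambda regularization weight in \[0, 1\].
#' @return an object of class `RldaModel` with fields `mu` (2 x N), `sigma`,
#'   `sigma_reg`, `lambda`, `priors`, `n_features`, and the affine
#'   discriminant (`w`, `b`) with `log_odds(x) = w'x + b` for the event
#'   class.
#' @export
rlda_fit <- function(X, y, lambda) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("`y` must have exactly two levels")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop("`lambda` must be a single value in [0, 1]")
  n_by <- table(y)
  if (any(n_by == 0L)) stop("class with 0 samples: ", names(n_by)[n_by == 0L])
  n <- nrow(X); N <- ncol(X)
  priors <- as.numeric(n_by) / n
  mu <- rbind(colMeans(X[y == levels(y)[1L], , drop = FALSE]),
              colMeans(X[y == levels(y)[2L], , drop = FALSE]))
  Xc <- X - mu[as.integer(y), , drop = FALSE]
  sigma <- crossprod(Xc) / n
  sigma_reg <- (1 - lambda) * sigma
  diag(sigma_reg) <- diag(sigma_reg) + lambda * (sum(diag(sigma)) / N)
  R <- tryCatch(chol(sigma_reg), error = function(e)
    stop("regularized covariance is not positive definite (lambda = ",
         lambda, "); increase lambda or training size"))
  # affine log-odds: w'x + b
  dmu <- mu[1L, ] - mu[2L, ]
  w <- backsolve(R, backsolve(R, dmu, transpose = TRUE))
  b <- -0.5 * sum(w * (mu[1L, ] + mu[2L, ])) + log(priors[1L] / priors[2L])
  structure(list(mu = mu, sigma = sigma, sigma_reg = sigma_reg,
                 lambda = lambda, priors = priors, n_features = N,
                 classes = levels(y), chol = R, w = w, b = b),
            class = "RldaModel")
}

#' @export
print.RldaModel <- function(x, ...) {
  cat(sprintf("RldaModel: %d features, lambda = %g, priors = %.3f/%.3f (%s/%s)\n",
              x$n_features, x$lambda, x$priors[1], x$priors[2],
              x$classes[1], x$classes[2]))
  invisible(x)
}

#' Posterior event probability
#'
#' `P(event | x)` under the shared-covariance Gaussian model, via Bayes'
#' rule in the log domain: the log posterior odds is the affine discriminant
#' `w'x + b`, mapped through the logistic function, so the computation is
#' stable for arbitrarily large Mahalanobis distances.
#'
#' @param model an [rlda_fit()] result.
#' @param x numeric feature vector, or a samples x features matrix.
#' @return posterior probability (vector for matrix input), in \[0, 1\];
#'   complements `P(non-event | x)` exactly.
#' @export
rlda_posterior <- function(model, x) {
  if (is.null(dim(x))) {
    if (length(x) != model$n_features)
      stop("feature vector has ", length(x), " entries, model expects ",
           model$n_features)
    x <- matrix(x, nrow = 1L)
  } else if (ncol(x) != model$n_features) {
    stop("feature matrix has ", ncol(x), " columns, model expects ",
         model$n_features)
  }
  stats::plogis(drop(x %*% model$w) + model$b)
}

#' Serialize / restore an RLDA model
#'
#' Single portable JSON file holding means, covariance, lambda and priors.
#'
#' @param model an `RldaModel`.
#' @param path file path.
#' @export
write_rlda <- function(model, path) {
  jsonlite::write_json(
    list(mu = model$mu, sigma = model$sigma, lambda = model$lambda,
         priors = model$priors, classes = model$classes),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_rlda
#' @return `read_rlda` returns the restored `RldaModel` (refit from the
#'   stored statistics).
#' @export
read_rlda <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  mu <- as.matrix(d$mu); sigma <- as.matrix(d$sigma)
  N <- ncol(sigma)
  sigma_reg <- (1 - d$lambda) * sigma
  diag(sigma_reg) <- diag(sigma_reg) + d$lambda * (sum(diag(sigma)) / N)
  R <- chol(sigma_reg)
  dmu <- mu[1L, ] - mu[2L, ]
  w <- backsolve(R, backsolve(R, dmu, transpose = TRUE))
  b <- -0.5 * sum(w * (mu[1L, ] + mu[2L, ])) + log(d$priors[1L] / d$priors[2L])
  structure(list(mu = mu, sigma = sigma, sigma_reg = sigma_reg,
                 lambda = d$lambda, priors = d$priors, n_features = N,
                 classes = d$classes, chol = R, w = w, b = b),
            class = "RldaModel")
}
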