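#' Numerically stable sigmoid
#'
#' f(z) = 1 / (1 + exp(-z)), evaluated without overflow for large |z|.
#'
#' @param z numeric vector of finite values.
#' @return values in (0, 1) (reaching 0/1 only by floating-point underflow).
#' @examples
#' sigmoid(c(-710, 0, 710))
#' @export
sigmoid <- function(z) {
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out
}

.checkXy <- function(X, y = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("X must be finite")
  if (!is.null(y)) {
    if (length(y) != nrow(X)) stop("X and y lengths differ")
    if (!all(y %in% c(0, 1))) stop("y must be 0/1")
  }
  X
}

.linearScore <- function(model, X) {
  if (ncol(X) != length(model@weights))
    stop("feature dimension does not match the model")
  drop(model@bias + X %*% model@weights)
}

#' Bernoulli log-likelihood of a logistic model
#'
#' Sum over samples of y log f(z) + (1 - y) log(1 - f(z)), the log of the
#' likelihood product; fitted probabilities are clipped to
#' \[1e-12, 1 - 1e-12\] before the logs.
#'
#' @param model a [LogRegModel-class].
#' @param X n x d feature matrix.
#' @param y 0/1 labels of length n.
#' @return a single numeric (<= 0).
#' @export
logLikelihood <- function(model, X, y) {
  X <- .checkXy(X, y)
  p <- sigmoid(.linearScore(model, X))
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Gradient of the log-likelihood
#'
#' Component j is the sum over samples of (y_i - f(z_i)) x_ij, with x_i0 = 1
#' for the bias; the direction of steepest log-likelihood ascent.
#'
#' @inheritParams logLikelihood
#' @return numeric vector of length d + 1: bias component first.
#' @export
logregGradient <- function(model, X, y) {
  X <- .checkXy(X, y)
  r <- y - sigmoid(.linearScore(model, X))
  c(sum(r), drop(crossprod(X, r)))
}

#' Fit a logistic model by full-batch gradient ascent
#'
#' The textbook loop: initialize the weights to small seeded random values,
#' compute the linear scores and fitted probabilities, evaluate the error
#' (negative mean log-likelihood), take a gradient step, and repeat until the
#' error change falls below `tol` or `maxIters` is reached. The update uses
#' the mean gradient (sum gradient divided by n) so `alpha` is comparable
#' across sample sizes.
#'
#' @param X n x d feature matrix (finite).
#' @param y 0/1 labels.
#' @param alpha learning rate; default 0.1, tuned for features on a \[0, 1\]
#'   or unit scale.
#' @param maxIters iteration budget; default 500.
#' @param tol stop when |change in mean negative log-likelihood| < tol;
#'   default 1e-8.
#' @param seed seed for the uniform \[-0.01, 0.01\] weight initialization.
#' @return A fitted [LogRegModel-class].
#' @examples
#' X <- matrix(rnorm(200), 100, 2)
#' y <- rbinom(100, 1, sigmoid(1 + X %*% c(2, -2)))
#' fitLogReg(X, y, maxIters = 200)
#' @export
fitLogReg <- function(X, y, alpha = 0.1, maxIters = 500L, tol = 1e-8,
                      seed = 1L) {
  X <- .checkXy(X, y)
  n <- nrow(X)
  if (n < 1L) stop("need at least one sample")
  set.seed(seed)
  w <- stats::runif(ncol(X) + 1L, -0.01, 0.01)
  model <- new("LogRegModel",
    bias = w[1L], weights = w[-1L], alpha = alpha,
    maxIters = as.integer(maxIters), tol = tol,
    finalLogLik = NA_real_, iterations = 0L
  )
  prevErr <- -logLikelihood(model, X, y) / n
  iters <- 0L
  for (it in seq_len(maxIters)) {
    g <- logregGradient(model, X, y) / n
    model@bias <- model@bias + alpha * g[1L]
    model@weights <- model@weights + alpha * g[-1L]
    iters <- it
    err <- -logLikelihood(model, X, y) / n
    if (abs(prevErr - err) < tol) {
      prevErr <- err
      break
    }
    prevErr <- err
  }
  model@finalLogLik <- -prevErr * n
  model@iterations <- iters
  model
}

#' Predicted probabilities of a logistic model
#'
#' @param model a [LogRegModel-class].
#' @param X n x d feature matrix.
#' @return numeric vector of probabilities sigmoid(w0 + X w).
#' @export
predictProba <- function(model, X) {
  X <- .checkXy(X)
  sigmoid(.linearScore(model, X))
}

#' @describeIn fitLogReg predicted 0/1 labels at a probability threshold
#'   (default 0.5; probability >= threshold maps to 1).
#' @param object a fitted [LogRegModel-class].
#' @param newdata feature matrix to score.
#' @param threshold decision threshold on the probability.
#' @export
setMethod("predict", "LogRegModel", function(object, newdata,
                                             threshold = 0.5) {
  as.numeric(predictProba(object, newdata) >= threshold)
})
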