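#' @include AllClasses.R
NULL

#' Fit a PLS1 regression model by NIPALS
#'
#' Partial least squares regression of a single response on a spectral
#' matrix. Predictors and response are mean-centered; components are
#' extracted by the NIPALS recursion started from the response vector, with
#' deflation of X only. For a univariate response the inner iteration
#' converges in one step, so the fit is fully deterministic. The regression
#' vector is `b = W (P'W)^{-1} q`, and training predictions from the score
#' decomposition and from `b` agree to numerical precision.
#'
#' If a late component collapses numerically (score norm below `1e-12` of
#' the first component's, as happens beyond the rank of noiseless data), the
#' model is truncated to the components actually extracted, with a warning.
#'
#' @param X numeric matrix, samples in rows, wavelengths in columns.
#' @param y numeric response (SSC, degrees Brix), one value per row of `X`.
#' @param nLv number of latent variables, at most `min(nrow(X) - 1, ncol(X))`.
#' @return A [PLSModel-class].
#' @seealso [predict,PLSModel-method], [selectLatentVariables()]
#' @export
fitPLS <- function(X, y, nLv) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) .stopf("X has %d rows but y has %d values", n, length(y))
  nLv <- as.integer(nLv)
  bound <- min(n - 1L, p)
  if (nLv < 1L || nLv > bound)
    .stopf("nLv must satisfy 1 <= nLv <= min(n-1, p) = %d (got %d)", bound, nLv)
  if (sd(y) == 0) .stopf("response has zero variance")
  xMean <- colMeans(X)
  yMean <- mean(y)
  E <- sweep(X, 2L, xMean)      # deflated X
  yc <- y - yMean
  W <- matrix(0, p, nLv); P <- matrix(0, p, nLv); q <- numeric(nLv)
  scoreScale <- NA_real_
  a <- 0L
  while (a < nLv) {
    w <- drop(crossprod(E, yc))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-300) break
    w <- w / wn
    tt <- drop(E %*% w)
    tss <- sum(tt^2)
    if (is.na(scoreScale)) scoreScale <- tss
    if (tss < 1e-12 * scoreScale) break
    a <- a + 1L
    W[, a] <- w
    P[, a] <- drop(crossprod(E, tt)) / tss
    q[a] <- sum(yc * tt) / tss
    E <- E - tcrossprod(tt, P[, a])
  }
  if (a == 0L) .stopf("no latent variable could be extracted")
  if (a < nLv) {
    .warnf("PLS truncated to %d latent variables (requested %d): later components are numerically degenerate",
           a, nLv)
    W <- W[, seq_len(a), drop = FALSE]
    P <- P[, seq_len(a), drop = FALSE]
    q <- q[seq_len(a)]
    nLv <- a
  }
  R <- W %*% solve(crossprod(P, W))          # projection: scores = Xc %*% R
  b <- drop(R %*% q)
  res <- yc - drop(sweep(X, 2L, xMean) %*% b)
  new("PLSModel", nLv = nLv, xMean = xMean, yMean = yMean, weights = W,
      xLoadings = P, yLoadings = q, coefficients = b, projection = R,
      residuals = res)
}

#' Predict SSC from spectra
#'
#' `y_hat = (X - xMean) %*% b + yMean`; deterministic. With `nLv` below the
#' model's component count, the regression vector is rebuilt from the first
#' `nLv` components only.
#'
#' @param object a [PLSModel-class].
#' @param newdata numeric matrix with one column per model predictor.
#' @param nLv optional truncated component count (`1..nLatent(object)`).
#' @return Numeric vector of predictions.
#' @export
setMethod("predict", "PLSModel", function(object, newdata, nLv = NULL) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object@xMean))
    .stopf("newdata has %d columns but the model expects %d",
           ncol(X), length(object@xMean))
  b <- if (is.null(nLv)) object@coefficients else .plsCoefAt(object, nLv)
  drop(sweep(X, 2L, object@xMean) %*% b) + object@yMean
})

# regression vector using only the first a components
.plsCoefAt <- function(model, a) {
  a <- as.integer(a)
  if (a < 1L || a > model@nLv)
    .stopf("nLv must be in 1..%d (got %d)", model@nLv, a)
  W <- model@weights[, seq_len(a), drop = FALSE]
  P <- model@xLoadings[, seq_len(a), drop = FALSE]
  drop(W %*% solve(crossprod(P, W)) %*% model@yLoadings[seq_len(a)])
}

#' Choose the latent-variable count by cross-validation
#'
#' Contiguous-block cross-validation on the calibration set: samples are cut
#' into `folds` consecutive blocks, each block is predicted from a model fit
#' on the others, and the component count minimizing the cross-validated
#' RMSE over `1..lvMax` is returned (ties go to the fewest components).
#' `lvMax` is clipped, with a warning, to the rank bound of the smallest
#' training fold.
#'
#' @param X calibration spectra matrix.
#' @param y calibration response.
#' @param lvMax largest component count to consider (default 20).
#' @param folds number of contiguous blocks (default 10).
#' @return The chosen component count. The cross-validated RMSE curve is
#'   attached as attribute `"rmsecv"`.
#' @export
selectLatentVariables <- function(X, y, lvMax = 20L, folds = 10L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  lvMax <- as.integer(lvMax)
  folds <- as.integer(folds)
  if (lvMax < 1L) .stopf("lvMax must be >= 1")
  if (folds < 2L || folds > n) .stopf("folds must be in 2..%d (got %d)", n, folds)
  foldId <- as.integer(cut(seq_len(n), folds, labels = FALSE))
  minTrain <- n - max(tabulate(foldId))
  bound <- min(minTrain - 1L, ncol(X))
  if (lvMax > bound) {
    .warnf("lvMax clipped from %d to the rank bound %d", lvMax, bound)
    lvMax <- bound
  }
  sse <- numeric(lvMax)
  achieved <- lvMax
  for (k in seq_len(folds)) {
    hold <- foldId == k
    fit <- suppressWarnings(fitPLS(X[!hold, , drop = FALSE], y[!hold], lvMax))
    achieved <- min(achieved, nLatent(fit))
    for (a in seq_len(nLatent(fit))) {
      pred <- predict(fit, X[hold, , drop = FALSE], nLv = a)
      sse[a] <- sse[a] + sum((y[hold] - pred)^2)
    }
    if (nLatent(fit) < lvMax)   # degenerate beyond the data's rank: reuse
      for (a in seq(nLatent(fit) + 1L, lvMax))
        sse[a] <- sse[a] + sum((y[hold] -
                                predict(fit, X[hold, , drop = FALSE]))^2)
  }
  rmsecv <- sqrt(sse / n)
  best <- which.min(rmsecv)     # first minimum = fewest components on ties
  structure(as.integer(best), rmsecv = rmsecv)
}

#' Correlation between measured and predicted values
#'
#' The conventional prediction-set correlation coefficient is Pearson's r
#' between measured and predicted SSC (`variant = "pearson"`, the default).
#' `variant = "printed"` computes `1 - SS_res / SS_tot` instead, a
#' residual-based variant sometimes printed in place of the correlation; it
#' is reported alongside for transparency but is not a correlation.
#'
#' @param y measured values (length >= 3, non-constant).
#' @param yHat predicted values (non-constant for the Pearson variant).
#' @param variant `"pearson"` or `"printed"`.
#' @return A single number.
#' @export
correlationMetric <- function(y, yHat, variant = c("pearson", "printed")) {
  variant <- match.arg(variant)
  if (length(y) != length(yHat)) .stopf("y and yHat lengths differ")
  if (length(y) < 3) .stopf("correlation metric needs at least 3 values")
  if (sd(y) == 0) .stopf("measured values are constant; correlation undefined")
  if (variant == "printed")
    return(1 - sum((y - yHat)^2) / sum((y - mean(y))^2))
  if (sd(yHat) == 0)
    .stopf("predicted values are constant; correlation undefined")
  cor(y, yHat)
}

#' Root mean square error of prediction
#'
#' `sqrt(sum((y - yHat)^2) / (n - 1))` with the conventional chemometrics
#' divisor n-1 by default; divisor n is available as an option.
#'
#' @param y measured values (length >= 2).
#' @param yHat predicted values.
#' @param divisor `"n_minus_1"` (default) or `"n"`.
#' @return RMSE in the units of `y` (degrees Brix for SSC).
#' @export
rmseMetric <- function(y, yHat, divisor = c("n_minus_1", "n")) {
  divisor <- match.arg(divisor)
  if (length(y) != length(yHat)) .stopf("y and yHat lengths differ")
  n <- length(y)
  if (n < 2) .stopf("RMSE needs at least 2 values")
  den <- if (divisor == "n_minus_1") n - 1 else n
  sqrt(sum((y - yHat)^2) / den)
}
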