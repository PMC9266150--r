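seededXy <- function(n = 40, p = 12, noise = 0.2, seed = 43) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p) * rbinom(p, 1, 0.4)
  list(X = X, y = drop(X %*% beta) + rnorm(n, 0, noise))
}

test_that("one latent variable suffices when y is linear in one channel", {
  set.seed(47)
  # centered orthogonal channels: the NIPALS weight then isolates channel 3
  X <- qr.Q(qr(scale(matrix(rnorm(30 * 6), 30), scale = FALSE)))
  y <- 2.5 * X[, 3] + 7
  f <- fitPLS(X, y, 1)
  expect_lt(max(abs(f@residuals)), 1e-9)
  expect_equal(predict(f, X), y, tolerance = 1e-9)
})

test_that("full-rank PLS reproduces ordinary least squares", {
  d <- seededXy(n = 30, p = 5)
  f <- fitPLS(d$X, d$y, 5)
  ols <- lm(d$y ~ d$X)
  expect_equal(predict(f, d$X), unname(fitted(ols)), tolerance = 1e-8)
})

test_that("score-space and regression-vector predictions agree", {
  d <- seededXy()
  f <- fitPLS(d$X, d$y, 6)
  Xc <- sweep(d$X, 2, f@xMean)
  scores <- Xc %*% f@projection
  viaScores <- drop(scores %*% f@yLoadings) + f@yMean
  expect_equal(predict(f, d$X), viaScores, tolerance = 1e-10)
})

test_that("fitting is invariant to sample permutation and equivariant to y shifts", {
  d <- seededXy(seed = 53)
  f <- fitPLS(d$X, d$y, 4)
  perm <- sample(nrow(d$X))
  fPerm <- fitPLS(d$X[perm, ], d$y[perm], 4)
  expect_equal(coef(fPerm), coef(f), tolerance = 1e-10)
  fShift <- fitPLS(d$X, d$y + 100, 4)
  expect_equal(predict(fShift, d$X), predict(f, d$X) + 100, tolerance = 1e-8)
})

test_that("training RMSE never increases with more components", {
  d <- seededXy(seed = 59)
  f <- fitPLS(d$X, d$y, 10)
  rmse <- vapply(1:10, function(a)
    rmseMetric(d$y, predict(f, d$X, nLv = a)), 0)
  expect_true(all(diff(rmse) <= 1e-12))
})

test_that("predicting the training mean spectrum returns the mean response", {
  d <- seededXy(seed = 61)
  f <- fitPLS(d$X, d$y, 3)
  expect_equal(predict(f, matrix(colMeans(d$X), 1)), mean(d$y),
               tolerance = 1e-10)
})

test_that("fit guards: rank bound, degenerate response, shape mismatches", {
  d <- seededXy(n = 10, p = 4)
  expect_error(fitPLS(d$X, d$y, 5), "nLv")
  expect_error(fitPLS(d$X, d$y, 0), "nLv")
  expect_error(fitPLS(d$X, rep(3, 10), 2), "variance")
  expect_error(fitPLS(d$X, d$y[-1], 2), "rows")
  f <- fitPLS(d$X, d$y, 2)
  expect_error(predict(f, d$X[, 1:3]), "columns")
})

test_that("components beyond the data rank are truncated with a warning", {
  set.seed(67)
  base <- matrix(rnorm(30 * 2), 30)
  X <- base %*% matrix(rnorm(2 * 8), 2)   # rank 2
  y <- drop(base %*% c(1, -2))
  expect_warning(f <- fitPLS(X, y, 6), "truncated")
  expect_lte(nLatent(f), 2L)
})

test_that("cross-validation selects the true rank on noiseless data and few LVs on noise", {
  set.seed(71)
  base <- matrix(rnorm(60 * 2), 60)
  X <- base %*% matrix(rnorm(2 * 15), 2) +
    matrix(rnorm(60 * 15, 0, 1e-6), 60)
  y <- drop(base %*% c(2, -1))
  expect_identical(as.integer(selectLatentVariables(X, y, lvMax = 8)), 2L)
  # pure-noise response: no structure to chase
  yNoise <- rnorm(60)
  expect_lte(as.integer(selectLatentVariables(X, yNoise, lvMax = 8)), 3L)
  # single candidate
  d <- seededXy(seed = 73)
  expect_identical(as.integer(selectLatentVariables(d$X, d$y, lvMax = 1)), 1L)
  # clipping beyond the rank bound warns
  expect_warning(selectLatentVariables(d$X[1:12, ], d$y[1:12], lvMax = 20),
                 "clipped")
})

test_that("correlation metric behaves like Pearson r with a permutation null", {
  y <- c(1, 2, 3, 4, 5)
  expect_equal(correlationMetric(y, y), 1)
  expect_equal(correlationMetric(y, -y + 10), -1)
  expect_equal(correlationMetric(y, y), cor(y, y))
  set.seed(79)
  big <- rnorm(500)
  expect_lt(abs(correlationMetric(big, sample(big))), 0.2)
  expect_error(correlationMetric(rep(1, 5), y), "constant")
  expect_error(correlationMetric(y[1:2], y[1:2]), "at least 3")
  # printed residual-based variant
  expect_equal(correlationMetric(y, y, variant = "printed"), 1)
  yhat <- y + c(0.5, -0.5, 0, 0.5, -0.5)
  expect_equal(correlationMetric(y, yhat, variant = "printed"),
               1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
})

test_that("RMSE uses the n-1 divisor by default and is homogeneous", {
  expect_equal(rmseMetric(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 2))
  expect_equal(rmseMetric(c(1, 2, 3), c(1, 2, 4), divisor = "n"), sqrt(1 / 3))
  expect_equal(rmseMetric(1:5, 1:5), 0)
  y <- rnorm(10); e <- rnorm(10)
  expect_equal(rmseMetric(y, y + 3 * e), 3 * rmseMetric(y, y + e),
               tolerance = 1e-12)
  expect_error(rmseMetric(1, 1), "at least 2")
})

test_that("NIPALS predictions match an established PLS implementation", {
  set.seed(83)
  n <- 50; p <- 20
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("w", 1:p)))
  y <- drop(X[, 1] * 2 + X[, 5] - X[, 9]) + rnorm(n, 0, 0.3)
  Xnew <- matrix(rnorm(10 * p), 10, p, dimnames = list(NULL, paste0("w", 1:p)))
  f <- fitPLS(X, y, 4)
  mo <- mixOmics::pls(X, y, ncomp = 4, scale = FALSE, mode = "regression")
  expect_equal(predict(f, Xnew),
               unname(predict(mo, Xnew)$predict[, 1, 4]), tolerance = 1e-6)
})
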