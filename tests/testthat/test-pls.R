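test_that("column filtering implements the minimum-sigma rule", {
  X <- cbind(const = rep(2, 6), small = c(0, 1, 0, 1, 0, 1),
             big = seq(0, 25, by = 5))
  expect_equal(unname(filterColumns(X, 0.1)), c(FALSE, TRUE, TRUE))
  expect_true(all(filterColumns(X, 0)))
  # column sds exactly 1.9 and 2.1: only the second survives the 2.0 filter
  X2 <- cbind(a = c(-1, 1) * 1.9 / sqrt(2), b = c(-1, 1) * 2.1 / sqrt(2))
  expect_equal(unname(filterColumns(X2, 2.0)), c(FALSE, TRUE))
  expect_error(filterColumns(X, 100), "lower the threshold")
})

test_that("a one-column linear response is fit exactly with one component", {
  set.seed(1)
  x <- rnorm(12)
  y <- 3 * x + 1
  m <- fitPLS(cbind(x), y, 1)
  expect_lt(max(abs(m@fitted - y)), 1e-8)
})

test_that("full-rank PLS equals ordinary least squares", {
  toy <- toyRegression(n = 6, k = 4, seed = 11)
  for (scaling in c("none", "comfa_std", "autoscale")) {
    m <- fitPLS(toy$X, toy$y, ncomp = 4, scaling = scaling)
    ols <- lm.fit(cbind(1, toy$X), toy$y)
    pred <- as.numeric(cbind(1, toy$X) %*% ols$coefficients)
    expect_lt(max(abs(predict(m, toy$X) - pred)), 1e-8)
  }
})

test_that("duplicating every column leaves predictions unchanged", {
  toy <- toyRegression(n = 10, k = 5, seed = 3)
  m1 <- fitPLS(toy$X, toy$y, ncomp = 3, scaling = "none")
  m2 <- fitPLS(cbind(toy$X, toy$X), toy$y, ncomp = 3, scaling = "none")
  expect_equal(predict(m1, toy$X), predict(m2, cbind(toy$X, toy$X)),
               tolerance = 1e-9)
})

test_that("stored fitted values satisfy the prediction contract", {
  toy <- toyRegression()
  m <- fitPLS(toy$X, toy$y, ncomp = 2)
  expect_lt(max(abs(predict(m, toy$X) - m@fitted)), 1e-10)
  expect_error(fitPLS(toy$X, rep(1, 8), 2), "zero variance")
  expect_error(fitPLS(toy$X, toy$y, 20), "ncomp")
})

test_that("leave-one-out CV equals brute-force refitting", {
  toy <- toyRegression(n = 8, k = 5, seed = 5)
  for (scaling in c("none", "comfa_std")) {
    cv <- looCrossValidate(toy$X, toy$y, maxComponents = 3, scaling = scaling)
    for (nc in 1:3) {
      press <- 0
      for (i in 1:8) {
        m <- fitPLS(toy$X[-i, ], toy$y[-i], ncomp = nc, scaling = scaling)
        press <- press + (toy$y[i] - predict(m, toy$X[i, , drop = FALSE]))^2
      }
      expect_equal(cv@press[nc], press, tolerance = 1e-10,
                   info = paste(scaling, nc))
    }
  }
})

test_that("cross-validation recognises noiseless linear structure", {
  set.seed(9)
  X <- matrix(rnorm(15 * 4), 15, 4)
  y <- as.numeric(X %*% c(1, -2, 0.5, 0))
  cv <- looCrossValidate(X, y, maxComponents = 4)
  expect_gt(max(q2(cv)), 0.999)
  # clipping warns
  expect_warning(looCrossValidate(X, y, maxComponents = 50), "clipped")
})

test_that("the ONC is the smallest component count at the q2 maximum", {
  set.seed(21)
  X <- matrix(rnorm(12 * 6), 12, 6)
  y <- as.numeric(X[, 1] - X[, 2]) + rnorm(12, sd = 0.05)
  cv <- looCrossValidate(X, y, maxComponents = 5)
  expect_equal(q2(cv)[onc(cv)], max(q2(cv)))
  if (onc(cv) > 1) expect_true(all(q2(cv)[seq_len(onc(cv) - 1)] < max(q2(cv))))
})

test_that("internal statistics follow the r2 / SEE / F definitions", {
  toy <- toyRegression(n = 12, k = 3, seed = 2)
  m <- fitPLS(toy$X, toy$y, ncomp = 3)
  st <- internalStats(m, toy$X, toy$y)
  res <- toy$y - predict(m, toy$X)
  expect_equal(st$r2, 1 - sum(res^2) / sum((toy$y - mean(toy$y))^2))
  expect_equal(st$see, sqrt(sum(res^2) / (12 - 3 - 1)))
  expect_equal(st$f, (st$r2 / 3) / ((1 - st$r2) / (12 - 3 - 1)))
  expect_equal(sum(st$contributions), 1, tolerance = 1e-9)
  # perfect fit: r2 = 1, SEE = 0
  yy <- as.numeric(toy$X %*% c(1, 2, 3)) + 5
  mp <- fitPLS(toy$X, yy, ncomp = 3)
  sp <- internalStats(mp, toy$X, yy)
  expect_equal(sp$r2, 1, tolerance = 1e-9)
  expect_equal(sp$see, 0, tolerance = 1e-6)
  expect_error(internalStats(m, toy$X[1:4, ], toy$y[1:4]), "n > ncomp")
})

test_that("field contributions respect channel structure", {
  set.seed(4)
  X <- matrix(rnorm(10 * 6), 10, 6)
  ch <- rep(c("steric", "elec"), each = 3)
  y <- as.numeric(X[, 1:3] %*% c(1, 1, 1))  # only the steric block matters
  m <- fitPLS(X, y, ncomp = 4, scaling = "none", channelOfColumn = ch)
  contr <- fieldContributions(m, X)
  expect_named(contr, c("steric", "elec"))
  expect_gt(contr[["steric"]], contr[["elec"]])
  expect_equal(sum(contr), 1)
})

test_that("PLS recovers sparse coefficients from synthetic data as noise vanishes", {
  # identifiable (overdetermined) regime: with p < n the coefficient vector
  # is estimable and PLS at full-ish rank must recover it as noise vanishes
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  cosines <- vapply(c(0.5, 0.05, 0), function(ns) {
    d <- genLinearDataset(nSamples = 60, nColumns = 30, nActive = 8,
                          noiseSd = ns, seed = 99)
    m <- fitPLS(d$X, d$y, ncomp = 12, scaling = "none")
    b <- numeric(ncol(d$X)); b[m@columnMask] <- m@coefficients
    cosine(b, d$betaTrue)
  }, 0)
  expect_true(all(diff(cosines) > -1e-6))  # improves as noise shrinks
  expect_gt(cosines[3], 0.95)
})
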