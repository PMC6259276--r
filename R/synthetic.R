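## synthetic_data: datasets with the statistical structure the analysis
## assumes, so the PLS, cross-validation and validation stages can be
## exercised end to end without any chemistry.

#' Generate a locally correlated sparse linear dataset
#'
#' Columns are produced by a moving-average smoother (window
#' \code{correlationLength}) over independent standard normals, mimicking
#' the smoothness of grid fields that makes column filtering and PLS
#' non-trivial; the response is a sparse linear combination of
#' \code{nActive} random columns plus Gaussian noise. The default shape
#' (21 samples, 500 columns, 10 active, noise sd 0.3 log units) matches a
#' small congeneric QSAR training set.
#'
#' @param nSamples,nColumns matrix dimensions.
#' @param nActive number of nonzero true coefficients (<= nColumns).
#' @param correlationLength moving-average window, in columns.
#' @param noiseSd response noise standard deviation (log units, >= 0).
#' @param seed integer seed; the dataset is reproducible given the seed.
#' @return list of class \code{"syntheticDataset"}: \code{X},
#'   \code{y}, \code{betaTrue}, \code{noiseSd}, \code{seed},
#'   \code{channelOfColumn} (all \code{"synthetic"}).
#' @export
genLinearDataset <- function(nSamples = 21L, nColumns = 500L, nActive = 10L,
                             correlationLength = 5L, noiseSd = 0.3,
                             seed = 1L) {
  if (nSamples < 2L || nColumns < 1L) stop("degenerate dataset size")
  if (nActive > nColumns) stop("nActive must not exceed nColumns")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(as.integer(seed))
  L <- max(1L, as.integer(correlationLength))
  Z <- matrix(stats::rnorm(nSamples * (nColumns + L - 1L)), nSamples)
  X <- vapply(seq_len(nColumns), function(j)
    rowMeans(Z[, j:(j + L - 1L), drop = FALSE]) * sqrt(L), numeric(nSamples))
  betaTrue <- numeric(nColumns)
  active <- sample.int(nColumns, nActive)
  betaTrue[active] <- stats::rnorm(nActive)
  y <- as.numeric(X %*% betaTrue) + stats::rnorm(nSamples, sd = noiseSd)
  structure(list(X = X, y = y, betaTrue = betaTrue, noiseSd = noiseSd,
                 seed = as.integer(seed),
                 channelOfColumn = rep("synthetic", nColumns)),
            class = "syntheticDataset")
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
    envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.syntheticDataset <- function(x, ...) {
  cat(sprintf("syntheticDataset: %d x %d, %d active columns, noise sd %.3g, seed %d\n",
    nrow(x$X), ncol(x$X), sum(x$betaTrue != 0), x$noiseSd, x$seed))
  invisible(x)
}

#' Generate a perturbed conformer series
#'
#' n copies of a template conformer, each given a random rigid motion
#' (uniform random rotation, translation) and isotropic Gaussian coordinate
#' jitter of the stated standard deviation, for exercising the alignment
#' stage: superposition must map each copy back to the template with an
#' RMSD consistent with the jitter.
#'
#' @param template a \code{\link{Conformer}}.
#' @param n number of copies.
#' @param jitterSd per-coordinate jitter standard deviation (Angstrom, >= 0).
#' @param seed integer seed.
#' @return list of \code{\link{Conformer}} objects.
#' @export
genPerturbedSeries <- function(template, n = 10L, jitterSd = 0.1, seed = 1L) {
  if (jitterSd < 0) stop("jitterSd must be >= 0")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(as.integer(seed))
  xyz0 <- atomCoords(template)
  lapply(seq_len(n), function(i) {
    R <- .randomRotation()
    t <- stats::rnorm(3, sd = 5)
    jit <- matrix(stats::rnorm(length(xyz0), sd = jitterSd), ncol = 3)
    cf <- template
    cf@compoundId <- paste0(template@compoundId, "_perturbed", i)
    cf@atoms[, c("x", "y", "z")] <- (xyz0 + jit) %*% t(R) +
      matrix(t, nrow(xyz0), 3, byrow = TRUE)
    cf
  })
}

# uniform random rotation matrix (QR of a Gaussian matrix, sign-fixed)
.randomRotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  d <- diag(sign(diag(qr.R(qr_))))
  Q <- Q %*% d
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
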