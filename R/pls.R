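## pls_engine: column filtering, block scaling, NIPALS PLS, LOO
## cross-validation and internal model diagnostics.

#' Column filtering by standard deviation
#'
#' Drops descriptor columns whose standard deviation across compounds is
#' below the threshold (the "minimum sigma" column filter; the conventional
#' default for energy fields is 2.0 kcal/mol).
#'
#' @param X numeric matrix (compounds x columns) or \code{\link{FieldMatrix}}.
#' @param threshold non-negative numeric; columns with sd < threshold drop.
#' @return logical vector, \code{TRUE} for retained columns.
#' @export
filterColumns <- function(X, threshold = 2.0) {
  if (is(X, "FieldMatrix")) X <- fieldValues(X)
  if (threshold < 0) stop("threshold must be >= 0")
  sds <- apply(X, 2, sd)
  mask <- sds >= threshold
  if (!any(mask))
    stop("column filter at threshold ", threshold,
         " drops every column; lower the threshold")
  mask
}

# per-column multiplicative weights implementing the scaling mode
.columnWeights <- function(X, scaling, channelOfColumn) {
  v <- apply(X, 2, var)
  if (scaling == "none") return(rep(1, ncol(X)))
  if (scaling == "autoscale") {
    w <- 1 / sqrt(v)
    w[!is.finite(w)] <- 0
    return(w)
  }
  # "comfa_std": block scaling - every channel block is weighted to the mean
  # block variance, so blocks contribute equally while the data keep their
  # overall (energy-like) magnitude; a uniform rescaling leaves the PLS fit
  # unchanged, but the magnitude matters to the post-scaling column filter
  if (is.null(channelOfColumn)) channelOfColumn <- rep("all", ncol(X))
  bv <- tapply(v, channelOfColumn, sum)
  w <- sqrt(mean(bv) / bv[channelOfColumn])
  w[!is.finite(w)] <- 0
  as.numeric(w)
}

# NIPALS PLS1 on a centred/scaled matrix and centred response.
# Returns cumulative coefficient matrix (k x ncomp) in the scaled space.
.nipals <- function(Xs, ys, ncomp) {
  k <- ncol(Xs)
  W <- P <- matrix(0, k, ncomp)
  q <- numeric(ncomp)
  Xd <- Xs; yd <- ys
  a <- 0L
  for (c in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # response fully explained
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < 1e-24) break
    p <- crossprod(Xd, t) / tt
    qc <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, p)
    yd <- yd - qc * t
    a <- c
    W[, c] <- w; P[, c] <- p; q[c] <- qc
  }
  if (a == 0L) stop("no PLS component could be extracted")
  B <- matrix(0, k, a)
  for (c in seq_len(a)) {
    Wc <- W[, seq_len(c), drop = FALSE]
    Pc <- P[, seq_len(c), drop = FALSE]
    B[, c] <- Wc %*% solve(crossprod(Pc, Wc), q[seq_len(c)])
  }
  list(B = B, ncomp = a)
}

#' Fit a PLS regression of activity on a descriptor matrix
#'
#' NIPALS partial least squares with column filtering applied beforehand
#' (\code{mask}) and the selected column scaling. Coefficients are mapped
#' back to original column units so that predictions work on raw rows.
#'
#' @param X numeric matrix (compounds x columns) or \code{\link{FieldMatrix}}.
#' @param y numeric response (activity, log units).
#' @param ncomp number of latent components.
#' @param scaling \code{"comfa_std"} (block scaling, default), \code{"none"}
#'   or \code{"autoscale"}.
#' @param mask logical column mask from \code{\link{filterColumns}}; default
#'   keeps all columns.
#' @param channelOfColumn channel label per column (taken from the
#'   \code{FieldMatrix} when \code{X} is one).
#' @return a \code{\link{PLSModel}}.
#' @export
fitPLS <- function(X, y, ncomp, scaling = c("comfa_std", "none", "autoscale"),
                   mask = NULL, channelOfColumn = NULL) {
  scaling <- match.arg(scaling)
  if (is(X, "FieldMatrix")) {
    if (is.null(channelOfColumn)) channelOfColumn <- channelOfColumn(X)
    X <- fieldValues(X)
  }
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("missing values not supported")
  if (var(y) < 1e-24) stop("response has zero variance")
  if (is.null(mask)) mask <- rep(TRUE, ncol(X))
  if (is.null(channelOfColumn)) channelOfColumn <- rep("all", ncol(X))
  n <- nrow(X)
  Xr <- X[, mask, drop = FALSE]
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > min(n - 1L, ncol(Xr)))
    stop("ncomp must lie in 1..min(n_samples-1, n_retained_columns)")
  mu <- colMeans(Xr)
  Xc <- sweep(Xr, 2, mu)
  wts <- .columnWeights(Xc, scaling, channelOfColumn[mask])
  Xs <- sweep(Xc, 2, wts, "*")
  ybar <- mean(y)
  fit <- .nipals(Xs, y - ybar, ncomp)
  bScaled <- fit$B[, fit$ncomp]
  bOrig <- bScaled * wts
  intercept <- ybar - sum(bOrig * mu)
  model <- new("PLSModel", ncomp = fit$ncomp, columnMask = mask,
    columnMeans = mu, columnScales = wts,
    coefficients = bOrig, coefScaled = bScaled,
    intercept = intercept, channelOfColumn = channelOfColumn,
    fitted = as.numeric(Xr %*% bOrig + intercept), y = as.numeric(y))
  model
}

#' Predict activities from a fitted PLS model
#' @param object a \code{\link{PLSModel}}.
#' @param newdata matrix with the same (unmasked) column layout as the
#'   training descriptor block, or a \code{\link{FieldMatrix}}.
#' @param ... unused.
#' @return numeric predictions.
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
  if (is(newdata, "FieldMatrix")) newdata <- fieldValues(newdata)
  newdata <- matrix(newdata, ncol = length(object@columnMask))
  as.numeric(newdata[, object@columnMask, drop = FALSE] %*%
             object@coefficients + object@intercept)
})

#' @rdname channelOfColumn
#' @export
setMethod("channelOfColumn", "PLSModel", function(x) x@channelOfColumn)

#' @rdname onc
#' @export
setMethod("onc", "PLSModel", function(x) x@ncomp)

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d components, %d/%d columns retained\n",
    object@ncomp, sum(object@columnMask), length(object@columnMask)))
})

#' Leave-one-out cross-validation with component selection
#'
#' For every component count up to \code{maxComponents}, each compound is
#' held out in turn, the model is refit on the remainder (centring and
#' scaling recomputed per fold; the column mask is fixed), and the held-out
#' activity is predicted. q2 (cross-validated r2) is
#' 1 - PRESS / sum((y - mean(y))^2) with the full-training mean in the
#' denominator. The optimal number of components (ONC) is the smallest count
#' attaining the maximal q2.
#'
#' @inheritParams fitPLS
#' @param maxComponents upper bound on the component count; clipped (with a
#'   warning) to n - 2 and the retained column count.
#' @return a \code{\link{LooResult}}.
#' @export
looCrossValidate <- function(X, y, maxComponents = 10L,
    scaling = c("comfa_std", "none", "autoscale"),
    mask = NULL, channelOfColumn = NULL) {
  scaling <- match.arg(scaling)
  if (is(X, "FieldMatrix")) {
    if (is.null(channelOfColumn)) channelOfColumn <- channelOfColumn(X)
    X <- fieldValues(X)
  }
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("leave-one-out requires at least 3 samples")
  if (is.null(mask)) mask <- rep(TRUE, ncol(X))
  if (is.null(channelOfColumn)) channelOfColumn <- rep("all", ncol(X))
  Xr <- X[, mask, drop = FALSE]
  bound <- min(n - 2L, ncol(Xr))
  if (maxComponents > bound) {
    warning("maxComponents clipped from ", maxComponents, " to ", bound)
    maxComponents <- bound
  }
  maxComponents <- as.integer(maxComponents)
  pred <- matrix(NA_real_, n, maxComponents)
  for (i in seq_len(n)) {
    Xi <- Xr[-i, , drop = FALSE]
    yi <- y[-i]
    mu <- colMeans(Xi)
    Xc <- sweep(Xi, 2, mu)
    wts <- .columnWeights(Xc, scaling, channelOfColumn[mask])
    fit <- .nipals(sweep(Xc, 2, wts, "*"), yi - mean(yi), maxComponents)
    xnew <- (Xr[i, ] - mu) * wts
    pr <- as.numeric(xnew %*% fit$B) + mean(yi)
    # if fewer components were extractable, carry the last one forward
    if (fit$ncomp < maxComponents)
      pr <- c(pr, rep(pr[fit$ncomp], maxComponents - fit$ncomp))
    pred[i, ] <- pr
  }
  press <- colSums((pred - y)^2)
  sstot <- sum((y - mean(y))^2)
  q2 <- 1 - press / sstot
  onc <- which(q2 >= max(q2) - 1e-12)[1]
  new("LooResult", q2 = q2, press = press, onc = as.integer(onc))
}

#' @rdname onc
#' @export
setMethod("onc", "LooResult", function(x) x@onc)

#' @rdname q2
#' @export
setMethod("q2", "LooResult", function(x) x@q2)

setMethod("show", "LooResult", function(object) {
  cat(sprintf("LooResult: ONC = %d, q2 = %.3f (profile over %d components)\n",
    object@onc, object@q2[object@onc], length(object@q2)))
})

#' Internal (training-set) model statistics
#'
#' r2 = 1 - SSres/SStot, standard error of estimate
#' SEE = sqrt(SSres / (n - c - 1)) and F = (r2/c) / ((1 - r2)/(n - c - 1))
#' for a model with c latent components, plus per-channel field
#' contributions sum_j |coef_j| sd_j normalized across channels.
#'
#' @param model a \code{\link{PLSModel}}.
#' @param X the training descriptor block (matrix or
#'   \code{\link{FieldMatrix}}).
#' @param y the training response.
#' @return list with \code{r2}, \code{see}, \code{f}, \code{ncomp},
#'   \code{contributions} (named fractions summing to 1).
#' @export
internalStats <- function(model, X, y) {
  if (is(X, "FieldMatrix")) X <- fieldValues(X)
  n <- length(y)
  c <- model@ncomp
  if (n <= c + 1L) stop("need n > ncomp + 1 for SEE and F")
  res <- y - predict(model, X)
  ssres <- sum(res^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- 1 - ssres / sstot
  list(r2 = r2,
       see = sqrt(ssres / (n - c - 1)),
       f = (r2 / c) / ((1 - r2) / (n - c - 1)),
       ncomp = c,
       contributions = fieldContributions(model, X))
}

#' Per-channel field contributions of a fitted model
#'
#' The conventional contribution measure: sum over columns of
#' |coefficient| x column standard deviation, totalled per channel and
#' normalized to fractions.
#'
#' @param model a \code{\link{PLSModel}}.
#' @param X the training descriptor block.
#' @return named numeric vector of fractions summing to 1.
#' @export
fieldContributions <- function(model, X) {
  if (is(X, "FieldMatrix")) X <- fieldValues(X)
  sds <- apply(X[, model@columnMask, drop = FALSE], 2, sd)
  contrib <- abs(model@coefficients) * sds
  ch <- model@channelOfColumn[model@columnMask]
  tot <- tapply(contrib, ch, sum)
  out <- tot / sum(tot)
  ord <- unique(model@channelOfColumn)
  out[ord[ord %in% names(out)]]
}
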