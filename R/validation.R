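## validation_stats: external (test-set) validation of a QSAR model -
## predictive r2, regression through the origin, Roy's rm^2, and the
## Golbraikh-Tropsha acceptability battery.

#' Predictive r2 over an external test set
#'
#' r2pred = (SD - PRESS) / SD, where PRESS = sum((pred - actual)^2) over the
#' test compounds and SD = sum((actual - trainMean)^2), the squared
#' deviations of the test activities about the mean activity of the
#' *training* molecules.
#'
#' @param testActual,testPred numeric, actual and predicted activities of the
#'   test set (>= 2 points).
#' @param trainMean mean activity of the training set.
#' @return list with \code{r2pred}, \code{press}, \code{sd}.
#' @export
r2Pred <- function(testActual, testPred, trainMean) {
  if (length(testActual) < 2L || length(testActual) != length(testPred))
    stop("need >= 2 paired test points")
  press <- sum((testPred - testActual)^2)
  sd2 <- sum((testActual - trainMean)^2)
  if (sd2 <= 0) stop("SD about the training mean is zero; r2pred undefined")
  list(r2pred = (sd2 - press) / sd2, press = press, sd = sd2)
}

#' Slopes of the regressions through the origin
#'
#' k = sum(y yhat) / sum(yhat^2) (actual regressed on predicted) and
#' k' = sum(y yhat) / sum(y^2) (predicted regressed on actual). k is the
#' headline value.
#'
#' @param actual,pred numeric activity vectors (>= 2 points).
#' @return list with \code{k}, \code{kPrime}.
#' @export
slopeK <- function(actual, pred) {
  if (length(actual) < 2L || length(actual) != length(pred))
    stop("need >= 2 paired points")
  if (sum(pred^2) <= 0 || sum(actual^2) <= 0)
    stop("zero norm; slope undefined")
  s <- sum(actual * pred)
  list(k = s / sum(pred^2), kPrime = s / sum(actual^2))
}

#' Determination coefficients of the regressions through the origin
#'
#' r0^2 = 1 - sum((yhat - k y)^2) / sum((yhat - mean(yhat))^2), with the
#' through-origin slope k of \code{\link{slopeK}}; the primed variant swaps
#' the roles of actual and predicted. Negative values are possible and
#' meaningful (worse than the mean).
#'
#' @param actual,pred numeric activity vectors.
#' @return list with \code{r0sq}, \code{r0sqPrime}.
#' @export
r0Squared <- function(actual, pred) {
  ks <- slopeK(actual, pred)
  vp <- sum((pred - mean(pred))^2)
  va <- sum((actual - mean(actual))^2)
  if (vp <= 0 || va <= 0) stop("zero variance; r0^2 undefined")
  list(r0sq = 1 - sum((pred - ks$k * actual)^2) / vp,
       r0sqPrime = 1 - sum((actual - ks$kPrime * pred)^2) / va)
}

#' Roy's rm^2
#'
#' rm^2 = r2 * (1 - sqrt(|r2 - r0^2|)). The absolute value makes the measure
#' well defined when r0^2 exceeds r2 (negative gap).
#'
#' @param r2 squared correlation (model r2).
#' @param r0sq through-origin determination coefficient.
#' @return numeric rm^2.
#' @export
rmSquared <- function(r2, r0sq) {
  if (any(abs(c(r2, r0sq)) > 1 + 1e-12))
    stop("inputs must lie in [-1, 1]")
  r2 * (1 - sqrt(abs(r2 - r0sq)))
}

#' Golbraikh-Tropsha acceptability criteria
#'
#' A model is considered externally predictive when all of:
#' q2 > 0.5, r2 > 0.6, (r2 - r0^2)/r2 < 0.1, 0.85 <= k <= 1.15 and
#' rm^2 > 0.5.
#'
#' @param q2 cross-validated r2 of the training model.
#' @param r2 model r2.
#' @param r0sq through-origin determination coefficient.
#' @param k through-origin slope.
#' @param rm2 Roy's rm^2.
#' @return named logical vector with one flag per criterion plus
#'   \code{overall}.
#' @export
criteriaCheck <- function(q2, r2, r0sq, k, rm2) {
  out <- c(q2_gt_0.5 = q2 > 0.5,
           r2_gt_0.6 = r2 > 0.6,
           ratio_lt_0.1 = (r2 - r0sq) / r2 < 0.1,
           k_in_0.85_1.15 = k >= 0.85 & k <= 1.15,
           rm2_gt_0.5 = rm2 > 0.5)
  c(out, overall = all(out))
}

#' Residual table
#' @param actual,pred equal-length activity vectors.
#' @return data.frame with columns \code{actual}, \code{pred},
#'   \code{residual} (actual - predicted).
#' @export
residualTable <- function(actual, pred) {
  if (length(actual) != length(pred)) stop("length mismatch")
  data.frame(actual = actual, pred = pred, residual = actual - pred)
}

#' Full external validation report
#'
#' Assembles the test-set validation battery: r2pred (about the training
#' mean), through-origin slopes and r0^2 (both conventions), rm^2, the gap
#' ratio (r2 - r0^2)/r2, and the acceptability flags. Following the
#' convention of the packaged reference analysis, rm^2 combines the
#' *training* r2 with the test-set r0^2.
#'
#' @param testActual,testPred test-set activities, actual and predicted.
#' @param trainMean mean training activity.
#' @param trainR2 non-cross-validated r2 of the training model.
#' @param q2 cross-validated r2 of the training model (enters only the
#'   criteria flags; may be \code{NA} to skip that flag).
#' @return list mirroring the external-validation table: \code{r2pred},
#'   \code{press}, \code{sd}, \code{k}, \code{kPrime}, \code{r0sq},
#'   \code{r0sqPrime}, \code{rm2}, \code{ratio}, \code{criteria},
#'   \code{residuals}.
#' @export
externalValidation <- function(testActual, testPred, trainMean, trainR2,
                               q2 = NA_real_) {
  rp <- r2Pred(testActual, testPred, trainMean)
  ks <- slopeK(testActual, testPred)
  r0 <- r0Squared(testActual, testPred)
  rm2 <- rmSquared(trainR2, r0$r0sq)
  ratio <- (trainR2 - r0$r0sq) / trainR2
  list(r2pred = rp$r2pred, press = rp$press, sd = rp$sd,
    k = ks$k, kPrime = ks$kPrime,
    r0sq = r0$r0sq, r0sqPrime = r0$r0sqPrime,
    rm2 = rm2, ratio = ratio,
    criteria = criteriaCheck(q2, trainR2, r0$r0sq, ks$k, rm2),
    residuals = residualTable(testActual, testPred))
}
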