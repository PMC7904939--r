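#' Mean squared error
#'
#' @param y Observed affinities.
#' @param yhat Predicted affinities, same length.
#' @return Mean of squared residuals.
#' @export
mse <- function(y, yhat) {
  check_pair_vectors(y, yhat, min_n = 1L)
  mean((y - yhat)^2)
}

#' Concordance index
#'
#' The probability that, for two randomly drawn pairs with different measured
#' affinities, the predictions are ordered the same way as the measurements.
#' Over all ordered label pairs with `y_i > y_j`, a correctly ordered
#' prediction scores 1, a tied prediction 0.5 and an inverted one 0; the sum
#' is divided by the number of strictly ordered label pairs (label ties
#' contribute to neither side). 0.5 corresponds to a random predictor and
#' 1.0 to perfect ordering.
#'
#' @param y Observed affinities (at least two distinct values).
#' @param yhat Predictions, same length.
#' @return CI in \[0, 1\].
#' @examples
#' concordance_index(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
concordance_index <- function(y, yhat) {
  check_pair_vectors(y, yhat, min_n = 2L)
  if (length(unique(y)) < 2L) {
    abort("Concordance index undefined: all affinity labels are tied.",
          class = "simdta_undefined_error")
  }
  gt <- outer(y, y, ">")          # (i, j): y_i > y_j
  d <- outer(yhat, yhat, "-")[gt] # prediction differences on those pairs
  sum((d > 0) + 0.5 * (d == 0)) / sum(gt)
}

#' Modified squared correlation coefficient
#'
#' An external-validation statistic for regression models:
#' `rm2 = r2 * (1 - sqrt(|r2 - r02|))`, where `r2` is the squared Pearson
#' correlation of a least-squares fit of predictions on observations with an
#' intercept and `r02` the squared correlation of the corresponding fit
#' through the origin (observed on the abscissa, predicted on the ordinate in
#' both). `r02` uses the centred total sum of squares,
#' `r02 = 1 - sum((yhat - k*y)^2) / sum((yhat - mean(yhat))^2)` with slope
#' `k = sum(y*yhat) / sum(y^2)`. Since `r02` can exceed or fall below `r2`
#' depending on the data, the absolute difference is used under the root.
#' Values above 0.5 are conventionally read as an acceptable model.
#'
#' @param y Observed affinities (length >= 3, nonzero variance).
#' @param yhat Predictions, same length, nonzero variance.
#' @return The rm2 statistic (at most `r2`).
#' @export
rm_squared <- function(y, yhat) {
  check_pair_vectors(y, yhat, min_n = 3L)
  if (sd(y) == 0 || sd(yhat) == 0) {
    abort("rm2 undefined: zero variance in observations or predictions.",
          class = "simdta_undefined_error")
  }
  r2 <- cor(y, yhat)^2
  k <- sum(y * yhat) / sum(y^2)
  r02 <- 1 - sum((yhat - k * y)^2) / sum((yhat - mean(yhat))^2)
  r2 * (1 - sqrt(abs(r2 - r02)))
}

#' Area under the precision-recall curve at an affinity threshold
#'
#' Binarizes the measured affinities at `threshold` (a pair is positive when
#' its affinity is at or above the threshold if `positive_is_high`, at or
#' below otherwise), ranks pairs by predicted affinity and integrates the
#' precision-recall curve step-wise (average precision; no trapezoidal
#' interpolation). Tied prediction scores share a single PR point. The
#' conventional thresholds are pKd 7.0 for dissociation-constant data and
#' 12.1 for transformed KIBA scores.
#'
#' @param y Observed affinities.
#' @param yhat Predicted affinities, same length.
#' @param threshold Binarization threshold on the scale of `y`.
#' @param positive_is_high If `TRUE` (default) affinities at or above the
#'   threshold are the positive class.
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(y, yhat, threshold, positive_is_high = TRUE) {
  check_pair_vectors(y, yhat, min_n = 1L)
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  pos <- if (positive_is_high) y >= threshold else y <= threshold
  if (all(pos) || !any(pos)) {
    abort("AUPR undefined: only one class after binarization.",
          class = "simdta_undefined_error")
  }
  ord <- order(-yhat)
  pos <- pos[ord]
  s <- yhat[ord]
  # block ends at the last element of each tied-score run
  block_end <- which(c(s[-length(s)] != s[-1L], TRUE))
  tp <- cumsum(pos)[block_end]
  fp <- cumsum(!pos)[block_end]
  recall <- tp / sum(pos)
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Evaluate predictions with the four affinity-regression metrics
#'
#' Computes MSE, concordance index, rm2 and AUPR for one set of predictions.
#' When AUPR is undefined (one class after binarization) it is reported as
#' `NA` with a warning; an undefined CI or rm2 (all labels tied, zero
#' variance) is an error.
#'
#' @inheritParams aupr
#' @return A one-row tibble with columns `mse`, `ci`, `rm2`, `aupr`, `n`.
#' @export
evaluate_predictions <- function(y, yhat, threshold,
                                 positive_is_high = TRUE) {
  check_pair_vectors(y, yhat, min_n = 2L)
  aupr_val <- tryCatch(
    aupr(y, yhat, threshold, positive_is_high),
    simdta_undefined_error = function(e) {
      warn("AUPR undefined for this set (single class); reported as NA.")
      NA_real_
    })
  tibble(
    mse = mse(y, yhat),
    ci = concordance_index(y, yhat),
    rm2 = rm_squared(y, yhat),
    aupr = aupr_val,
    n = length(y)
  )
}

check_pair_vectors <- function(y, yhat, min_n) {
  if (!is.numeric(y) || !is.numeric(yhat) || length(y) != length(yhat)) {
    abort("`y` and `yhat` must be numeric vectors of equal length.",
          class = "simdta_input_error")
  }
  if (length(y) < min_n) {
    abort(sprintf("Need at least %d value(s).", min_n),
          class = "simdta_input_error")
  }
  if (anyNA(y) || anyNA(yhat)) {
    abort("Missing values are not allowed in metric inputs.",
          class = "simdta_input_error")
  }
  invisible(TRUE)
}
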