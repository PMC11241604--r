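## Evaluation metrics: confusion-matrix rates, Dice overlap, MSE/PSNR and
## SSIM image-quality measures.

#' Confusion counts from predicted and true labels
#'
#' @param predicted,truth label vectors of equal length.
#' @param positive label counted as positive (default \code{"Abnormal"}).
#' @return named numeric vector c(TP, FP, TN, FN).
#' @export
confusionCounts <- function(predicted, truth, positive = "Abnormal") {
  if (length(predicted) != length(truth)) stop("length mismatch")
  p <- predicted == positive; t <- truth == positive
  c(TP = sum(p & t), FP = sum(p & !t), TN = sum(!p & !t), FN = sum(!p & t))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall (= sensitivity), specificity, F-score, false
#' negative rate, false positive rate, false rejection rate (alias of FNR
#' for a binary screen) and error rate. Any metric with a zero denominator
#' is reported as 0 with a warning.
#'
#' @param TP,FP,TN,FN non-negative counts (at least one positive total).
#' @return named numeric vector.
#' @export
confusionMetrics <- function(TP, FP, TN, FN) {
  TP <- unname(TP); FP <- unname(FP); TN <- unname(TN); FN <- unname(FN)
  counts <- c(TP, FP, TN, FN)
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n < 1) stop("at least one observation required")
  safe <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator); reporting 0"); 0 }
    else num / den
  }
  accuracy <- (TP + TN) / n
  precision <- safe(TP, TP + FP, "precision")
  recall <- safe(TP, TP + FN, "recall")
  specificity <- safe(TN, TN + FP, "specificity")
  f <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  fnr <- safe(FN, FN + TP, "fnr")
  fpr <- safe(FP, FP + TN, "fpr")
  c(accuracy = accuracy, precision = precision, recall = recall,
    sensitivity = recall, specificity = specificity, f_score = f,
    fnr = fnr, fpr = fpr, frr = fnr, error_rate = 1 - accuracy)
}

#' Dice overlap of two masks
#'
#' \code{2 |A intersect B| / (|A| + |B|)}; two empty masks give 1 by
#' contract.
#'
#' @param a,b logical rasters of the same shape.
#' @return value in [0,1].
#' @export
diceScore <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Mean squared error and peak signal-to-noise ratio
#'
#' @param ref,test rasters of the same shape.
#' @param peak peak signal value (1 for normalized rasters, 255 selectable).
#' @return named numeric vector c(mse, psnr); psnr is \code{Inf} when
#'   mse = 0.
#' @export
msePsnr <- function(ref, test, peak = 1) {
  if (!identical(dim(ref), dim(test))) stop("shape mismatch")
  if (peak <= 0) stop("peak must be > 0")
  mse <- mean((ref - test)^2)
  psnr <- if (mse == 0) Inf else 10 * log10(peak^2 / mse)
  c(mse = mse, psnr = psnr)
}

#' Structural similarity index
#'
#' Mean local SSIM with the standard luminance-contrast-structure product,
#' computed over a Gaussian window.
#'
#' @param ref,test rasters of the same shape, at least as large as the
#'   window.
#' @param window window size in px (default 7).
#' @param k1,k2 stabilizer constants (defaults 0.01, 0.03).
#' @param peak data range (default 1).
#' @return value in [-1, 1].
#' @export
ssimIndex <- function(ref, test, window = 7L, k1 = 0.01, k2 = 0.03, peak = 1) {
  ref <- asRaster(ref); test <- asRaster(test)
  if (!identical(dim(ref), dim(test))) stop("shape mismatch")
  if (nrow(ref) < window || ncol(ref) < window)
    stop("image smaller than the SSIM window")
  c1 <- (k1 * peak)^2; c2 <- (k2 * peak)^2
  g <- stats::dnorm(seq(-(window %/% 2), window %/% 2), sd = 1.5)
  w <- outer(g, g); w <- w / sum(w)
  f <- function(x) EBImage::imageData(EBImage::filter2(EBImage::Image(x), w,
                                                       boundary = "replicate"))
  mu1 <- f(ref); mu2 <- f(test)
  s11 <- f(ref * ref) - mu1^2
  s22 <- f(test * test) - mu2^2
  s12 <- f(ref * test) - mu1 * mu2
  ssimMap <- ((2 * mu1 * mu2 + c1) * (2 * s12 + c2)) /
             ((mu1^2 + mu2^2 + c1) * (s11 + s22 + c2))
  mean(ssimMap)
}
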