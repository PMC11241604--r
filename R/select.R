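## Feature selection: 2x2 chi-square scoring with the significance level
## taken from a binomial pmf value (the "significance rank").

#' Binomially derived significance rank
#'
#' The binomial probability of exactly \code{rho} successes in \code{e}
#' trials at success probability \code{g}:
#' \code{choose(e, rho) g^rho (1-g)^(e-rho)}. Used downstream as the
#' significance level of the chi-square test.
#'
#' @param e number of trials (>= 0).
#' @param rho number of successes (0 <= rho <= e).
#' @param g success probability in [0,1].
#' @return value in [0,1].
#' @export
significanceRank <- function(e, rho, g) {
  if (rho < 0 || rho > e) stop("require 0 <= rho <= e")
  if (g < 0 || g > 1) stop("require 0 <= g <= 1")
  stats::dbinom(rho, size = e, prob = g)
}

#' Degrees of freedom of a two-way contingency test
#'
#' @param levelsA,levelsB number of levels of each categorical variable
#'   (each >= 2).
#' @return integer \code{(levelsA - 1) * (levelsB - 1)}.
#' @export
chisqDof <- function(levelsA, levelsB) {
  if (levelsA < 2 || levelsB < 2) stop("levels must be >= 2")
  as.integer((levelsA - 1) * (levelsB - 1))
}

#' Chi-square association score of a 2x2 contingency table
#'
#' \code{e (WZ - YX)^2 / ((W+Y)(X+Z)(W+X)(Y+Z))} with \code{e} the total
#' count; algebraically identical to the Pearson statistic
#' \code{sum((O - E)^2 / E)}. A zero marginal means the feature (or class)
#' is constant: the score is 0 with a warning.
#'
#' @param W feature-high and class-positive count.
#' @param X feature-high and class-negative count.
#' @param Y feature-low and class-positive count.
#' @param Z feature-low and class-negative count.
#' @return statistic >= 0.
#' @export
chiSquareScore <- function(W, X, Y, Z) {
  counts <- c(W, X, Y, Z)
  if (any(counts < 0)) stop("counts must be non-negative")
  e <- sum(counts)
  if (e < 1) stop("table must contain at least one observation")
  marg <- c(W + Y, X + Z, W + X, Y + Z)
  if (any(marg == 0)) {
    warning("zero marginal: uninformative feature, score 0")
    return(0)
  }
  e * (W * Z - Y * X)^2 / prod(marg)
}

#' Binarize a feature against class labels into a 2x2 table
#'
#' Feature-high is value > median (ties count as low); the class-positive
#' level is \code{positive}.
#'
#' @param values numeric feature values (>= 2 samples).
#' @param labels class labels, two levels present.
#' @param positive label counted as the positive class (default
#'   \code{"Abnormal"}).
#' @return named numeric vector c(W, X, Y, Z).
#' @export
binarizeFeature <- function(values, labels, positive = "Abnormal") {
  if (length(values) < 2L) stop("need at least 2 samples")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  high <- values > stats::median(values)
  pos <- labels == positive
  c(W = sum(high & pos), X = sum(high & !pos),
    Y = sum(!high & pos), Z = sum(!high & !pos))
}

#' Select class-informative features by chi-square scoring
#'
#' Each feature column is median-binarized against the labels and scored
#' with [chiSquareScore()]. The significance level is the binomial rank
#' R = [significanceRank()]\code{(e, rho, g)} (or \code{alpha} when given),
#' the critical value is the chi-square quantile at 1 - R with
#' [chisqDof()]\code{(2, 2) = 1} degree of freedom, and features scoring at
#' least the critical value are kept, sorted by descending score. If none
#' survive, the top \code{fallbackK} features are kept with a warning.
#'
#' @param x numeric matrix, samples in rows, features in columns.
#' @param labels class labels (two levels).
#' @param e,rho,g binomial parameters of the significance rank (defaults
#'   20, 1, 0.05).
#' @param alpha optional plain significance level overriding the rank.
#' @param fallbackK features to keep when none pass (default 10).
#' @param positive positive class label.
#' @return a [SelectionResult-class].
#' @export
selectFeatures <- function(x, labels, e = 20L, rho = 1L, g = 0.05,
                           alpha = NULL, fallbackK = 10L,
                           positive = "Abnormal") {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("feature matrix must be finite")
  R <- if (is.null(alpha)) significanceRank(e, rho, g) else alpha
  crit <- stats::qchisq(1 - R, df = chisqDof(2, 2))
  scores <- vapply(seq_len(ncol(x)), function(j) {
    tab <- binarizeFeature(x[, j], labels, positive)
    suppressWarnings(chiSquareScore(tab["W"], tab["X"], tab["Y"], tab["Z"]))
  }, numeric(1))
  names(scores) <- colnames(x)
  keep <- which(scores >= crit)
  if (length(keep) == 0L) {
    warning("no feature passed the critical value; keeping the top ",
            fallbackK, " by score")
    keep <- order(scores, decreasing = TRUE)[seq_len(min(fallbackK, length(scores)))]
  }
  keep <- keep[order(scores[keep], decreasing = TRUE)]
  new("SelectionResult", scores = scores, rank = R, criticalValue = crit,
      selected = as.integer(keep))
}
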