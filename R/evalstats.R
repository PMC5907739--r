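#' Confusion-matrix performance measures
#'
#' Sensitivity, specificity, positive predictive value, and negative
#' predictive value of a binary prediction. A measure whose denominator
#' is empty (no true positives+false negatives, etc.) is reported as
#' `NA`, the explicit "undefined" marker used throughout the package.
#'
#' @param truth,pred Binary 0/1 vectors of equal length (>= 1); 1 = case.
#'
#' @return Named numeric vector `c(sensitivity, specificity, ppv, npv)`
#'   with `NA` for undefined entries.
#' @examples
#' confusionMeasures(c(1, 1, 1, 0, 0), c(1, 0, 1, 0, 1))
#' @export
confusionMeasures <- function(truth, pred) {
  if (length(truth) != length(pred) || length(truth) < 1L)
    stop("'truth' and 'pred' must be equal-length vectors of length >= 1")
  if (anyNA(truth) || anyNA(pred) ||
      !all(truth %in% 0:1) || !all(pred %in% 0:1))
    stop("'truth' and 'pred' must be binary 0/1")
  tp <- sum(truth == 1 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  c(sensitivity = safe(tp, tp + fn), specificity = safe(tn, tn + fp),
    ppv = safe(tp, tp + fp), npv = safe(tn, tn + fn))
}

#' Train/test consistency gap
#'
#' Absolute difference between training and testing values of each
#' performance measure for one replicate. A gap is `NA` (undefined) when
#' either side is undefined.
#'
#' @param train,test Named measure vectors as from [confusionMeasures()].
#' @return Named vector of |train - test| gaps.
#' @export
trainTestGap <- function(train, test) {
  stopifnot(length(train) == length(test))
  abs(train - test)
}

## ECDF of sample at the given evaluation points.
ecdfAt <- function(sample, points) {
  findInterval(points, sort(sample)) / length(sample)
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' Tests the null of no difference between two gap distributions against
#' the one-sided alternative that `y` is stochastically smaller than `x`
#' (its ECDF dominates). The statistic is
#' \eqn{D = \sup_t (\hat F_y(t) - \hat F_x(t))} evaluated over the pooled
#' sample points and clipped at 0; the p-value is the standard asymptotic
#' exponential bound \eqn{\exp(-2 D^2 n_x n_y / (n_x + n_y))} capped at 1,
#' or a Monte Carlo permutation p-value when `exact = TRUE` (uses the
#' current random number stream).
#'
#' In the PICV comparison, `x` is the traditional-CV gap sample and `y`
#' the PICV gap sample hypothesized to be smaller. Missing values
#' (undefined gaps) are not accepted; exclude them pairwise first.
#'
#' @param x Reference sample (non-empty numeric).
#' @param y Candidate "smaller" sample (non-empty numeric).
#' @param exact Use a permutation p-value instead of the asymptotic bound.
#' @param nPermutations Number of Monte Carlo permutations when
#'   `exact = TRUE`.
#'
#' @return An object of class `"htest"` with statistic `D` and `p.value`.
#' @export
ksOneSided <- function(x, y, exact = FALSE, nPermutations = 2000) {
  if (length(x) < 1L || length(y) < 1L || anyNA(x) || anyNA(y))
    stop("'x' and 'y' must be non-empty samples without missing values")
  ksD <- function(a, b) {
    pts <- c(a, b)
    max(0, max(ecdfAt(b, pts) - ecdfAt(a, pts)))
  }
  D <- ksD(x, y)
  m <- length(x); n <- length(y)
  if (exact) {
    pool <- c(x, y)
    hits <- 0L
    for (i in seq_len(nPermutations)) {
      idx <- sample.int(m + n, m)
      if (ksD(pool[idx], pool[-idx]) >= D - 1e-12) hits <- hits + 1L
    }
    p <- (hits + 1) / (nPermutations + 1)
    meth <- "One-sided two-sample Kolmogorov-Smirnov test (permutation)"
  } else {
    p <- min(1, exp(-2 * D^2 * m * n / (m + n)))
    meth <- "One-sided two-sample Kolmogorov-Smirnov test (asymptotic)"
  }
  structure(
    list(statistic = c(D = D), p.value = p, method = meth,
         alternative = "the second sample is stochastically smaller",
         data.name = paste(deparse1(substitute(x)), "and",
                           deparse1(substitute(y)))),
    class = "htest")
}

#' Median and maximum gap summary for one comparison
#'
#' Medians and maxima of the retained (defined) gaps of both methods,
#' with strict "PICV smaller" indicators: ties count as not smaller.
#' Undefined gaps are dropped per method, with counts reported. The
#' median of an even-length sample is the mean of the two central order
#' statistics.
#'
#' @param traditional,picv Numeric gap vectors (may contain `NA` for
#'   undefined replicates).
#'
#' @return List with medians, maxima, retained/dropped counts, the
#'   indicators `picvMedianSmaller` / `picvMaxSmaller`, and `available`
#'   (`FALSE` when either sample is entirely undefined).
#' @export
medianMaxSummary <- function(traditional, picv) {
  tKeep <- traditional[!is.na(traditional)]
  pKeep <- picv[!is.na(picv)]
  out <- list(
    nTraditional = length(tKeep), nPicv = length(pKeep),
    droppedTraditional = length(traditional) - length(tKeep),
    droppedPicv = length(picv) - length(pKeep),
    available = length(tKeep) > 0 && length(pKeep) > 0)
  if (!out$available) {
    out[c("medianTraditional", "medianPicv", "maxTraditional", "maxPicv",
          "picvMedianSmaller", "picvMaxSmaller")] <- NA
    return(out)
  }
  out$medianTraditional <- stats::median(tKeep)
  out$medianPicv <- stats::median(pKeep)
  out$maxTraditional <- max(tKeep)
  out$maxPicv <- max(pKeep)
  out$picvMedianSmaller <- out$medianPicv < out$medianTraditional
  out$picvMaxSmaller <- out$maxPicv < out$maxTraditional
  out
}
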