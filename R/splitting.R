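newSplitIndices <- function(train, test) {
  structure(list(train = as.integer(train), test = as.integer(test)),
            class = "SplitIndices")
}

#' @export
print.SplitIndices <- function(x, ...) {
  cat("SplitIndices: ", length(x$train), " train / ", length(x$test),
      " test\n", sep = "")
  invisible(x)
}

#' Traditional random cross-validation split
#'
#' Allocates a uniform random subset of `floor(trainFraction * n)` rows to
#' training and the remainder to testing, ignoring any structure in the
#' data. Uses the current random number stream.
#'
#' @param n Number of rows (>= 2).
#' @param trainFraction Training fraction in (0, 1); default two thirds.
#'
#' @return A `SplitIndices` list with sorted integer components `train`
#'   and `test`, disjoint and jointly exhaustive.
#' @examples
#' set.seed(1)
#' s <- traditionalSplit(2000)
#' lengths(s) # 1333 train, 667 test
#' @export
traditionalSplit <- function(n, trainFraction = 2/3) {
  if (length(n) != 1L || is.na(n) || n < 2)
    stop("'n' must be at least 2")
  if (length(trainFraction) != 1L || is.na(trainFraction) ||
      trainFraction <= 0 || trainFraction >= 1)
    stop("'trainFraction' must be in (0, 1)")
  n <- as.integer(n)
  t <- floor(trainFraction * n)
  if (t < 1L || t >= n)
    stop("trainFraction leaves an empty train or test partition for n = ", n)
  train <- sort(sample.int(n, t))
  newSplitIndices(train, setdiff(seq_len(n), train))
}

#' Two-locus genotype stratum labels
#'
#' Maps each row of a genotype dataset to one of the 9 SNP1 x SNP2
#' genotype categories (the Cartesian product \{00, 01, ..., 22\}), coded
#' `3 * snp1 + snp2` in 0..8.
#'
#' @param data A genotype dataset `data.frame` (columns `snp1`, `snp2`).
#' @return Integer vector of stratum labels in 0..8.
#' @export
genotypeStrata <- function(data) {
  checkGenotypeDataset(data)
  as.integer(3L * data$snp1 + data$snp2)
}

#' Proportional instance cross-validation (PICV) split
#'
#' Splits within each stratum of an independent variable so that the
#' stratum proportions of the full data are preserved in both partitions:
#' within each stratum of size \eqn{m_k} the training count is
#' \eqn{\lfloor f m_k \rfloor} or \eqn{\lceil f m_k \rceil}, with the
#' global training size fixed at \eqn{\lfloor f n \rfloor} — the same
#' total as [traditionalSplit()] — by largest-remainder apportionment
#' (ties broken by larger stratum, then lower stratum id). Selection
#' within each stratum is uniform. Strata so small that they receive 0
#' train or 0 test members are allocated by the same rule.
#'
#' @param strata Vector of stratum labels, one per row. With
#'   `checkGenotype = TRUE` (default) labels must be genotype codes in
#'   0..8 as from [genotypeStrata()]; set `checkGenotype = FALSE` to
#'   stratify on arbitrary integer or factor labels.
#' @param trainFraction Training fraction in (0, 1); default two thirds.
#' @param checkGenotype Enforce genotype coding of `strata`.
#'
#' @return A `SplitIndices` list (`train`, `test`), disjoint and jointly
#'   exhaustive over `seq_along(strata)`.
#' @examples
#' set.seed(1)
#' d <- simulateBalancedDataset(builtinModels()[["Scenario 1"]], 300)
#' s <- picvSplit(genotypeStrata(d))
#' lengths(s) # 200 train, 100 test
#' @export
picvSplit <- function(strata, trainFraction = 2/3, checkGenotype = TRUE) {
  if (length(strata) < 2L)
    stop("'strata' must label at least 2 rows")
  if (anyNA(strata)) stop("'strata' must not contain missing values")
  if (checkGenotype && !all(strata %in% 0:8))
    stop("genotype strata must be coded 0..8; ",
         "use checkGenotype = FALSE for generic strata")
  if (length(trainFraction) != 1L || is.na(trainFraction) ||
      trainFraction <= 0 || trainFraction >= 1)
    stop("'trainFraction' must be in (0, 1)")
  n <- length(strata)
  total <- floor(trainFraction * n)
  if (total < 1L || total >= n)
    stop("trainFraction leaves an empty train or test partition for n = ", n)
  groups <- split(seq_len(n), strata)   # occupied strata, label-sorted
  m <- lengths(groups)
  base <- floor(trainFraction * m)
  rem <- trainFraction * m - base
  extra <- total - sum(base)            # 0 <= extra < number of strata
  take <- base
  if (extra > 0) {
    ord <- order(-rem, -m, seq_along(m))
    take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1
  }
  train <- unlist(lapply(seq_along(groups), function(k) {
    idx <- groups[[k]]
    if (take[k] == 0) integer() else idx[sample.int(m[k], take[k])]
  }), use.names = FALSE)
  train <- sort(train)
  newSplitIndices(train, setdiff(seq_len(n), train))
}
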