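## Genotype datasets are plain data.frames with integer columns snp1, snp2
## (minor allele doses 0/1/2), a binary status column (1 = case), and any
## further numeric columns treated as covariates.

checkGenotypeDataset <- function(data, covariates = character()) {
  if (!is.data.frame(data))
    stop("genotype dataset must be a data.frame")
  need <- c("snp1", "snp2", "status")
  if (!all(need %in% names(data)))
    stop("genotype dataset must have columns: ", paste(need, collapse = ", "))
  for (col in c("snp1", "snp2")) {
    if (anyNA(data[[col]]) || !all(data[[col]] %in% 0:2))
      stop("column '", col, "' must contain minor allele doses in {0, 1, 2}")
  }
  if (anyNA(data$status) || !all(data$status %in% 0:1))
    stop("column 'status' must be binary (0 = control, 1 = case)")
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov))
    stop("covariate column(s) not found: ", paste(missing_cov, collapse = ", "))
  invisible(TRUE)
}

## Conditional genotype cell distributions for cases and controls implied
## by a penetrance model: P(cell | case) = f * pen / K and
## P(cell | control) = f * (1 - pen) / (1 - K).
conditionalCellProbs <- function(model) {
  f <- jointGenotypeProbs(model)
  K <- sum(f * model@pen)
  if (K <= 0 || K >= 1)
    stop("degenerate model: prevalence K = ", K,
         "; cannot sample both cases and controls")
  list(case = f * model@pen / K, control = f * (1 - model@pen) / (1 - K),
       K = K)
}

cellsToRows <- function(counts) {
  # counts: 9-vector in row-major (SNP1, SNP2) cell order
  idx <- rep.int(0:8, counts)
  data.frame(snp1 = idx %/% 3L, snp2 = idx %% 3L)
}

#' Simulate a balanced case-control dataset from a penetrance model
#'
#' Draws exactly `n/2` cases and `n/2` controls, with genotype cells
#' sampled directly from the analytic conditional distributions
#' \eqn{P(cell \mid case) = f_{ij} p_{ij} / K} and
#' \eqn{P(cell \mid control) = f_{ij} (1 - p_{ij}) / (1 - K)}. This is
#' distributionally identical to sampling from the population and
#' retaining equal numbers of cases and controls (the GAMETES balanced
#' design), with deterministic runtime even at low prevalence. Rows are
#' returned in shuffled order. Uses the current R random number stream;
#' call [set.seed()] for reproducibility.
#'
#' @param model A [PenetranceModel-class].
#' @param n Total sample size (even, >= 2).
#'
#' @return A genotype dataset `data.frame` with columns `snp1`, `snp2`,
#'   `status`.
#' @examples
#' set.seed(1)
#' d <- simulateBalancedDataset(builtinModels()[["Scenario 15"]], 2000)
#' table(d$status)
#' @export
simulateBalancedDataset <- function(model, n) {
  stopifnot(is(model, "PenetranceModel"))
  if (length(n) != 1L || is.na(n) || n < 2 || n %% 2 != 0)
    stop("'n' must be an even sample size >= 2")
  cc <- conditionalCellProbs(model)
  half <- n / 2
  cases <- cellsToRows(stats::rmultinom(1, half, as.vector(t(cc$case)))[, 1])
  ctrls <- cellsToRows(stats::rmultinom(1, half, as.vector(t(cc$control)))[, 1])
  out <- rbind(cbind(cases, status = 1L), cbind(ctrls, status = 0L))
  out <- out[sample.int(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate an unascertained population sample
#'
#' Genotypes drawn from the HWE joint cell distribution, case status
#' Bernoulli with the cell's penetrance. The empirical case fraction
#' converges to the model prevalence `K` as `n` grows. Utility for
#' prevalence checks and likelihood-ratio test calibration.
#'
#' @param model A [PenetranceModel-class].
#' @param n Sample size (>= 1).
#' @return A genotype dataset `data.frame` (`snp1`, `snp2`, `status`).
#' @export
simulatePopulation <- function(model, n) {
  stopifnot(is(model, "PenetranceModel"))
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a sample size >= 1")
  validObject(model)
  f <- jointGenotypeProbs(model)
  geno <- cellsToRows(stats::rmultinom(1, n, as.vector(t(f)))[, 1])
  geno <- geno[sample.int(n), , drop = FALSE]
  p <- model@pen[cbind(geno$snp1 + 1L, geno$snp2 + 1L)]
  out <- cbind(geno, status = stats::rbinom(n, 1L, p))
  rownames(out) <- NULL
  out
}

#' Read and write genotype datasets as delimited text
#'
#' Tab- or comma-delimited tables with a header; the delimiter is inferred
#' from the file extension (`.csv` means comma, anything else tab).
#' Required columns are `snp1`, `snp2`, `status`; all other numeric
#' columns are carried along as covariates.
#'
#' @param path File path.
#' @param data A genotype dataset `data.frame`.
#'
#' @return `readGenotypeDataset` returns the validated `data.frame`;
#'   `writeGenotypeDataset` invisibly returns `path`.
#' @export
readGenotypeDataset <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  data <- utils::read.table(path, header = TRUE, sep = sep)
  checkGenotypeDataset(data)
  data
}

#' @rdname readGenotypeDataset
#' @export
writeGenotypeDataset <- function(data, path) {
  checkGenotypeDataset(data)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(data, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a PLINK .raw additive-coded genotype file
#'
#' Reads the dialect produced by `plink --recode A`: a whitespace-delimited
#' header `FID IID PAT MAT SEX PHENOTYPE` followed by additive-coded SNP
#' columns (minor allele dose 0/1/2, typically named `rsid_allele`).
#' PHENOTYPE coding 1/2 is mapped to control/case (0/1). Rows with missing
#' phenotype (`-9`, `0`, or `NA`) or missing genotype at the selected SNPs
#' are dropped with a message giving the count.
#'
#' @param path File path.
#' @param snps Character vector of two SNP column names (matched ignoring
#'   the `_allele` suffix), or `NULL` to take the first two SNP columns.
#'
#' @return A genotype dataset `data.frame` with columns `snp1`, `snp2`,
#'   `status`; the selected column names are kept in attribute
#'   `"snpNames"`.
#' @export
readPlinkRaw <- function(path, snps = NULL) {
  raw <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           na.strings = c("NA", "-9"))
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta %in% names(raw)))
    stop("not a PLINK .raw file: expected header columns ",
         paste(meta, collapse = " "))
  snpcols <- setdiff(names(raw), meta)
  if (length(snpcols) < 2L)
    stop("PLINK .raw file must contain at least two SNP columns")
  if (is.null(snps)) {
    sel <- snpcols[1:2]
  } else {
    stopifnot(length(snps) == 2L)
    sel <- vapply(snps, function(s) {
      hit <- snpcols[snpcols == s | sub("_[ACGT0-9]+$", "", snpcols) == s]
      if (length(hit) != 1L) stop("SNP '", s, "' not found uniquely")
      hit
    }, character(1))
  }
  pheno <- raw$PHENOTYPE
  status <- ifelse(pheno %in% c(1, 2), pheno - 1, NA_real_)
  out <- data.frame(snp1 = raw[[sel[1]]], snp2 = raw[[sel[2]]],
                    status = status)
  drop <- !stats::complete.cases(out)
  if (any(drop))
    message("readPlinkRaw: dropped ", sum(drop),
            " row(s) with missing phenotype or genotype")
  out <- out[!drop, , drop = FALSE]
  out$status <- as.integer(out$status)
  rownames(out) <- NULL
  checkGenotypeDataset(out)
  attr(out, "snpNames") <- unname(sel)
  out
}
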