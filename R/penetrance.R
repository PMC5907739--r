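#' Hardy-Weinberg genotype probabilities
#'
#' Genotype dose probabilities implied by a minor allele frequency under
#' Hardy-Weinberg equilibrium: \eqn{((1-q)^2, 2q(1-q), q^2)} for doses
#' 0, 1, 2 of the minor allele.
#'
#' @param maf Minor allele frequency in \[0, 0.5\]. The boundary value 0 is
#'   admitted as the monomorphic limit (all dose 0).
#'
#' @return Numeric vector of length 3 summing to 1, named by dose.
#' @examples
#' hweGenotypeProbs(0.5) # 0.25 0.50 0.25
#' hweGenotypeProbs(0.1) # 0.81 0.18 0.01
#' @export
hweGenotypeProbs <- function(maf) {
  if (!is.numeric(maf) || length(maf) != 1L || is.na(maf) ||
      maf < 0 || maf > 0.5)
    stop("'maf' must be a single allele frequency in [0, 0.5]")
  c(`0` = (1 - maf)^2, `1` = 2 * maf * (1 - maf), `2` = maf^2)
}

#' Joint genotype cell probabilities
#'
#' The 3x3 matrix of two-locus genotype probabilities
#' \eqn{f_{ij} = P(SNP1 = i) P(SNP2 = j)} under HWE at each locus and
#' independence of the loci (no linkage disequilibrium, the generating
#' assumption of the simulated data).
#'
#' @param model A [PenetranceModel-class].
#'
#' @return 3x3 numeric matrix summing to 1; rows = SNP1 dose,
#'   columns = SNP2 dose.
#' @export
jointGenotypeProbs <- function(model) {
  stopifnot(is(model, "PenetranceModel"))
  validObject(model)
  f <- outer(hweGenotypeProbs(model@maf1), hweGenotypeProbs(model@maf2))
  dimnames(f) <- list(SNP1 = 0:2, SNP2 = 0:2)
  f
}

#' Population prevalence of a penetrance model
#'
#' Marginal case probability \eqn{K = \sum_{ij} f_{ij} p_{ij}}, the
#' HWE-genotype-frequency-weighted mean of the 9 penetrances.
#'
#' @param model A [PenetranceModel-class].
#' @return Prevalence `K` in \[0, 1\].
#' @export
populationPrevalence <- function(model) {
  sum(jointGenotypeProbs(model) * model@pen)
}

#' Genotype-attributable heritability of a penetrance model
#'
#' Narrow-sense heritability in the penetrance-table sense used by the
#' GAMETES simulator: the genotype-frequency-weighted variance of the
#' penetrance values about the prevalence, scaled by the phenotypic
#' variance of the binary trait,
#' \eqn{h^2 = \sum_{ij} f_{ij} (p_{ij} - K)^2 / (K (1 - K))}.
#'
#' @param model A [PenetranceModel-class].
#' @return Heritability `h2` (0 for a constant penetrance table).
#' @export
modelHeritability <- function(model) {
  f <- jointGenotypeProbs(model)
  K <- sum(f * model@pen)
  if (K <= 0 || K >= 1)
    stop("heritability undefined for degenerate prevalence K = ", K)
  sum(f * (model@pen - K)^2) / (K * (1 - K))
}

#' Marginal single-locus penetrances
#'
#' Case probability by dose at one locus, averaging the penetrance table
#' over the HWE distribution of the other locus:
#' \eqn{m_1(i) = \sum_j P(SNP2 = j) p_{ij}} and symmetrically for SNP2.
#' A diagnostic for residual main effects implied by an epistasis table.
#'
#' @param model A [PenetranceModel-class].
#' @return List with components `snp1` and `snp2`, each a 3-vector of
#'   marginal penetrances by dose.
#' @export
marginalPenetrances <- function(model) {
  w1 <- hweGenotypeProbs(model@maf1)
  w2 <- hweGenotypeProbs(model@maf2)
  validObject(model)
  list(snp1 = as.numeric(model@pen %*% w2),
       snp2 = as.numeric(w1 %*% model@pen))
}

#' Bundled two-locus epistasis models (prevalence 0.5 design)
#'
#' The 15 penetrance models covering all pairs of minor allele frequencies
#' from \{0.1, 0.2, 0.3, 0.4, 0.5\}, generated by the GAMETES penetrance
#' search at target heritability 0.005 and prevalence 0.5, shipped as a
#' plain-text CSV fixture. Scenario 11 (MAF 0.5/0.1) is bundled verbatim as
#' published even though its table implies a prevalence of about 0.33
#' rather than 0.5 (its heritability is 0.005 as stated); see the methods
#' vignette for the full analysis of this inconsistency.
#'
#' @return Named list of 15 [PenetranceModel-class] objects, labels
#'   `"Scenario 1"` ... `"Scenario 15"`.
#' @examples
#' mods <- builtinModels()
#' sapply(mods, populationPrevalence)
#' @export
builtinModels <- function() {
  path <- system.file("extdata", "penetrance_prev05.csv", package = "picv",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, colClasses = "numeric")
  expected <- c("scenario", "maf1", "maf2",
                paste0("p", rep(0:2, each = 3), rep(0:2, 3)))
  if (!identical(names(tab), expected) || nrow(tab) != 15L || anyNA(tab) ||
      !identical(tab$scenario, as.numeric(1:15)))
    stop("bundled penetrance table fixture is corrupted")
  pcols <- as.matrix(tab[, 4:12])
  if (any(pcols < 0) || any(pcols > 1) ||
      any(tab$maf1 <= 0 | tab$maf1 > 0.5 | tab$maf2 <= 0 | tab$maf2 > 0.5))
    stop("bundled penetrance table fixture is corrupted")
  out <- lapply(1:15, function(i) {
    pen <- matrix(pcols[i, ], nrow = 3, byrow = TRUE)
    PenetranceModel(tab$maf1[i], tab$maf2[i], pen,
                    label = paste("Scenario", i))
  })
  names(out) <- paste("Scenario", 1:15)
  out
}

#' Read or write a penetrance model as YAML
#'
#' The on-disk format is a small YAML document with keys `label`, `maf1`,
#' `maf2`, and `penetrance` (a list of three 3-value rows, SNP1 dose by
#' SNP2 dose). [writePenetranceModel()] and [readPenetranceModel()]
#' round-trip exactly.
#'
#' @param path File path.
#' @param model A [PenetranceModel-class].
#'
#' @return `readPenetranceModel` returns a [PenetranceModel-class];
#'   `writePenetranceModel` invisibly returns `path`.
#' @export
readPenetranceModel <- function(path) {
  doc <- yaml::read_yaml(path)
  need <- c("maf1", "maf2", "penetrance")
  if (!all(need %in% names(doc)))
    stop("penetrance model file must contain keys: ",
         paste(need, collapse = ", "))
  pen <- do.call(rbind, lapply(doc$penetrance, as.numeric))
  PenetranceModel(doc$maf1, doc$maf2, pen,
                  label = if (is.null(doc$label)) "" else doc$label)
}

#' @rdname readPenetranceModel
#' @export
writePenetranceModel <- function(model, path) {
  stopifnot(is(model, "PenetranceModel"))
  validObject(model)
  yaml::write_yaml(
    list(label = model@label, maf1 = model@maf1, maf2 = model@maf2,
         penetrance = lapply(1:3, function(i) as.numeric(model@pen[i, ]))),
    path)
  invisible(path)
}
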