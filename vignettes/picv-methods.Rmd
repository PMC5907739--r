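---
title: "Proportional instance cross validation for two-locus epistasis models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proportional instance cross validation for two-locus epistasis models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picv)
```

## The problem

Internal cross validation splits a dataset into a training partition, on
which a model is fit, and a testing partition, on which its predictive
performance is estimated. When the predictor of interest is a strongly
imbalanced categorical variable — the canonical example here is the
9-level SNP1 × SNP2 interaction genotype of a two-locus epistasis
analysis, where homozygous-minor combinations can be vanishingly rare —
a purely random split can by chance place most members of a rare
genotype cell in one partition. The fitted interaction term for that
cell then rests on a handful of observations, and the training and
testing estimates of sensitivity, specificity, PPV, and NPV disagree
more than sampling noise alone would explain. This erodes the apparent
reproducibility of interaction findings.

Proportional instance cross validation (PICV) addresses this by
splitting *within* each genotype stratum: two thirds of the
observations of every SNP1 × SNP2 genotype go to training and the rest
to testing, so the genotype composition of both partitions matches the
full data while the overall train/test ratio is unchanged. The idea is
not specific to genotypes; `picvSplit(..., checkGenotype = FALSE)`
stratifies on any categorical label.

## The generative model

A scenario is a `PenetranceModel`: minor allele frequencies $q_1, q_2
\in (0, 0.5]$ for two biallelic, unlinked SNPs, and a $3 \times 3$
penetrance table $p_{ij} = P(\text{case} \mid SNP1 = i, SNP2 = j)$ over
minor allele doses. Under Hardy–Weinberg equilibrium each locus has dose
probabilities $((1-q)^2,\, 2q(1-q),\, q^2)$, and the joint cell
probabilities are the outer product $f_{ij}$. The model implies

* prevalence $K = \sum_{ij} f_{ij}\, p_{ij}$,
* heritability (penetrance-table sense)
  $h^2 = \sum_{ij} f_{ij} (p_{ij} - K)^2 / K(1-K)$,
* marginal single-locus penetrances, a diagnostic for residual main
  effects in a nominally epistatic table.

`builtinModels()` ships 15 such scenarios — every MAF pair from
$\{0.1, \dots, 0.5\}$ — from a GAMETES-style design with target
heritability 0.005 and prevalence 0.5. Recomputing the algebra from the
bundled tables confirms $h^2 \in [0.0049, 0.0051]$ for all 15, and
$|K - 0.5| < 10^{-3}$ for 14 of them; see *Known limitations* for the
fifteenth.

## Data simulation

`simulateBalancedDataset()` draws exactly $n/2$ cases and $n/2$
controls directly from the analytic conditional cell distributions
$P(\text{cell} \mid \text{case}) = f_{ij} p_{ij}/K$ and
$P(\text{cell} \mid \text{control}) = f_{ij}(1-p_{ij})/(1-K)$. This is
distributionally identical to sampling a population and keeping equal
numbers of each status, but has deterministic runtime even at
prevalence 0.02. `simulatePopulation()` provides unascertained draws
for prevalence checks and LRT calibration.

The generator emulates idealised case-control data: HWE at both loci,
no linkage disequilibrium, no genotyping error or missingness, no
population structure, and no simulated covariates. Passing tests
therefore demonstrate the splitting method's behaviour under clean
conditions; real GWAS data violate several of these assumptions, and
results here do not quantify robustness to those violations.

## Splitting rules

Both splitters fix the global training size at
$\lfloor f n \rfloor$ with $f = 2/3$ by default, so the two methods are
always compared at identical train/test sizes. `traditionalSplit()`
takes a uniform random subset. `picvSplit()` gives each stratum of size
$m_k$ either $\lfloor f m_k \rfloor$ or $\lceil f m_k \rceil$ training
members, reconciling the global total by largest-remainder
apportionment (ties broken toward larger strata, then lower stratum
id); selection within strata is uniform. Strata with one or two members
are handled by the same rule and may land entirely in one partition.
Whether the floor, the ceiling, or a stochastic rule is the "right"
reading of a two-thirds split is underdetermined; the floor was chosen
and is applied identically to both methods. PICV stratifies by genotype
only, not genotype × status, so within-stratum case fractions can still
drift between partitions.

## Logistic models, prediction, and the LRT

Two specifications are fit by maximum likelihood with treatment coding
(reference genotype $(0,0)$, the homozygous-major/homozygous-major
cell): main effects (intercept + 2 + 2 dose dummies) and interaction
(adds the four products, one free parameter per genotype cell — a
saturated model when covariate-free). Design matrices are built as
explicit dummy columns rather than R factors, so a dose level or cell
absent from training yields an `NA` coefficient and predictions for
such rows fall back to the main-effects part of the fit instead of
failing. Covariate-free fits run IRLS on the genotype-cell sufficient
statistics (at most 9 weighted rows, `maxit = 100`), and the
covariate-free interaction fit's cell probabilities are set to the
exact observed cell fractions — the saturated-model closed form, which
the IRLS solution matches to numerical precision and which doubles as
an internal consistency oracle in the tests. Perfect separation
saturates a cell probability at 0/1 and sets a flag rather than
erroring; the log-likelihood uses the convention $0 \log 0 = 0$.

Classification is case iff $P(\text{case}) > 0.5$ strictly, ties to
control. `likelihoodRatioTest()` compares nested fits on the same rows:
statistic $2(\ell_1 - \ell_0)$ clipped at zero, degrees of freedom the
difference in estimated parameters (4 for interaction vs main effects
when all cells are occupied — fewer when empty cells drop dummies), and
an upper-tail chi-square p-value. Log-likelihoods are always Bernoulli,
whether computed from cells or rows, so nested comparisons are
well-defined.

## Performance measures and the KS comparison

`confusionMeasures()` reports sensitivity, specificity, PPV, and NPV,
with `NA` as the explicit undefined marker when a denominator is empty
(e.g. PPV with no predicted positives). Per replicate, the consistency
gap is |train − test| per measure; a gap is undefined if either side
is. Undefined gaps are excluded *pairwise* from each KS comparison, and
drop counts are reported so a user can detect selective loss.

The one-sided two-sample Kolmogorov–Smirnov statistic is
$D = \sup_t (\hat F_{\mathrm{PICV}}(t) - \hat F_{\mathrm{trad}}(t))$
over the pooled sample points, clipped at zero, with the asymptotic
exponential bound $p = \exp(-2 D^2 n_1 n_2/(n_1+n_2))$ capped at 1.
A Monte-Carlo permutation option (`exact = TRUE`) is available for
small samples. Median/maximum summaries use strict inequality for the
"PICV smaller" indicators (ties count as not smaller) and define the
median of an even-length sample as the mean of the two central order
statistics.

## Study design

`runScenario()` applies both splitters to the *same* simulated dataset
each replicate. Pairing reduces the Monte-Carlo variance of the
between-method comparison and is the default; `paired = FALSE` draws
independent datasets per method. A fresh dataset is simulated every
replicate by default, since repeated splitting of one fixed dataset
(`resplit = TRUE`) answers a narrower question — reproducibility
conditional on one realised sample — and empirically weakens the
comparison. Replicate $r$ of scenario $s$ runs under the derived seed
`(baseSeed * 16807 + s * 1e6 + r) mod (2^31 - 1)`, so every number in
every output table is a pure function of `(baseSeed, configuration)`
and replicates are independently reproducible. Replicate failures
(e.g. a single-class training partition at tiny $n$) are recorded with
a warning and the scenario continues; more than 10% failures mark the
scenario invalid.

The package's reference experiment is 15 scenarios × 200 paired
replicates at $n = 2000$, $f = 2/3$, cutoff 0.5, $\alpha = 0.05$ —
about two minutes on one CPU thanks to the cell-aggregated fits. The
full-scale design of 1000 replicates sharpens the KS p-values (the
one-sided p is $\exp(-N D^2)$ for two samples of size $N$, so p-values
shrink geometrically in the replicate count at fixed $D$) but does not
change which comparisons have large $D$. No multiple-testing correction
is applied across the 15 × 8 comparisons; each is reported at
$\alpha = 0.05$.

## Known limitations

**Scenario 11 (MAF 0.5/0.1) is inconsistent as bundled.** Its
penetrance values imply prevalence 0.328, not the design value 0.5 —
under *every* permutation and orientation of its nine values — while
its heritability about its own prevalence is 0.0050, exactly on target.
The table is evidently a genuine GAMETES product whose prevalence
constraint does not match the rest of the design (the other 14
scenarios hit $K = 0.5$ to within $3 \times 10^{-4}$); it is bundled
verbatim rather than silently repaired, the fixture-integrity tests
document the exception, and the package-level check that all bundled
scenarios imply $K \approx 0.5$ deliberately fails on it. The scenario
remains a perfectly valid generative model for the splitting
comparison.

**PICV helps row measures more than column measures.** At prevalence
0.5 with balanced sampling, cases and controls are statistically
symmetric, so sensitivity/specificity (computed within truth rows of
the confusion matrix) behave as twins, as do PPV/NPV (computed within
prediction columns). Across the bundled scenarios PICV strongly
stabilises the row measures — the sensitivity-gap KS comparison rejects
in ~14/15 scenarios at 200 replicates, and PICV gives smaller median
specificity gaps in 15/15 — while the column-measure gaps improve only
mildly (gap-SD ratios around 0.9 versus 0.78, KS rejections in only a
few scenarios at this scale). Mechanistically, PICV fixes the genotype
cell counts of both partitions, which stabilises the *composition* of
the predicted-positive set (a union of genotype cells), but a column
measure is a case *fraction* within that set, whose sampling variance
is dominated by within-cell status noise that genotype stratification
cannot remove. Users should expect the clearest consistency gains for
sensitivity and specificity. Variants tested and found not to change
this (see the test suite): re-splitting one fixed dataset, numeric
additive dose coding, tie-to-case classification, and unpaired designs.

**Other limitations.** Only two loci and a binary phenotype are
supported; *k*-fold and nested variants are out of scope; continuous
independent variables would need binning before stratification; and
covariates are accepted in the LRT workflow but never simulated.
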