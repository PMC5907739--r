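# picv — proportional instance cross validation for epistasis analysis

When a case-control association analysis targets the interaction of two
SNPs, the relevant predictor is the 9-level SNP1 × SNP2 genotype — and
at low minor allele frequencies some of its levels are rare. A
traditional cross-validation split, which allocates individuals to
training and testing at random, can badly misrepresent those rare
genotype cells in one partition, so training and testing estimates of
classification performance disagree for reasons that have nothing to do
with the biology. **Proportional instance cross validation (PICV)**
splits within each genotype stratum instead: two thirds of each SNP1 ×
SNP2 genotype go to training, the rest to testing, preserving the
genotype distribution in both partitions at an unchanged overall
train/test ratio.

This package provides, for biostatisticians and methods researchers:

* the PICV splitter (`picvSplit`, largest-remainder apportionment over
  strata; also usable on arbitrary categorical strata) and the
  traditional splitter it is compared against;
* two-locus penetrance models under Hardy–Weinberg equilibrium
  (`PenetranceModel`, prevalence/heritability/marginal algebra, 15
  bundled scenarios covering all MAF pairs from {0.1, …, 0.5});
* a GAMETES-style balanced case-control simulator
  (`simulateBalancedDataset`) and population sampler;
* logistic main-effects and saturated interaction models with
  treatment-coded genotype dummies, robust empty-cell handling, and a
  nested likelihood-ratio test with optional covariate adjustment
  (`fitLogistic`, `likelihoodRatioTest`, `consistencyLRT`);
* the evaluation harness: sensitivity/specificity/PPV/NPV with explicit
  undefined states, |train − test| consistency gaps, one-sided
  two-sample Kolmogorov–Smirnov comparisons with the PICV gaps
  hypothesized stochastically smaller, and per-scenario / cross-scenario
  study tables (`runScenario`, `runStudy`);
* readers/writers for delimited genotype tables, PLINK `.raw` files,
  and YAML penetrance models, plus a thin command-line front end in
  `inst/scripts/picv.R`.

The core comparison: for gap samples of size $n_1, n_2$,
$D = \sup_t\,(\hat F_{\mathrm{PICV}}(t) - \hat F_{\mathrm{trad}}(t))$,
$p = \exp(-2 D^2 n_1 n_2 / (n_1 + n_2))$, reported per measure × model
specification at α = 0.05.

## Worked example

```r
library(picv)
mods <- builtinModels()
mods[["Scenario 15"]]
#> PenetranceModel: Scenario 15
#>   MAF SNP1: 0.5  MAF SNP2: 0.5
#>   prevalence K = 0.499938  heritability h2 = 0.005028
#>     SNP2
#> SNP1    0     1     2
#>    0 0.44 0.522 0.515
#>    1 0.56 0.484 0.472
#>    2 0.44 0.509 0.542

sc <- runScenario(mods[["Scenario 15"]], n = 2000, replicates = 200,
                  baseSeed = 42, scenarioIndex = 15)
sc
#> ScenarioResult: Scenario 15
#>   n = 2000 , replicates = 200 ( 0 failed )
#>   one-sided KS (PICV gaps smaller):
#>         spec     measure      D       p nUsed dropped
#>         main sensitivity 0.1100 0.08892   200       0
#>         main specificity 0.1600 0.00598   200       0
#>         main         ppv 0.0606 0.48323   198       2
#>         main         npv 0.0615 0.47785   195       5
#>  interaction sensitivity 0.1150 0.07101   200       0
#>  interaction specificity 0.1600 0.00598   200       0
#>  interaction         ppv 0.0450 0.66698   200       0
#>  interaction         npv 0.0450 0.66698   200       0
```

Reading this: over 200 paired replicates, each simulating a fresh
balanced dataset of 2000 from the MAF 0.5/0.5 scenario and splitting it
both ways, the specificity |train − test| gaps of PICV are
stochastically smaller than those of traditional CV (D = 0.16,
p ≈ 0.006), the sensitivity gaps trend the same way (p ≈ 0.07 at this
replicate count), and the PPV/NPV gap distributions are close to
indistinguishable. `nUsed`/`dropped` account for replicates where a
measure was undefined (empty denominator) for either method; those are
excluded pairwise. Everything is a pure function of
`(baseSeed, scenarioIndex, configuration)`.

`runStudy(mods, n = 2000, replicates = 200, baseSeed = 1)` repeats this
for all 15 scenarios and assembles a per-scenario p-value table plus
counts of scenarios where PICV achieved strictly smaller median and
maximum gaps.

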