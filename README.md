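# famEWAS

Kinship-aware epigenome-wide association analysis of age-related DNA
methylation in extended families.

## What it is for

Family cohorts are a strong design for studying how CpG methylation
drifts with age — wide in-sample age ranges, reduced genetic
heterogeneity — but relatives are correlated, so per-probe regressions
must account for the pedigree or their P values are wrong. famEWAS
provides the complete analysis chain for analysts working with
450K-style methylation matrices and pedigree data:

- pedigree parsing and exact kinship coefficients (`readPedigree()`,
  `kinship()`, `kinshipMatrix()`)
- probe QC: detection-P filter, exclusion lists, β-range filter,
  quantile normalization, β↔M logit2 transforms (`runQC()`,
  `betaToM()`, ...)
- reference-based blood cell-type deconvolution
  (`estimateCellProportions()`)
- per-CpG polygenic linear mixed models with a likelihood-ratio test of
  the age effect and Bonferroni thresholding (`fitProbe()`,
  `runEwas()`)
- positional clustering of significant sites into age-associated
  differentially methylated clusters, aDMCs (`callADMC()`)
- tests of group-dependent aging rates, e.g. by metabolic-syndrome
  status (`testDifferentialAging()`, `diffAgingScan()`)
- Fisher's-exact gene-set over-representation of cluster genes
  (`enrichClusters()`)
- a synthetic cohort generator with known truth (`simulateCohort()`),
  so the whole chain is testable without cohort data.

## The model

For one probe, the M value of individual *i* is

    Y_i = mu + X_i beta + g_i + e_i

with fixed effects X (age in years, sex, five of six blood cell
proportions), a polygenic random effect g and an iid residual e, and

    cov(Y_i, Y_j) = 2 phi_ij sigma2_g   (i != j)
    var(Y_i)      = sigma2_g + sigma2_e

where phi_ij is the kinship coefficient (2 phi = expected proportion of
alleles shared identical by descent, from the pedigree recursion).
Parameters are estimated by maximum likelihood: one eigendecomposition
of 2Φ per scan rotates the problem so that each probe needs only a
bounded 1-D search over the variance ratio h² = σ²g/(σ²g+σ²ε), with
closed-form fixed effects. The age P value is a χ²(1) likelihood-ratio
test; genome-wide significance is α divided by the number of probes
tested (0.05 / 137,168 ≈ 3.65 × 10⁻⁷ at the scale of a filtered 450K
panel). Clusters of significant sites are called when ≥ 50% of no fewer
than 10 post-QC probes in a ≤ 10 kb-gap chain are significant, and
labeled positive / negative / varying by slope signs.

## Worked example

```r
library(famEWAS)

## kinship from a parent-parent-child trio: 2*phi
trio <- Pedigree(data.frame(family = "f1", id = c("F", "M", "C"),
    father = c(NA, NA, "F"), mother = c(NA, NA, "M"),
    sex = c("male", "female", "female")))
2 * kinshipMatrix(trio)
#>     F   M   C
#> F 1.0 0.0 0.5
#> M 0.0 1.0 0.5
#> C 0.5 0.5 1.0

## default synthetic cohort: 7 extended families, 2,000 probes of which
## 60 carry true age slopes (0.02-0.04 M-units/year, 64% positive),
## 3 planted dense clusters
cohort <- simulateCohort(SimConfig(seed = 1))
cohort
#> SynthCohort: 2000 probes x 203 samples (60 age probes)

out <- runPipeline(cohort)
out$summary$n_probes_tested   # 1886  (114 probes fail the beta-range filter)
out$summary$n_significant     # 55    (26 positive, 29 negative slopes)
out$admcs[, c("chromosome", "start", "end", "n_probes_in_span",
              "n_significant", "direction", "genes")]
#>   chromosome    start      end n_probes_in_span n_significant direction   genes
#> 1          1  1000000  1011000               11            11  positive CLGENE1
#> 2          2  6000000  6011000               11            11  negative CLGENE2
#> 3          3 11000000 11011000               10            10  negative CLGENE3
```

The scan tests each probe's age slope in the kinship mixed model at the
Bonferroni threshold (0.05/1886 ≈ 2.7 × 10⁻⁵ here); the three called
aDMCs are exactly the three planted clustered regions, with their
planted directions. Real-data mode reads the same file formats the
simulator writes (`loadCohortFiles()`: PED pedigree, phenotype TSV,
probe × sample matrix TSV, annotation TSV) plus a cell-type reference
TSV and GMT gene sets.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch — simulating the default cohort and executing the full pipeline
(QC → deconvolution → EWAS → aDMC calling → differential aging →
enrichment) — and writes its JSON output to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

See `vignettes/famEWAS-methods.Rmd` for the model, the numerical
choices, what the simulator does and does not emulate, and known
limitations.
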