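---
title: "famEWAS: kinship-aware analysis of age-associated DNA methylation in families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{famEWAS: kinship-aware analysis of age-associated DNA methylation in families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famEWAS)
```

## The problem

DNA methylation at many CpG sites drifts with age, and family cohorts are
a powerful design for mapping that drift: extended pedigrees reduce
between-subject genetic heterogeneity and widen the in-sample age range.
The price is that relatives are not independent — methylation is
substantially heritable — so a per-probe regression of methylation on age
must model the familial correlation or its test statistics will be
miscalibrated.

famEWAS implements the full analysis chain for this design: pedigree
kinship, array-style QC, blood cell-type deconvolution, a per-CpG
polygenic linear mixed model, positional clustering of significant sites
into age-associated differentially methylated clusters (aDMCs),
group-dependent aging-rate tests (e.g. by metabolic-syndrome status), and
gene-set over-representation. A synthetic cohort generator with known
truth makes every stage testable without access to any cohort data.

## The trait model

For one probe, the M value of individual $i$ is modeled as

$$Y_i = \mu + \mathbf{X}_i \boldsymbol\beta + g_i + \varepsilon_i$$

with fixed effects $\mathbf{X}_i$ (age in years, sex, five of six blood
cell proportions), an additive polygenic random effect $g$, and an iid
residual. The covariance decomposition is

$$\mathrm{cov}(Y_i, Y_j) = 2\phi_{ij}\,\sigma^2_g \ (i \ne j), \qquad
  \mathrm{cov}(Y_i, Y_i) = \sigma^2_g + \sigma^2_\varepsilon,$$

where $\phi_{ij}$ is the kinship coefficient and $2\phi_{ij}$ the
expected proportion of alleles shared identical by descent.
`kinshipMatrix()` computes $\Phi$ from a PED-like pedigree by the
standard recursion (founders unrelated, $\phi_{ii} = \tfrac12 +
\tfrac12\phi_{fm}$, $\phi_{ij} = \tfrac12(\phi_{f(i)j} +
\phi_{m(i)j})$); half-relationships are encoded by one shared parent and
a missing parent is treated as an unobserved founder. The recursion
yields the textbook values exactly (parent--offspring $2\phi = 1/2$,
first cousins $1/8$, second cousins $1/32$, ...), which the test suite
pins for every unambiguous relationship class.

```{r kinship}
ped <- simulatePedigree(SimConfig(nFamilies = 1, generations = 4, seed = 1))
phi <- kinshipMatrix(ped)
table(round(2 * phi[upper.tri(phi)], 4))
```

## Maximum-likelihood estimation

Estimation is by ML, not REML. Writing $2\Phi = U D U^\top$ once per
scan, rotating $y$ and $X$ by $U^\top$ diagonalizes the covariance to
$\sigma^2_p\{h^2 D + (1 - h^2) I\}$ with $h^2 =
\sigma^2_g/\sigma^2_p$. For fixed $h^2$ the fixed effects and
$\sigma^2_p$ have closed weighted-least-squares forms, so the fit
reduces to a bounded 1-D search over $h^2 \in [0, 1 - 10^{-6}]$
(`optimize`, tolerance $10^{-8}$, boundary values checked explicitly).
The rotated likelihood is verified against a dense multivariate-normal
evaluation in the tests. The age P value is a likelihood-ratio
$\chi^2_1$ comparing ML fits with and without the age column (a Wald
mode is available as a cross-check; for very strong signals the LRT
saturates at $n\log(\mathrm{RSS}_0/\mathrm{RSS}_1)$ while the Wald z
keeps growing, so the two agree only away from saturation). Genome-wide
significance is Bonferroni: $\alpha$ divided by the number of probes
tested.

Numerical conventions: a perfectly fitted probe (zero residual) floors
$\sigma^2_p$ rather than producing an infinite likelihood; a constant
tested column returns $P = 1$ by convention (zero LRT); a singular
design is an error; any other per-probe failure is flagged
`converged = FALSE` and never aborts the scan. Because ML variance
estimates are slightly biased at small $n$, the LRT is mildly
anticonservative in small samples (analytically, the rejection rate at
nominal 0.05 is about 0.057 at $n = 100$ and 0.053 at $n = 200$ for
this design); the calibration checks therefore run at $n = 200$.

## QC and transforms

`runQC()` applies, in order: the detection filter (a probe is removed
when its detection P is $\ge 0.01$ in more than 5% of samples — exactly
5% is kept), a user-supplied exclusion list (cross-reactive and
polymorphic probes; the published lists are inputs, not package
content), and the $\beta$-range filter (removed when $\max\beta -
\min\beta < 0.17$, the platform's discrimination limit; the boundary is
kept). Each filter is a per-probe predicate, so the retained set is
order-independent. $\beta = I_m/(I_u + I_m + \alpha)$ and $M =
\log_2\{(I_m+\alpha)/(I_u+\alpha)\}$ use offset $\alpha = 100$ by
default (the platform convention; configurable). `betaToM()`/`mToBeta()`
are the logit2 pair; $\beta \in \{0,1\}$ is clamped to $[10^{-6},
1-10^{-6}]$ with a warning. Quantile normalization
(`quantileNormalize()`, via limma) is optional — the pipeline expects
pre-normalized $\beta$ in real-data mode, since probe-type correction
and color-bias adjustment are platform-specific steps outside this
package's scope.

## Cell-type deconvolution

Bulk blood methylation mixes six cell populations (granulocytes, CD4+ T,
CD8+ T, monocytes, NK, B). `estimateCellProportions()` fits each
sample's $\beta$ at discriminating probes as a non-negative mixture of
reference profiles (Lawson--Hanson NNLS, then rescaling to sum to 1) —
contractually equivalent to the constrained quadratic program of
reference-based deconvolution, with exact recovery of noiseless
mixtures. Five of the six proportions enter the design (all six are
collinear with the intercept); granulocytes, the largest fraction, are
dropped by default. Which five are used is a reparameterization: fitted
values are invariant to the choice, which the tests verify.

## aDMC calling

Significant probes are clustered per chromosome by chained gaps: a run
continues while consecutive sites are within 10 kb (inclusive).
A candidate becomes an aDMC only if the inclusive position span of its
members contains at least 10 post-QC probes and at least 50% of those
are genome-wide significant — the denominator uses all post-QC probes in
the span, which corrects for array probe density. Clusters are labeled
`positive`/`negative` when all significant members' slopes share a sign,
else `varying`; the three labels always partition the cluster set. An
all-pairs variant (cluster diameter $\le$ 10 kb rather than consecutive
gaps) is available behind `method = "allpairs"`, since the two readings
of "within 10 kb" differ; the chained rule is the default because it is
what positional cluster-makers implement.

## Differential aging by group

`testDifferentialAging()` asks whether the aging rate at a probe differs
between adults with and without a binary condition (here metabolic
syndrome; children, for whom the classification is undefined, are
excluded). Three nested kinship-aware models are fitted: pooled,
equal-slopes (group intercept only), and full (group intercept +
age-by-group interaction). The equal-slopes test is the LRT on the
interaction; the equal-intercepts test is the LRT on the group main
effect in the no-interaction model; both are reported separately since a
joint test answers a different question. Group slopes are the
reference-group coefficient and its sum with the interaction. Kinship is
retained in this sub-analysis (the conservative, consistent choice); an
unrelated-OLS mode exists for comparison. P values are reported at
nominal 0.05 without multiple-test correction, as the screen is run on a
small pre-specified candidate set.

## Enrichment

`enrichClusters()` takes the union of gene symbols from clusters of one
direction and tests each user-supplied gene set (GMT format) with the
one-sided hypergeometric tail $P(X \ge k)$ — Fisher's exact test of
over-representation — followed by Benjamini--Hochberg adjustment across
sets (Bonferroni available). The default background is the genes
carrying at least one post-QC probe, controlling for array coverage the
same way the cluster denominator does; a whole-annotation background can
be supplied instead. The package ships no pathway content.

## The synthetic cohort: what it emulates

`simulateCohort()` generates the stated world the pipeline is validated
in:

* **Pedigree**: 7 families × 4 generations, 3 offspring per mating, two
  children per generation marrying in unrelated founders — 203
  individuals, the scale of a large extended-family cohort, realizing
  parent--offspring through first-cousin (and deeper) relationship
  classes.
* **Ages** 6--85 years, uniform within generation bands (oldest
  generation first), so age and pedigree depth are realistically
  confounded.
* **Methylation**: per probe, $M = \mu_p + b_p\,\mathrm{age} +
  s_p\,\mathrm{male} + C\gamma_p + g + \varepsilon$ with $g \sim
  \mathcal N(0,\, 2\Phi\sigma^2_g)$ drawn through the symmetric
  eigendecomposition square root of $2\Phi$ (robust to semidefiniteness,
  unlike Cholesky). Defaults: $h^2 = 0.5$ (methylation heritability in
  blood is commonly reported in the 0.3--0.5 range; no cohort-calibrated
  value exists, so this is a fixed free choice), $\sigma_\varepsilon =
  0.3$ M-units, sex effects sd 0.1, cell-composition effects sd 0.5.
* **Age effects**: 60 of 2,000 probes carry slopes of magnitude
  0.02--0.04 M-units/year — the observed order of magnitude for
  age-drifting CpGs — with 64% positive sign, matching the roughly
  1.8:1 excess of methylation gains over losses reported for blood.
* **Clusters**: 3 regions of 12 age probes spaced 1 kb apart (each
  region one sign), background probes 50 kb apart so they can never
  chain; the cluster caller must recover exactly the planted regions.
* **Cell proportions**: Dirichlet around whole-blood means
  (granulocytes 0.60, CD4 0.15, CD8 0.08, monocytes 0.08, NK 0.05,
  B 0.04), emitted as truth.
* **Metabolic syndrome**: assigned to adults (age $\ge$ 18) at
  prevalence 0.24; 4 designated interaction probes get group slope
  $-0.37 \times b_p$, reproducing the reported pattern of aging rates
  that differ several-fold and flip sign between groups.

One master seed drives every stage through fixed per-stage substreams,
so a cohort is byte-reproducible.

What the generator does **not** emulate: probe type I/II chemistry,
batch and chip effects, raw two-color intensities, non-linear age
trajectories, and inbred matings. A green end-to-end test therefore
establishes the statistical machinery — calibration, recovery, and the
filtering/cluster logic — on data with the assumed covariance structure,
not robustness to array artifacts.

## Known limitations

* ML (not REML) variance components: slightly anticonservative tests in
  small samples, quantified above and covered by calibration tests.
* The $h^2$ grid is a scalar profile; probes with variance structure
  beyond polygenic + iid (e.g. shared environment) will absorb it into
  $\sigma^2_g$.
* Deconvolution quality is bounded by the reference panel; the bundled
  reference is synthetic and labeled as such.
* Cluster inference is rule-based (no permutation P for cluster counts);
  the criteria parameters are exposed and pinned by boundary tests.

## A worked run

```{r pipeline}
cfg <- SimConfig(nFamilies = 3, generations = 4, nProbes = 500,
                 nAgeProbes = 48, nClusteredRegions = 2, seed = 7)
cohort <- simulateCohort(cfg)
out <- runPipeline(cohort)
str(out$summary[c("n_probes_tested", "n_significant", "n_positive",
                  "n_negative")])
out$admcs[, c("chromosome", "start", "end", "n_probes_in_span",
              "n_significant", "direction", "genes")]
```
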