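---
title: "Testing allopatric versus ecological speciation along contact-zone transects"
author: "contactzone package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing allopatric versus ecological speciation along contact-zone transects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactzone)
```

## The scientific problem

When formerly allopatric lineages meet after their islands coalesce, two
competing speciation models make distinct predictions about nuclear genetic
structure along a transect crossing the contact zone. Under **allopatric
speciation**, reproductive isolation accumulated during spatial isolation:
nuclear genetic clusters should coincide with the old geographic
(geological) boundary, which is marked today by a steep mitochondrial-DNA
lineage transition. Under **ecological speciation** (isolation by
adaptation), gene flow is reduced where habitats change abruptly: clusters
should coincide with the ecotone — here, the transition between xeric
coastal woodland and montane rainforest — regardless of where the lineages
historically met.

`contactzone` implements the full inferential chain needed to discriminate
the two models from field-style data: mtDNA lineage assignment by in-silico
PCR-RFLP; habitat characterisation by climate PCA with ecotone detection;
quantitative-trait summarisation by canonical variates; admixture-model
Bayesian clustering of microsatellite genotypes with model-size selection;
AMOVA and standardized pairwise $F_{ST}'$; and $\phi$ goodness-of-fit tests
of genetic clusters against model-predicted categories. A synthetic
transect generator with retained ground truth makes every stage testable.

## The statistics at the core

For a $2\times2$ contingency table of genetic cluster against predicted
category, the association is measured by
$$\phi = \sqrt{\chi^2 / n},$$
with $\chi^2$ the Pearson statistic without continuity correction.
$\phi \to 1$ indicates complete association (complete isolation);
$\phi \to 0$ independence (free gene exchange). For a $2\times2$ table,
$\phi = |ad - bc| / \sqrt{(a+b)(c+d)(a+c)(b+d)}$, an identity the test
suite uses as an independent oracle.

Admixture-model clustering follows the standard Gibbs scheme: each allele
copy carries a latent cluster of origin $Z$; cluster allele frequencies $P$
receive $\mathrm{Dirichlet}(\lambda + \text{counts})$ updates; individual
membership vectors $Q$ receive $\mathrm{Dirichlet}(\alpha + \text{counts})$
updates; and the shared concentration $\alpha$ a Metropolis random walk
under a $\mathrm{Uniform}(0, \alpha_{\max}]$ prior. The number of clusters
$K$ is chosen by the model-evidence approximation
$$\widehat{\ln P(D)} = \overline{\ln L} - \tfrac{1}{2}\,
 \widehat{\mathrm{Var}}(\ln L)$$
computed from the post burn-in log-likelihood trace, maximised over $K$
(ties resolved toward the smaller $K$).

AMOVA partitions molecular variance among groups of populations
($\Phi_{CT}$), among populations within groups ($\Phi_{SC}$) and within
populations, using the mismatch (infinite-allele) distance on allele
copies, locus by locus, with the standard unbalanced-design coefficients.
The $\Phi_{CT}$ p-value permutes whole populations among groups.
Standardized differentiation $F_{ST}' = \theta / \theta_{\max}$ divides
the multilocus Weir–Cockerham estimate by its maximum attainable value,
obtained by recoding alleles so that no two populations share any allele
(which preserves within-population heterozygosity exactly).

## A worked run

```{r example, eval = FALSE}
sim <- simulateTransect(scenarioPreset("rainforest_ecotone"), seed = 1)
report <- analyzeTransect(sim$dataset,
                          config = mcmcConfig(burnin = 500, iters = 2000,
                                              nRuns = 2, kRange = 1:3),
                          seed = 1)
report
```

On this preset the report shows the package's central contrast: the
cluster-versus-ecological $\phi$ exceeds the cluster-versus-allopatric
$\phi$, the habitat-grouped AMOVA $\Phi_{CT}$ is significant while the
lineage-grouped one is not, and the mean cross-ecotone $F_{ST}'$ exceeds
the mean cross-lineage-boundary $F_{ST}'$ — the signature of ecological
rather than allopatric isolation.

## What the synthetic generator emulates

The generator is phenomenological, not demographic: it produces data with
the statistical structure the analysis consumes, under direct control of
the quantities the pipeline is supposed to recover.

* **Lineage divergence.** Each locus gets a common ancestral frequency
  vector; the two lineage pools are Dirichlet draws around it with a
  single divergence parameter $F$ (Balding–Nichols style). Presets use
  $F = 0.2$, enough for reliable two-cluster detection with 9
  microsatellite-like loci of 10 alleles, while the near-panmictic control
  uses $F = 0.02$.
* **Clines.** Site mean nuclear ancestry follows
  $\mu(x) = \mathrm{logistic}((x - c_{nuc})/w_{nuc})$; individual
  admixture is $\mathrm{Beta}(\mu\tau, (1-\mu)\tau)$ with dispersion
  $\tau = 10$. The mtDNA lineage follows its own logistic cline, so
  cyto-nuclear discordance — mtDNA boundary in one place, nuclear
  transition in another — is directly parameterisable.
* **Sampling design.** Defaults mirror the field design the framework
  targets: 5–9 sites per transect, 48 genotyped and 10 trait-measured
  individuals per site, 9 loci.
* **Climate.** The 19 bioclimatic variables are baseline + loading ×
  latent habitat factor + noise, with a fixed tropical-island measurement
  model (temperatures fall and precipitation rises toward rainforest).
  The latent factor is flat, a linear gradient, or a step of stated
  magnitude (3 latent s.d. in the ecotone preset).
* **Traits.** The 27 quantitative-trait columns (21 morphology-like, 6
  hue-like) are driven by the latent habitat factor and/or an mtDNA
  lineage effect, with total multivariate effect sizes chosen from the
  observed range of the study system (about 4–17 pooled within-group
  s.d. along a transect: 10.6 for the coastal-contact preset's lineage
  effect, 16 for the ecotone preset's habitat effect).

What it does **not** emulate: linkage, microsatellite mutation processes,
isolation by distance within sides, temporal dynamics, and spatially
autocorrelated climate noise. A green scenario test therefore establishes
that the pipeline recovers the stated structure from data of realistic
dimensions — not that the generator is a demographic model of any real
archipelago.

## Numerical and design choices

* **Climate PCA.** Variables are $\ln$-transformed ($\ln(x+1)$ only for
  columns containing zeros, since several precipitation summaries can be
  0) and column-standardized before PCA; the 19 variables mix degrees
  Celsius and millimetres, so correlation-matrix PCA is the defensible
  default. The "trend" component is the one whose site scores correlate
  most strongly (in absolute value) with position — not necessarily PC1.
* **Ecotone declaration.** The cut-point is the midpoint of the extreme
  trend scores. Because any noisy score vector can be split at its
  midpoint, a partition is only declared an *ecotone* when the labels
  change once along the transect, the between-side separation exceeds
  twice the larger within-side score range, and the trend component
  explains more than half the climatic variance. On the presets this
  calls the step profile an ecotone essentially always and the flat,
  gradient and control profiles essentially never; the thresholds are
  arguments to `ecotonePartition()`.
* **Canonical variates.** Groups are sites; scores are scaled so the
  pooled within-group s.d. is exactly 1. Axis signs are oriented so site
  means increase with position. Heteroscedasticity is flagged when the
  spread (max − min over sites) of the mean log trait variance exceeds
  `log(2)` — a two-fold geometric-mean variance ratio — in which case the
  method falls back to a PCA of standardized site means (tagged
  `pca_site_means`), rescaled to the same unit-within-s.d. convention so
  magnitudes stay comparable. A singular pooled within-group covariance
  is ridge-regularised ($\lambda = 10^{-6}\,\mathrm{tr}(W)/p$) with a
  warning. Note that with many traits and few individuals the leading
  canonical axis overfits, so observed magnitudes exceed the generating
  effect size; magnitude recovery is therefore validated on fixtures
  with adequate replication (30 individuals per site, 5 traits).
* **MCMC defaults.** $\lambda = 1$, $\alpha_{\max} = 10$, a single
  $\alpha$ shared across clusters with proposal s.d. 0.25 — the
  original program's defaults. Package defaults are desk-scale (2,000
  burn-in, 8,000 iterations, 3 runs, $K \le 4$); the field-scale
  settings (100,000 / 400,000, 10 runs, $K \le 9$) are available through
  `mcmcConfig()`. Missing allele copies contribute to no counts and no
  likelihood. Hard assignment is the arg-max of the aligned mean $Q$ at
  $K = 2$, ties to the lower cluster index; when selection chose
  $K \ne 2$ the comparative tests use a forced $K = 2$ view and set a
  flag, so control-like transects still yield comparable $\phi$ values.
* **Label alignment.** Replicate runs are aligned by a greedy cluster
  permutation maximising column-wise correlation with the first run;
  at $K \le 3$ the tests check the greedy solution against exhaustive
  enumeration.
* **AMOVA.** Mismatch distance rather than repeat-size distance (the
  framework reports $F_{ST}$-type, not $R_{ST}$-type, statistics);
  9,999 permutations by default with the +1/+1 correction; negative
  variance components are retained in the reported $\Phi$ (small negative
  $\Phi_{CT}$ values are meaningful output) but $F_{ST}'$ truncates a
  negative numerator at 0. With few sites the permutation p-value has a
  floor of roughly one over the number of distinct group assignments
  (about 0.03 for 7 sites split 3/4) — exactly the order of the
  habitat-grouping p-values the framework reports.
* **HWE/LD p-values.** Permutation tests use randomized tie-breaking,
  making the p-value exactly Uniform(0,1) under the null despite the
  discrete statistic; this is what the null-calibration tests check.
* **Correlation p-values.** Pearson $r$ with the two-sided
  $t = r\sqrt{n-2}/\sqrt{1-r^2}$ transform on $n - 2$ df, $n$ = number
  of sites (so power is low by design at 5–9 sites, as in the framework's
  tables).
* **Modal-lineage ties** exclude that site's individuals from
  category-based tests (conservative, logged) rather than guessing a
  label.

## Known limitations

* The admixture sampler implements the uncorrelated-frequency prior only
  (no F-model, no linkage model, no spatial priors), and convergence is
  summarised only through the log-likelihood trace.
* The ecotone detector assumes at most one habitat transition per
  transect; a mosaic landscape would need a different partitioner.
* $\phi$ p-values are asymptotic ($\chi^2$, 1 df); at the reported
  sample sizes ($n \approx 240$–430) this is adequate, but for very
  small transects a permutation version would be preferable.
* Site-level correlations treat sites as independent; spatial
  autocorrelation along a transect is not modelled.
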