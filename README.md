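# contactzone

Population-genetic tests of allopatric versus ecological speciation along
transects that cross secondary contact zones and habitat ecotones.

## The problem

Island coalescence brings formerly allopatric lineages into secondary
contact; habitat zonation (xeric coastal woodland vs montane rainforest)
independently creates ecotones. The two classic speciation models then make
different predictions about nuclear genetic structure along a transect:

* **allopatric speciation** — genetic clusters should track the old
  geographic boundary, marked today by a steep mtDNA lineage transition;
* **ecological speciation** (isolation by adaptation) — clusters should
  track the ecotone, wherever the lineages historically met.

`contactzone` is for population geneticists who want to run this
discrimination end to end: assign individuals to mtDNA lineages by
in-silico PCR-RFLP of a cytochrome-*b* amplicon (SspI/DraI decision tree);
characterise habitat from 19 bioclimatic variables by PCA with ecotone
detection; summarise quantitative traits by canonical variates scaled to
unit pooled within-group SD; infer nuclear structure from microsatellites
with an admixture-model Gibbs sampler (model-size selection by maximum
posterior probability of the data, replicate-run alignment), AMOVA,
standardized pairwise F<sub>ST</sub>′ and allele-frequency PCA; and
quantify the fit of genetic clusters to each speciation model with

&nbsp;&nbsp;&nbsp;&nbsp;φ = √(χ²/n)

from a 2×2 cluster-by-category table (φ → 1: complete isolation; φ → 0:
free gene exchange). A synthetic transect generator with retained ground
truth (`scenarioPreset()`, `simulateTransect()`) stands in for field data
and makes every stage testable.

## Worked example

```r
library(contactzone)
sim <- simulateTransect(scenarioPreset("rainforest_ecotone"), seed = 1)
report <- analyzeTransect(sim$dataset,
  config = mcmcConfig(burnin = 500, iters = 2000, nRuns = 2, kRange = 1:3),
  seed = 1)
report
```

```
TransectReport 'synthetic' (seed 1)
  selected K = 3
  phi(geology~lineage) = 0.950 (p = 7.24e-68, n = 336)
  phi(cluster~allopatric) = 0.551 (p = 5.46e-24, n = 336)
  phi(cluster~ecological) = 0.921 (p = 5.91e-64, n = 336)
  AMOVA by lineage: Phi_CT = 0.03613, p = 0.1870
  AMOVA by habitat: Phi_CT = 0.10176, p = 0.0380
  mean boundary FST' (lineage): 0.260
  mean boundary FST' (habitat): 0.379
```

Reading the report: the mtDNA lineages map almost perfectly onto the two
sides of the old geographic boundary (φ = 0.95 — a strong signature of
past allopatry), yet the *nuclear* clusters fit the habitat categories
(φ = 0.92) far better than the lineage categories (φ = 0.55); the AMOVA is
significant only when sites are grouped by habitat; and genetic
differentiation across the ecotone (mean F<sub>ST</sub>′ = 0.38) exceeds
that across the lineage contact (0.26). That is the signature of
ecological, not allopatric, isolation. The φ comparisons use the K = 2
cluster view (forced when model selection prefers another K, and flagged
as such in the report), so transects with K = 1 or K = 3 remain
comparable.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the full pipeline (`simulateTransect` → `analyzeTransect`) on the
rainforest-ecotone, coastal-contact and control presets at the given seed,
prints each transect report, and writes the JSON results file.

## Package layout

* `R/` — S4 classes (`Genotypes`, `TransectDataset`, `AncestryEstimate`,
  `AmovaResult`, `SpeciationTest`, `SimParams`) and the stage functions
  (`readGenepop`, `assignLineage`, `climatePca`, `ecotonePartition`,
  `cvaTraits`, `admixtureMcmc`, `runStructureScan`, `amova`,
  `fstPrime`, `meanBoundaryFstStd`, `phiFit`, `testSpeciation`,
  `analyzeTransect`, ...)
* `src/` — the admixture-model Gibbs sampler (Rcpp)
* `vignettes/contact-zone-analysis.Rmd` — the model, its assumptions,
  parameter choices and limitations
* `tests/testthat/` — unit, property and acceptance tests with
  independent oracles (closed-form φ, brute-force AMOVA, exhaustive
  permutation enumeration)
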