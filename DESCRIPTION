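Package: contactzone
Title: Population-Genetic Tests of Allopatric Versus Ecological Speciation
    Along Secondary Contact Transects
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discriminating allopatric from ecological speciation
    along geographic transects that cross secondary contact zones and
    habitat ecotones. Individuals are assigned to mitochondrial lineages by
    in-silico PCR-RFLP of cytochrome-b amplicons; habitat is characterised
    by principal component analysis of multivariate climate; quantitative
    traits are summarised by canonical variates scaled to unit pooled
    within-group standard deviation; nuclear genetic structure is inferred
    from microsatellites with an admixture-model Bayesian clustering Gibbs
    sampler, AMOVA, standardized pairwise FST', and allele-frequency PCA;
    and the fit of genetic clusters to competing speciation models is
    quantified with the phi coefficient from 2x2 contingency tables. A
    synthetic transect generator with retained ground truth supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
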