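#' @import methods
#' @importFrom stats cor cor.test prcomp pchisq pt rbeta rbinom rgamma rnorm
#'   runif sd setNames var complete.cases quantile
#' @importFrom utils head read.csv
#' @useDynLib contactzone, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Diploid multiallelic genotypes with site membership
#'
#' Container for co-dominant diploid genotypes (microsatellite fragment sizes
#' or arbitrary integer allele codes) at a set of loci, with each individual
#' belonging to exactly one site (population).  Missing allele copies are
#' \code{NA}; a heterozygous call with one missing copy is representable.
#'
#' @slot calls integer array of dimension individuals x loci x 2; allele codes
#'   are non-negative integers, \code{NA} = missing copy.
#' @slot siteOf named character vector mapping each individual to its site id,
#'   in the same order as the rows of \code{calls}.
#'
#' @seealso [readGenepop()], [writeGenepop()], [alleleCounts()]
#' @export
setClass("Genotypes",
  representation(calls = "array", siteOf = "character"))

setValidity("Genotypes", function(object) {
  d <- dim(object@calls)
  msg <- character()
  if (length(d) != 3L || d[3] != 2L)
    msg <- c(msg, "calls must be an individuals x loci x 2 array")
  if (!is.integer(object@calls))
    msg <- c(msg, "allele codes must be integer")
  if (any(object@calls < 0L, na.rm = TRUE))
    msg <- c(msg, "allele codes must be non-negative")
  if (length(object@siteOf) != d[1])
    msg <- c(msg, "siteOf must name a site for every individual")
  if (is.null(rownames(object@calls)) ||
      anyDuplicated(rownames(object@calls)))
    msg <- c(msg, "individual ids (rownames of calls) must be unique")
  if (!identical(names(object@siteOf), rownames(object@calls)))
    msg <- c(msg, "names(siteOf) must equal the individual ids, in order")
  if (length(msg)) msg else TRUE
})

#' Construct a Genotypes object
#'
#' @param calls individuals x loci x 2 integer array (or numeric, coerced);
#'   rownames are individual ids, second-dimension names are locus names.
#' @param siteOf character vector of site ids, one per individual (recycled
#'   names taken from \code{calls} rownames when unnamed).
#' @return A [Genotypes-class] object.
#' @examples
#' calls <- array(c(1L, 2L, 3L, 3L), dim = c(1, 2, 2),
#'                dimnames = list("ind1", c("locA", "locB"), NULL))
#' g <- Genotypes(calls, siteOf = "site1")
#' nInd(g)
#' @export
Genotypes <- function(calls, siteOf) {
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("ind_", seq_len(dim(calls)[1]))
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("locus_", seq_len(dim(calls)[2]))
  siteOf <- as.character(siteOf)
  if (length(siteOf) == 1L) siteOf <- rep(siteOf, dim(calls)[1])
  names(siteOf) <- rownames(calls)
  new("Genotypes", calls = calls, siteOf = siteOf)
}

#' Ordered transect dataset
#'
#' The universal pipeline input: an ordered series of sampling sites along a
#' geographic transect, with per-individual nuclear genotypes, mtDNA lineage
#' assignments, per-site climate vectors and per-site quantitative-trait
#' matrices.
#'
#' @slot transectId single character label.
#' @slot sites data.frame with columns \code{site} (character, unique),
#'   \code{position} (numeric, strictly increasing) and optionally
#'   \code{habitat}; rows define the site order.
#' @slot climate numeric matrix, sites x climate variables (19 Worldclim-style
#'   bioclimatic variables by convention), rownames = site ids.
#' @slot genotypes a [Genotypes-class] object whose sites all appear in
#'   \code{sites}.
#' @slot mtdnaLineage named character vector, individual -> lineage label;
#'   \code{NA} = unassigned.
#' @slot traits named list (by site id) of numeric matrices, trait-measured
#'   individuals x named traits.
#' @export
setClass("TransectDataset",
  representation(transectId = "character", sites = "data.frame",
                 climate = "matrix", genotypes = "Genotypes",
                 mtdnaLineage = "character", traits = "list"))

setValidity("TransectDataset", function(object) {
  msg <- character()
  s <- object@sites
  if (!all(c("site", "position") %in% names(s)))
    msg <- c(msg, "sites must have columns 'site' and 'position'")
  else {
    if (anyDuplicated(s$site)) msg <- c(msg, "site ids must be unique")
    if (is.unsorted(s$position, strictly = TRUE))
      msg <- c(msg, "site positions must be strictly increasing")
    if (!all(siteOf(object@genotypes) %in% s$site))
      msg <- c(msg, "every genotyped individual's site must appear in sites")
    if (nrow(object@climate) &&
        !identical(rownames(object@climate), as.character(s$site)))
      msg <- c(msg, "climate rownames must equal the site ids, in order")
    if (length(object@traits) &&
        !all(names(object@traits) %in% s$site))
      msg <- c(msg, "trait matrices must be keyed by known site ids")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TransectDataset
#'
#' @param transectId transect label.
#' @param sites data.frame with \code{site}, \code{position}, optional
#'   \code{habitat}.
#' @param genotypes a [Genotypes-class] object.
#' @param climate sites x variables numeric matrix (rownames = site ids);
#'   may have zero columns when climate was not recorded.
#' @param mtdnaLineage named character individual -> lineage (default: all
#'   unassigned).
#' @param traits named list of per-site trait matrices (default: none).
#' @return A [TransectDataset-class] object.
#' @export
TransectDataset <- function(transectId, sites, genotypes,
                            climate = NULL, mtdnaLineage = NULL,
                            traits = list()) {
  sites <- as.data.frame(sites)
  sites$site <- as.character(sites$site)
  if (is.null(climate)) {
    climate <- matrix(numeric(0), nrow = nrow(sites), ncol = 0)
    rownames(climate) <- sites$site
  }
  if (is.null(mtdnaLineage)) {
    mtdnaLineage <- rep(NA_character_, nInd(genotypes))
    names(mtdnaLineage) <- individualIds(genotypes)
  }
  new("TransectDataset", transectId = as.character(transectId),
      sites = sites, climate = climate, genotypes = genotypes,
      mtdnaLineage = mtdnaLineage, traits = traits)
}

#' Single-run admixture-model ancestry estimate
#'
#' Posterior summaries of one MCMC run of the admixture model: per-individual
#' membership proportions Q, per-cluster allele frequencies P, the posterior
#' mean of the admixture concentration alpha, and the model-evidence score
#' lnPD used for choosing the number of clusters.
#'
#' @slot K integer number of clusters.
#' @slot Q individuals x K matrix of posterior-mean membership proportions;
#'   rows sum to 1.
#' @slot P named list (by locus) of K x alleles posterior-mean frequency
#'   matrices; rows sum to 1.
#' @slot alpha posterior mean of the Dirichlet concentration.
#' @slot lnPD model-evidence score (mean minus half the variance of the
#'   log-likelihood trace).
#' @slot trace numeric vector: thinned log-likelihood trace.
#' @export
setClass("AncestryEstimate",
  representation(K = "integer", Q = "matrix", P = "list",
                 alpha = "numeric", lnPD = "numeric", trace = "numeric"))

setValidity("AncestryEstimate", function(object) {
  msg <- character()
  if (ncol(object@Q) != object@K)
    msg <- c(msg, "Q must have K columns")
  if (any(abs(rowSums(object@Q) - 1) > 1e-9))
    msg <- c(msg, "Q rows must sum to 1")
  for (pl in object@P)
    if (any(abs(rowSums(pl) - 1) > 1e-9))
      msg <- c(msg, "P frequency vectors must sum to 1")
  if (!is.finite(object@lnPD)) msg <- c(msg, "lnPD must be finite")
  if (length(msg)) msg else TRUE
})

#' Hierarchical AMOVA result
#'
#' Variance components of molecular variance partitioned among groups of
#' populations, among populations within groups, and within populations, with
#' the derived Phi statistics and a permutation p-value for Phi_CT.
#'
#' @slot sigma named numeric: variance components \code{amongGroups},
#'   \code{amongPopsWithin}, \code{withinPops} (summed over loci).
#' @slot phi named numeric: \code{PhiCT}, \code{PhiSC}, \code{PhiST}.
#' @slot pPhiCT permutation p-value for Phi_CT (+1/+1 corrected).
#' @slot nPerm number of permutations used.
#' @slot grouping label describing the grouping factor (e.g. "lineage",
#'   "habitat").
#' @slot ss data.frame of per-level sums of squares and degrees of freedom.
#' @export
setClass("AmovaResult",
  representation(sigma = "numeric", phi = "numeric", pPhiCT = "numeric",
                 nPerm = "integer", grouping = "character",
                 ss = "data.frame"))

setValidity("AmovaResult", function(object) {
  msg <- character()
  if (object@sigma[["withinPops"]] < 0)
    msg <- c(msg, "within-population variance component must be >= 0")
  if (any(object@phi < -1 - 1e-9 | object@phi > 1 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "Phi statistics must lie in [-1, 1]")
  if (!is.na(object@pPhiCT) &&
      (object@pPhiCT <= 0 || object@pPhiCT > 1))
    msg <- c(msg, "p-value must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Speciation-model goodness-of-fit test
#'
#' A 2x2 contingency table of genetic cluster (or mtDNA lineage) against a
#' model-predicted category, with the Pearson chi-squared statistic, the phi
#' coefficient sqrt(chi2/n) and its asymptotic p-value.
#'
#' @slot model one of "allopatric", "ecological", "geology_lineage".
#' @slot table 2x2 integer matrix (rows = genetic label, cols = category).
#' @slot chi2,phi,p,n test statistics; \code{phi = sqrt(chi2/n)}.
#' @slot K integer: number of clusters the assignment used (NA for
#'   lineage-based tests).
#' @slot forcedK TRUE when K = 2 was imposed although model selection chose a
#'   different K.
#' @slot degenerate TRUE when a zero marginal made the statistic undefined.
#' @export
setClass("SpeciationTest",
  representation(model = "character", table = "matrix", chi2 = "numeric",
                 phi = "numeric", p = "numeric", n = "integer",
                 K = "integer", forcedK = "logical", degenerate = "logical"))

setValidity("SpeciationTest", function(object) {
  msg <- character()
  if (!object@degenerate) {
    if (abs(object@phi - sqrt(object@chi2 / object@n)) > 1e-12)
      msg <- c(msg, "phi must equal sqrt(chi2/n)")
    if (object@phi < 0 || object@phi > 1 + 1e-12)
      msg <- c(msg, "phi must lie in [0, 1]")
  }
  if (any(object@table < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Generative description of a synthetic transect
#'
#' Full parameterisation of the synthetic transect generator: sampling
#' design, lineage divergence, nuclear and mitochondrial cline geometry,
#' climate profile and quantitative-trait model.  See [simulateTransect()]
#' for the generative model and [scenarioPreset()] for the four named
#' scenario presets.
#'
#' @slot nSites,nPerSite,nTraitPerSite,nLoci,allelesPerLocus sampling design
#'   (defaults 7 sites, 48 genotyped and 10 trait-measured individuals per
#'   site, 9 loci, 10 alleles per locus).
#' @slot F divergence between the two ancestral lineage allele pools
#'   (Balding-Nichols style), in [0, 1).
#' @slot nuclearCline,mtdnaCline numeric c(center, width) in site units.
#' @slot tau ancestry dispersion (> 0): Beta concentration of individual
#'   admixture around the site mean.
#' @slot climateProfile list: \code{profile} in c("flat","gradient","step"),
#'   \code{stepAfter} (last site of habitat A), \code{magnitude} (latent
#'   s.d. units), \code{noiseSd}.
#' @slot traitModel list: \code{betaClimate}, \code{deltaLineage} (total
#'   multivariate effect sizes in residual s.d. units), \code{residSd}.
#' @export
setClass("SimParams",
  representation(nSites = "integer", nPerSite = "integer",
                 nTraitPerSite = "integer", nLoci = "integer",
                 allelesPerLocus = "integer", F = "numeric",
                 nuclearCline = "numeric", mtdnaCline = "numeric",
                 tau = "numeric", climateProfile = "list",
                 traitModel = "list"))

setValidity("SimParams", function(object) {
  msg <- character()
  if (object@F < 0 || object@F >= 1) msg <- c(msg, "F must lie in [0, 1)")
  if (object@nuclearCline[2] <= 0 || object@mtdnaCline[2] <= 0)
    msg <- c(msg, "cline widths must be strictly positive")
  if (object@tau <= 0) msg <- c(msg, "tau must be strictly positive")
  n <- object@nSites
  ctrs <- c(object@nuclearCline[1], object@mtdnaCline[1])
  if (any(ctrs < 1 - 2 | ctrs > n + 2))
    msg <- c(msg, "cline centers must lie within [1, nSites] +/- 2")
  if (length(msg)) msg else TRUE
})
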