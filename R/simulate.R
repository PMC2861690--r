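#' Construct simulation parameters
#'
#' The generator is phenomenological: instead of a forward-time demographic
#' model it draws genotypes directly from two lineage allele pools (a
#' Balding-Nichols style divergence \code{F} around a common ancestral
#' frequency), places a logistic admixture cline for nuclear ancestry and an
#' independent logistic cline for the maternally inherited mtDNA lineage,
#' builds 19 bioclimatic variables from one latent habitat factor, and
#' drives quantitative traits by that factor plus an optional lineage
#' effect.  Direct control of cline centers and widths gives clean oracles
#' for every downstream stage.
#'
#' @param nSites number of sites along the transect.
#' @param nPerSite genotyped individuals per site (field design: 48).
#' @param nTraitPerSite trait-measured individuals per site (field: 10
#'   adult males).
#' @param nLoci microsatellite loci (field: 9).
#' @param allelesPerLocus alleles segregating per locus.
#' @param F divergence between the two lineage allele pools, in [0, 1).
#' @param nuclearCline,mtdnaCline numeric \code{c(center, width)} in site
#'   units; ancestry / lineage-B probability is
#'   \code{plogis((x - center)/width)}.
#' @param tau Beta concentration of individual admixture proportions around
#'   the site mean.
#' @param climateProfile list with \code{profile} ("flat", "gradient" or
#'   "step"), \code{stepAfter} (last site of habitat A for the step
#'   profile), \code{magnitude} (latent step/gradient size in units of the
#'   latent factor's s.d.), \code{noiseSd} (per-variable noise multiplier).
#' @param traitModel list with \code{betaClimate} and \code{deltaLineage}
#'   (total multivariate effect magnitudes in residual s.d. units, spread
#'   evenly over the 27 trait columns) and \code{residSd}.
#' @param lineageLabels labels for the two lineages (A side, B side).
#' @return A [SimParams-class] object.
#' @export
simParams <- function(nSites = 7L, nPerSite = 48L, nTraitPerSite = 10L,
                      nLoci = 9L, allelesPerLocus = 10L, F = 0.2,
                      nuclearCline = c(center = 3.5, width = 0.4),
                      mtdnaCline = c(center = 3.5, width = 0.2),
                      tau = 10,
                      climateProfile = list(profile = "flat",
                                            stepAfter = NA, magnitude = 0,
                                            noiseSd = 1),
                      traitModel = list(betaClimate = 0, deltaLineage = 0,
                                        residSd = 1),
                      lineageLabels = c("central", "northwest")) {
  cp <- utils::modifyList(list(profile = "flat", stepAfter = NA,
                               magnitude = 0, noiseSd = 1), climateProfile)
  tm <- utils::modifyList(list(betaClimate = 0, deltaLineage = 0,
                               residSd = 1), traitModel)
  cp$lineageLabels <- NULL
  if (!cp$profile %in% c("flat", "gradient", "step"))
    stop("unknown climate profile: ", cp$profile)
  tm$lineageLabels <- lineageLabels
  new("SimParams", nSites = as.integer(nSites),
      nPerSite = as.integer(nPerSite),
      nTraitPerSite = as.integer(nTraitPerSite),
      nLoci = as.integer(nLoci),
      allelesPerLocus = as.integer(allelesPerLocus), F = F,
      nuclearCline = unname(nuclearCline), mtdnaCline = unname(mtdnaCline),
      tau = tau, climateProfile = cp, traitModel = tm)
}

#' Named scenario presets mirroring the transect archetypes
#'
#' \describe{
#'   \item{coastal_contact}{steep, co-located nuclear and mtDNA clines in a
#'     climatically flat coastal strip, with a large lineage effect on
#'     quantitative traits (a coastal secondary contact).}
#'   \item{rainforest_ecotone}{nuclear cline centered on an abrupt climate
#'     step (xeric coast to montane rainforest) while the mtDNA boundary
#'     lies elsewhere; traits track habitat, not lineage.}
#'   \item{mesic_contact}{shallow nuclear cline at the mtDNA boundary under
#'     a gentle climate gradient within the mesic zone.}
#'   \item{control}{no clines: one mtDNA lineage, near-zero divergence,
#'     flat climate (a control transect).}
#' }
#' Effect magnitudes follow the observed ranges of the study system:
#' quantitative-trait separations of roughly 4-17 pooled within-group s.d.
#' along a transect, climate steps of a few latent s.d. at the ecotone.
#'
#' @param name one of \code{"coastal_contact"}, \code{"rainforest_ecotone"},
#'   \code{"mesic_contact"}, \code{"control"}.
#' @return A [SimParams-class] object.
#' @export
scenarioPreset <- function(name) {
  switch(name,
    coastal_contact = simParams(
      nSites = 8L, F = 0.2,
      nuclearCline = c(4.5, 0.3), mtdnaCline = c(4.5, 0.15), tau = 10,
      climateProfile = list(profile = "flat", magnitude = 0, noiseSd = 1),
      traitModel = list(betaClimate = 0, deltaLineage = 10.6, residSd = 1)),
    rainforest_ecotone = simParams(
      nSites = 7L, F = 0.2,
      nuclearCline = c(3.5, 0.4), mtdnaCline = c(5.5, 0.2), tau = 10,
      climateProfile = list(profile = "step", stepAfter = 3L,
                            magnitude = 3, noiseSd = 1),
      traitModel = list(betaClimate = 16, deltaLineage = 0, residSd = 1)),
    mesic_contact = simParams(
      nSites = 9L, F = 0.2,
      nuclearCline = c(4.5, 1.5), mtdnaCline = c(4.5, 0.2), tau = 10,
      climateProfile = list(profile = "gradient", magnitude = 1.2,
                            noiseSd = 1),
      traitModel = list(betaClimate = 5, deltaLineage = 0, residSd = 1),
      lineageLabels = c("central", "southwest")),
    control = simParams(
      nSites = 5L, F = 0.02,
      nuclearCline = c(3, 1000), mtdnaCline = c(7, 0.2), tau = 10,
      climateProfile = list(profile = "flat", magnitude = 0, noiseSd = 1),
      traitModel = list(betaClimate = 0, deltaLineage = 0, residSd = 1),
      lineageLabels = c("central", "central_b")),
    stop("unknown scenario preset: ", name))
}

# Fixed bioclimatic measurement model: baseline (tropical island profile),
# loading on the latent habitat factor (montane = cooler, wetter), and the
# per-variable noise scale multiplied by climateProfile$noiseSd.
.climateModel <- function() {
  v <- climateVariableNames()
  baseline <- c(25.5, 8.2, 0.72, 1.1, 30.5, 19.5, 11.0, 25.8, 25.0, 26.4,
                24.6, 1800, 260, 40, 45, 700, 160, 520, 420)
  loading <- c(-0.8, -0.3, 0.01, -0.05, -0.9, -0.7, -0.2, -0.8, -0.8,
               -0.85, -0.75, 350, 45, 12, -2, 130, 35, 95, 80)
  scale <- c(0.15, 0.10, 0.01, 0.02, 0.20, 0.20, 0.15, 0.15, 0.15, 0.15,
             0.15, 30, 8, 3, 1.5, 15, 6, 12, 10)
  list(names = v, baseline = setNames(baseline, v),
       loading = setNames(loading, v), scale = setNames(scale, v))
}

# latent habitat factor per site, in latent s.d. units
.latentFactor <- function(cp, positions) {
  n <- length(positions)
  switch(cp$profile,
    flat = rep(0, n),
    gradient = cp$magnitude * (positions - positions[1]) /
      (positions[n] - positions[1]),
    step = ifelse(positions > cp$stepAfter, cp$magnitude, 0))
}

#' Simulate a transect dataset with retained ground truth
#'
#' Generative model, in order: (a) for each locus a common ancestral
#' frequency vector is drawn and the two lineage pools are drawn around it
#' with Balding-Nichols divergence \code{F}; (b) site mean ancestry follows
#' the logistic nuclear cline; (c) each individual's admixture proportion
#' \code{q} is Beta-distributed around the site mean with concentration
#' \code{tau}; (d) each allele copy comes from lineage pool B with
#' probability \code{q}, else pool A; (e) the mtDNA lineage is Bernoulli
#' along its own logistic cline; (f) the 19 climate variables are baseline +
#' loading x latent habitat factor + noise; (g) the 27 quantitative traits
#' (21 morphology-like, 6 hue-like) are driven by the latent habitat factor
#' and the individual's mtDNA lineage.
#'
#' @param params a [SimParams-class] object (see [scenarioPreset()]).
#' @param seed integer seed; with a fixed seed the output is byte-identical
#'   across runs.
#' @return list with \code{dataset} (a [TransectDataset-class]) and
#'   \code{truth} (a \code{TruthRecord} list: per-individual \code{qTrue},
#'   per-site \code{siteMeanAncestry}, \code{habitat} labels, the echoed
#'   \code{params} and \code{seed}).
#' @examples
#' sim <- simulateTransect(scenarioPreset("control"), seed = 1)
#' sim$dataset
#' @export
simulateTransect <- function(params, seed) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  set.seed(as.integer(seed))
  nS <- params@nSites; nI <- params@nPerSite; nL <- params@nLoci
  A <- params@allelesPerLocus
  positions <- seq_len(nS)
  siteIds <- paste0("site_", positions)
  labs <- params@traitModel$lineageLabels

  ## (a) lineage allele pools
  alleleCodes <- 100L + 2L * seq_len(A)
  pools <- vector("list", nL)
  for (l in seq_len(nL)) {
    anc <- .rdirichlet(rep(1, A))
    if (params@F == 0) {
      p1 <- p2 <- anc
    } else {
      conc <- anc * (1 - params@F) / params@F
      p1 <- .rdirichlet(conc); p2 <- .rdirichlet(conc)
    }
    pools[[l]] <- rbind(p1, p2)
  }

  ## (b)-(d) ancestry and genotypes
  muSite <- stats::plogis((positions - params@nuclearCline[1]) /
                          params@nuclearCline[2])
  pMt <- stats::plogis((positions - params@mtdnaCline[1]) /
                       params@mtdnaCline[2])
  ids <- paste0(rep(siteIds, each = nI), "_ind",
                sprintf("%02d", rep(seq_len(nI), nS)))
  siteOfInd <- rep(siteIds, each = nI)
  qTrue <- numeric(nS * nI)
  calls <- array(NA_integer_, dim = c(nS * nI, nL, 2L),
                 dimnames = list(ids, paste0("locus_", seq_len(nL)), NULL))
  mtdna <- character(nS * nI)
  for (s in seq_len(nS)) {
    idx <- (s - 1L) * nI + seq_len(nI)
    mu <- min(max(muSite[s], 1e-12), 1 - 1e-12)
    q <- rbeta(nI, mu * params@tau, (1 - mu) * params@tau)
    qTrue[idx] <- q
    for (l in seq_len(nL)) {
      fromB <- matrix(runif(2L * nI) < q, nrow = nI)  # recycles q by column
      pA <- pools[[l]][1L, ]; pB <- pools[[l]][2L, ]
      for (cpy in 1:2) {
        nB <- sum(fromB[, cpy])
        draw <- integer(nI)
        if (nB) draw[fromB[, cpy]] <-
            sample.int(A, nB, replace = TRUE, prob = pB)
        if (nB < nI) draw[!fromB[, cpy]] <-
            sample.int(A, nI - nB, replace = TRUE, prob = pA)
        calls[idx, l, cpy] <- alleleCodes[draw]
      }
    }
    mtdna[idx] <- labs[1L + rbinom(nI, 1L, pMt[s])]
  }
  names(qTrue) <- ids
  names(mtdna) <- ids
  g <- Genotypes(calls, siteOf = siteOfInd)

  ## (f) climate
  cm <- .climateModel()
  f <- .latentFactor(params@climateProfile, positions)
  noise <- params@climateProfile$noiseSd
  climate <- matrix(0, nS, length(cm$names),
                    dimnames = list(siteIds, cm$names))
  for (s in seq_len(nS))
    climate[s, ] <- cm$baseline + cm$loading * f[s] +
      rnorm(length(cm$names), 0, noise * cm$scale)
  climate[, grep("precip", colnames(climate))] <-
    pmax(climate[, grep("precip", colnames(climate))], 0)

  ## (g) traits: 21 morphology-like + 6 hue-like columns
  nT <- params@nTraitPerSite
  traitNames <- c(sprintf("morph_%02d", 1:21), sprintf("hue_%d", 1:6))
  p <- length(traitNames)
  sgn <- rep(c(1, -1), length.out = p)
  gx <- if (max(abs(f)) > 0) f / max(abs(f)) else rep(0, nS)
  tm <- params@traitModel
  betaPer <- sgn * tm$betaClimate / sqrt(p)
  deltaPer <- sgn * tm$deltaLineage / sqrt(p)
  traits <- vector("list", nS); names(traits) <- siteIds
  for (s in seq_len(nS)) {
    linB <- rbinom(nT, 1L, pMt[s])
    m <- matrix(rnorm(nT * p, 0, tm$residSd), nT, p,
                dimnames = list(paste0(siteIds[s], "_qt", seq_len(nT)),
                                traitNames))
    m <- m + rep(betaPer * gx[s], each = nT) + outer(linB, deltaPer)
    traits[[s]] <- m
  }

  habitat <- if (params@climateProfile$profile == "step")
    ifelse(positions > params@climateProfile$stepAfter, "B", "A")
  else rep("A", nS)

  sites <- data.frame(site = siteIds, position = as.numeric(positions),
                      habitat = habitat, stringsAsFactors = FALSE)
  td <- TransectDataset("synthetic", sites, g, climate = climate,
                        mtdnaLineage = mtdna, traits = traits)
  truth <- list(qTrue = qTrue,
                siteMeanAncestry = setNames(muSite, siteIds),
                habitat = setNames(habitat, siteIds),
                mtdnaProbB = setNames(pMt, siteIds),
                params = params, seed = as.integer(seed))
  class(truth) <- "TruthRecord"
  list(dataset = td, truth = truth)
}

.rdirichlet <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[which.max(alpha)] <- 1   # degenerate guard
  x / sum(x)
}
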