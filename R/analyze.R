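#' Full per-transect analysis report
#'
#' Runs the whole pipeline in order: mtDNA lineage frequencies; climate PCA
#' and ecotone partition; canonical-variate trait summary with the
#' QT-lineage and QT-climate site correlations; HWE/LD quality checks
#' (optional); admixture-model clustering over a K range with replicate
#' runs, K selection and label alignment (plus a forced K = 2 view for
#' comparison); allele-frequency PCA and its correlation with the K = 2
#' cluster site frequencies; AMOVA grouped by lineage and, when an ecotone
#' exists, by habitat; mean boundary F_ST'; and the phi goodness-of-fit
#' tests of the geological, allopatric and ecological models.  Any stage
#' error is recorded in \code{$errors} and dependent stages are skipped;
#' a report is always produced.  Identical seed and configuration give an
#' identical report.
#'
#' @param td a [TransectDataset-class].
#' @param config an [mcmcConfig()] for the clustering stage.
#' @param seed integer master seed (all stage seeds derive from it).
#' @param geologyBoundaryAfter declared geological boundary (site index of
#'   the last site of the first precursor block); default: the last site
#'   before the modal mtDNA lineage first changes.
#' @param nPermAmova permutations for the AMOVA Phi_CT tests.
#' @param runQc run the per-site HWE and per-site LD permutation tests
#'   (slower; default FALSE).
#' @param nPermQc permutations for the QC tests.
#' @return list of class \code{TransectReport}; see the individual stage
#'   functions for the component formats.
#' @export
analyzeTransect <- function(td, config = mcmcConfig(), seed = 1L,
                            geologyBoundaryAfter = NULL,
                            nPermAmova = 999L, runQc = FALSE,
                            nPermQc = 2000L) {
  stopifnot(is(td, "TransectDataset"))
  report <- list(transectId = td@transectId,
                 settings = list(config = config, seed = as.integer(seed),
                                 nPermAmova = as.integer(nPermAmova)),
                 errors = list())
  class(report) <- "TransectReport"
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, 8L)
  sites <- siteInfo(td)$site
  positions <- siteInfo(td)$position
  rec <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  ## lineage frequencies and geology boundary
  report$lineageFreqs <- rec("lineageFreqs", lineageSiteFrequencies(td))
  if (is.null(geologyBoundaryAfter) && !is.null(report$lineageFreqs)) {
    modal <- attr(report$lineageFreqs, "modal")[sites]
    chg <- which(modal[-1] != modal[-length(modal)])
    geologyBoundaryAfter <- if (length(chg)) chg[1] else NA_integer_
  }
  report$geologyBoundaryAfter <- geologyBoundaryAfter

  ## climate and ecotone
  report$climate <- rec("climate", climatePca(td))
  report$habitat <- if (!is.null(report$climate))
    rec("habitat", ecotonePartition(report$climate)) else NULL

  ## quantitative traits
  if (length(traitData(td))) {
    report$cva <- rec("cva", cvaTraits(td))
    if (!is.null(report$cva) && !is.null(report$lineageFreqs)) {
      linFreq <- .modalSideFrequency(report$lineageFreqs, sites)
      report$corQtLineage <- rec("corQtLineage",
        siteCorrelation(report$cva$siteMeans[sites], linFreq))
    }
    if (!is.null(report$cva) && !is.null(report$climate))
      report$corQtClimate <- rec("corQtClimate",
        siteCorrelation(report$cva$siteMeans[sites],
                        report$climate$scores[sites]))
  }

  ## QC
  if (runQc)
    report$qc <- rec("qc", .qcTables(genotypes(td), nPermQc, seeds[1]))

  ## clustering
  report$scan <- rec("scan",
    runStructureScan(genotypes(td), config, seed = seeds[2]))

  ## allele-frequency PCA and its fit to the K = 2 cluster frequencies
  report$pcaGeno <- rec("pcaGeno",
    alleleFreqPca(genotypes(td), positions = positions,
                  siteOrder = sites))
  if (!is.null(report$pcaGeno) && !is.null(report$scan)) {
    report$rPc1Cluster <- rec("rPc1Cluster", {
      q2 <- report$scan$meanQ2
      siteQ <- vapply(sites, function(s)
        mean(q2[siteOf(genotypes(td)) == s, 2]), 0)
      sc <- siteCorrelation(report$pcaGeno$scores[sites], siteQ)
      sc$r <- abs(sc$r)   # cluster label orientation is arbitrary
      sc
    })
  }

  ## AMOVA and boundary F_ST'
  haveEcotone <- !is.null(report$habitat) &&
    isTRUE(report$habitat$isEcotone)
  modalOk <- !is.null(report$lineageFreqs) &&
    !anyNA(attr(report$lineageFreqs, "modal")[sites]) &&
    length(unique(attr(report$lineageFreqs, "modal")[sites])) == 2L
  g <- genotypes(td)
  if (modalOk) {
    grpLin <- attr(report$lineageFreqs, "modal")[sites]
    report$amovaLineage <- rec("amovaLineage",
      amova(g, groupOf = grpLin, nPerm = nPermAmova, seed = seeds[3],
            grouping = "lineage"))
    report$fstLineage <- rec("fstLineage",
      meanBoundaryFstStd(td, boundary = "lineage"))
  }
  if (haveEcotone) {
    grpHab <- report$habitat$habitat[sites]
    report$amovaHabitat <- rec("amovaHabitat",
      amova(g, groupOf = grpHab, nPerm = nPermAmova, seed = seeds[4],
            grouping = "habitat"))
    report$fstHabitat <- rec("fstHabitat",
      meanBoundaryFstStd(td, boundary = "habitat",
                         habitat = report$habitat))
  }

  ## phi goodness-of-fit tests
  if (!is.null(report$geologyBoundaryAfter) &&
      !is.na(report$geologyBoundaryAfter))
    report$phiGeology <- rec("phiGeology",
      geologyLineageFit(td, report$geologyBoundaryAfter))
  if (!is.null(report$scan)) {
    hard <- report$scan$hardAssignment
    Ksel <- report$scan$selection$K
    report$phiAllopatric <- rec("phiAllopatric",
      testSpeciation(td, hard, model = "allopatric", K = Ksel))
    if (haveEcotone)
      report$phiEcological <- rec("phiEcological",
        testSpeciation(td, hard, model = "ecological",
                       habitat = report$habitat, K = Ksel))
  }
  report
}

#' @export
print.TransectReport <- function(x, ...) {
  cat("TransectReport '", x$transectId, "' (seed ", x$settings$seed,
      ")\n", sep = "")
  if (!is.null(x$scan))
    cat("  selected K =", x$scan$selection$K,
        if (x$scan$selection$tie) "(tie)", "\n")
  fmtPhi <- function(t, lab) {
    if (is.null(t)) return(invisible())
    if (is(t, "SpeciationTest") && !t@degenerate)
      cat(sprintf("  phi(%s) = %.3f (p = %.3g, n = %d)\n",
                  lab, t@phi, t@p, t@n))
    else cat("  phi(", lab, "): not applicable / degenerate\n", sep = "")
  }
  fmtPhi(x$phiGeology, "geology~lineage")
  fmtPhi(x$phiAllopatric, "cluster~allopatric")
  fmtPhi(x$phiEcological, "cluster~ecological")
  if (!is.null(x$amovaLineage))
    cat(sprintf("  AMOVA by lineage: Phi_CT = %.5f, p = %.4f\n",
                x$amovaLineage@phi[["PhiCT"]], x$amovaLineage@pPhiCT))
  if (!is.null(x$amovaHabitat))
    cat(sprintf("  AMOVA by habitat: Phi_CT = %.5f, p = %.4f\n",
                x$amovaHabitat@phi[["PhiCT"]], x$amovaHabitat@pPhiCT))
  if (!is.null(x$fstLineage))
    cat(sprintf("  mean boundary FST' (lineage): %.3f\n", x$fstLineage$mean))
  if (!is.null(x$fstHabitat))
    cat(sprintf("  mean boundary FST' (habitat): %.3f\n", x$fstHabitat$mean))
  if (length(x$errors))
    cat("  stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

# per-site frequency of the transect's overall-second-most-common lineage
# (a monotone summary to correlate with trait clines)
.modalSideFrequency <- function(lf, sites) {
  labs <- names(sort(table(lf$lineage), decreasing = TRUE))
  target <- if (length(labs) >= 2) labs[2] else labs[1]
  vapply(sites, function(s) {
    rows <- lf$site == s
    if (!any(rows)) return(NA_real_)
    f <- lf$freq[rows & lf$lineage == target]
    if (length(f)) f else 0
  }, 0)
}

.qcTables <- function(g, nPerm, seed) {
  set.seed(seed)
  sites <- unique(siteOf(g))
  loci <- lociNames(g)
  hwe <- expand.grid(site = sites, locus = loci,
                     stringsAsFactors = FALSE)
  hwe$p <- NA_real_
  for (i in seq_len(nrow(hwe))) {
    res <- tryCatch(hweTest(g, hwe$site[i], hwe$locus[i], nPerm = nPerm,
                            seed = sample.int(1e8, 1)),
                    error = function(e) NULL)
    if (!is.null(res)) hwe$p[i] <- res$p
  }
  prs <- t(utils::combn(loci, 2))
  ld <- do.call(rbind, lapply(sites, function(s)
    data.frame(site = s, locusA = prs[, 1], locusB = prs[, 2],
               stringsAsFactors = FALSE)))
  ld$p <- NA_real_
  for (i in seq_len(nrow(ld))) {
    res <- tryCatch(ldTest(g, ld$site[i], ld$locusA[i], ld$locusB[i],
                           nPerm = nPerm, seed = sample.int(1e8, 1)),
                    error = function(e) NULL)
    if (!is.null(res)) ld$p[i] <- res$p
  }
  hwe$pBonferroni <- bonferroniAdjust(hwe$p)
  ld$pBonferroni <- bonferroniAdjust(ld$p)
  list(hwe = hwe, ld = ld)
}
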