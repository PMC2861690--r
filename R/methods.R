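#' @rdname Genotypes-class
#' @export
setMethod("nInd", "Genotypes", function(x) dim(x@calls)[1])

#' @rdname Genotypes-class
#' @export
setMethod("nLoci", "Genotypes", function(x) dim(x@calls)[2])

#' @rdname Genotypes-class
#' @export
setMethod("individualIds", "Genotypes", function(x) rownames(x@calls))

#' @rdname Genotypes-class
#' @export
setMethod("lociNames", "Genotypes", function(x) colnames(x@calls))

#' @rdname Genotypes-class
#' @export
setMethod("siteOf", "Genotypes", function(x) x@siteOf)

#' @rdname Genotypes-class
#' @export
setMethod("genotypeCalls", "Genotypes", function(x) x@calls)

#' Subset a Genotypes object by individuals
#'
#' @param x a [Genotypes-class] object.
#' @param i individual indices, ids, or a logical vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "Genotypes", function(x, i, j, ..., drop = FALSE) {
  calls <- x@calls[i, , , drop = FALSE]
  new("Genotypes", calls = calls, siteOf = x@siteOf[i])
})

setMethod("show", "Genotypes", function(object) {
  cat("Genotypes: ", nInd(object), " individuals x ", nLoci(object),
      " loci, ", length(unique(object@siteOf)), " site(s)\n", sep = "")
  miss <- mean(is.na(object@calls))
  cat(sprintf("  missing allele copies: %.1f%%\n", 100 * miss))
})

#' @rdname TransectDataset-accessors
#' @export
setMethod("siteInfo", "TransectDataset", function(x) x@sites)

#' @rdname TransectDataset-accessors
#' @export
setMethod("climateData", "TransectDataset", function(x) x@climate)

#' @rdname TransectDataset-accessors
#' @export
setMethod("genotypes", "TransectDataset", function(x) x@genotypes)

#' @rdname TransectDataset-accessors
#' @export
setMethod("mtdnaLineage", "TransectDataset", function(x) x@mtdnaLineage)

#' @rdname TransectDataset-accessors
#' @export
setMethod("traitData", "TransectDataset", function(x) x@traits)

setMethod("show", "TransectDataset", function(object) {
  cat("TransectDataset '", object@transectId, "': ",
      nrow(object@sites), " sites, ", nInd(object@genotypes),
      " genotyped individuals\n", sep = "")
  cat("  climate variables:", ncol(object@climate),
      " | trait tables:", length(object@traits), "\n")
  assigned <- sum(!is.na(object@mtdnaLineage))
  cat("  mtDNA lineage assigned:", assigned, "/",
      length(object@mtdnaLineage), "\n")
})

#' @rdname AncestryEstimate-class
#' @export
setMethod("membershipQ", "AncestryEstimate", function(x) x@Q)

#' @rdname AncestryEstimate-class
#' @export
setMethod("clusterFreqP", "AncestryEstimate", function(x) x@P)

#' @rdname AncestryEstimate-class
#' @export
setMethod("lnPD", "AncestryEstimate", function(x) x@lnPD)

setMethod("show", "AncestryEstimate", function(object) {
  cat("AncestryEstimate: K =", object@K, "|", nrow(object@Q),
      "individuals | lnPD =", format(object@lnPD, digits = 6),
      "| alpha =", format(object@alpha, digits = 4), "\n")
})

setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA (grouping:", object@grouping, ")\n")
  print(object@ss)
  cat(sprintf("  Phi_CT = %.5f (p = %.5f, %d permutations)\n",
              object@phi[["PhiCT"]], object@pPhiCT, object@nPerm))
  cat(sprintf("  Phi_SC = %.5f  Phi_ST = %.5f\n",
              object@phi[["PhiSC"]], object@phi[["PhiST"]]))
})

setMethod("show", "SpeciationTest", function(object) {
  cat("SpeciationTest [", object@model, "]\n", sep = "")
  print(object@table)
  if (object@degenerate) {
    cat("  degenerate table (zero marginal): phi undefined\n")
  } else {
    cat(sprintf("  chi2 = %.4f  phi = %.4f  p = %.3g  n = %d\n",
                object@chi2, object@phi, object@p, object@n))
  }
  if (isTRUE(object@forcedK)) cat("  note: K = 2 forced for comparison\n")
})

setMethod("show", "SimParams", function(object) {
  cat("SimParams:", object@nSites, "sites x", object@nPerSite,
      "ind;", object@nLoci, "loci; F =", object@F, "\n")
  cat("  nuclear cline c =", object@nuclearCline[1], "w =",
      object@nuclearCline[2], "| mtDNA cline c =", object@mtdnaCline[1],
      "w =", object@mtdnaCline[2], "\n")
  cat("  climate profile:", object@climateProfile$profile, "\n")
})
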