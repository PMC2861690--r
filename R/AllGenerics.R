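#' @rdname Genotypes-class
#' @param x,object a \code{Genotypes} (or other package) object.
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))

#' @rdname Genotypes-class
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname Genotypes-class
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname Genotypes-class
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))

#' @rdname Genotypes-class
#' @export
setGeneric("siteOf", function(x) standardGeneric("siteOf"))

#' @rdname Genotypes-class
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' Accessors for TransectDataset components
#'
#' @param x a [TransectDataset-class] object.
#' @return \code{siteInfo}: the ordered site data.frame; \code{climateData}:
#'   the sites x variables climate matrix; \code{genotypes}: the embedded
#'   [Genotypes-class]; \code{mtdnaLineage}: the individual -> lineage map;
#'   \code{traitData}: the per-site list of trait matrices.
#' @name TransectDataset-accessors
NULL

#' @rdname TransectDataset-accessors
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

#' @rdname TransectDataset-accessors
#' @export
setGeneric("climateData", function(x) standardGeneric("climateData"))

#' @rdname TransectDataset-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname TransectDataset-accessors
#' @export
setGeneric("mtdnaLineage", function(x) standardGeneric("mtdnaLineage"))

#' @rdname TransectDataset-accessors
#' @export
setGeneric("traitData", function(x) standardGeneric("traitData"))

#' @rdname AncestryEstimate-class
#' @param x an \code{AncestryEstimate}.
#' @export
setGeneric("membershipQ", function(x) standardGeneric("membershipQ"))

#' @rdname AncestryEstimate-class
#' @export
setGeneric("clusterFreqP", function(x) standardGeneric("clusterFreqP"))

#' @rdname AncestryEstimate-class
#' @export
setGeneric("lnPD", function(x) standardGeneric("lnPD"))
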