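#' Phi goodness of fit for a 2x2 contingency table
#'
#' Pearson chi-squared statistic without continuity correction,
#' \code{phi = sqrt(chi2/n)} and the asymptotic p-value on 1 df.  For a
#' 2x2 table phi equals \code{|ad - bc| / sqrt((a+b)(c+d)(a+c)(b+d))}; a
#' table with a zero marginal is flagged degenerate rather than raising an
#' error.  Phi approaches unity for complete association (complete
#' reproductive isolation) and 0 for independence.
#'
#' @param tab 2x2 matrix of non-negative integer counts, or
#'   \code{c(a, b, c, d)} filled row-wise.
#' @return list of class \code{PhiFit}: \code{chi2}, \code{phi}, \code{p},
#'   \code{n}, \code{degenerate}, \code{table}.
#' @examples
#' phiFit(c(30, 10, 10, 30))  # phi = 0.5
#' @export
phiFit <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2, 2, byrow = TRUE)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  n <- sum(tab)
  if (n < 1) stop("empty table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(structure(list(chi2 = NA_real_, phi = NA_real_, p = NA_real_,
                          n = n, degenerate = TRUE, table = tab),
                     class = "PhiFit"))
  e <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - e)^2 / e)
  phi <- sqrt(chi2 / n)
  structure(list(chi2 = chi2, phi = phi,
                 p = pchisq(chi2, df = 1, lower.tail = FALSE),
                 n = n, degenerate = FALSE, table = tab),
            class = "PhiFit")
}

#' @export
print.PhiFit <- function(x, ...) {
  if (x$degenerate) cat("PhiFit: degenerate table (zero marginal)\n")
  else cat(sprintf("PhiFit: chi2 = %.4f, phi = %.4f, p = %.3g, n = %d\n",
                   x$chi2, x$phi, x$p, x$n))
  invisible(x)
}

#' Assign individuals to speciation-model categories
#'
#' Every individual inherits its site's category: under the allopatric
#' model the site's modal mtDNA lineage; under the ecological model the
#' site's habitat type; under the geology model the side of a declared
#' geological boundary.  Sites with a tied modal lineage are excluded
#' (their individuals get \code{NA}), with the excluded count logged.
#'
#' @param td a [TransectDataset-class].
#' @param model \code{"allopatric"}, \code{"ecological"} or
#'   \code{"geology"}.
#' @param habitat an [ecotonePartition()] (required for the ecological
#'   model unless the dataset's site table has habitat labels with two
#'   levels).
#' @param geologyBoundaryAfter site index of the last site before the
#'   geological boundary (required for the geology model).
#' @return list of class \code{CategoryAssignment}: \code{category}
#'   (named per-individual labels, \code{NA} = excluded),
#'   \code{notApplicable} flag (ecological model without an ecotone),
#'   \code{excludedSites}, \code{nExcluded}.
#' @export
assignCategories <- function(td, model = c("allopatric", "ecological",
                                           "geology"),
                             habitat = NULL, geologyBoundaryAfter = NULL) {
  model <- match.arg(model)
  stopifnot(is(td, "TransectDataset"))
  sites <- siteInfo(td)$site
  siteMap <- siteOf(genotypes(td))
  excluded <- character(0)
  if (model == "allopatric") {
    lf <- lineageSiteFrequencies(td)
    modal <- attr(lf, "modal")[sites]
    tie <- attr(lf, "tie")[sites]
    excluded <- sites[which(tie | is.na(modal))]
    catOf <- modal
  } else if (model == "ecological") {
    if (!is.null(habitat)) {
      if (!isTRUE(habitat$isEcotone))
        return(structure(list(category = NULL, notApplicable = TRUE,
                              excludedSites = character(0), nExcluded = 0L),
                         class = "CategoryAssignment"))
      catOf <- habitat$habitat[sites]
    } else {
      catOf <- setNames(siteInfo(td)$habitat, sites)
    }
    if (length(unique(catOf[!is.na(catOf)])) < 2L)
      return(structure(list(category = NULL, notApplicable = TRUE,
                            excludedSites = character(0), nExcluded = 0L),
                       class = "CategoryAssignment"))
  } else {
    if (is.null(geologyBoundaryAfter))
      stop("geology model needs a declared boundary (site index)")
    catOf <- setNames(
      ifelse(seq_along(sites) <= geologyBoundaryAfter,
             "precursor_A", "precursor_B"), sites)
  }
  catOf[excluded] <- NA_character_
  category <- setNames(catOf[siteMap], names(siteMap))
  structure(list(category = category, notApplicable = FALSE,
                 excludedSites = excluded,
                 nExcluded = sum(is.na(category))),
            class = "CategoryAssignment")
}

#' Test a speciation model against genetic cluster assignment
#'
#' Builds the 2x2 table of hard cluster assignment (K = 2) against the
#' model-predicted categories and applies [phiFit()].  The cluster-to-
#' category orientation is irrelevant for chi-squared, but the orientation
#' maximising the main diagonal is recorded for reporting.
#'
#' @param td a [TransectDataset-class].
#' @param clusterOf named integer/character per-individual hard cluster
#'   assignment with exactly two levels (e.g. from
#'   \code{runStructureScan()$hardAssignment}).
#' @param model,habitat,geologyBoundaryAfter passed to
#'   [assignCategories()].
#' @param K the selected number of clusters behind the assignment (the
#'   forced-K flag is set when it differs from 2).
#' @return a [SpeciationTest-class], or a \code{CategoryAssignment} with
#'   \code{notApplicable = TRUE} for the ecological model without an
#'   ecotone.
#' @export
testSpeciation <- function(td, clusterOf, model = "allopatric",
                           habitat = NULL, geologyBoundaryAfter = NULL,
                           K = 2L) {
  cats <- assignCategories(td, model, habitat, geologyBoundaryAfter)
  if (isTRUE(cats$notApplicable)) return(cats)
  shared <- intersect(names(clusterOf), names(cats$category))
  keep <- shared[!is.na(cats$category[shared]) &
                 !is.na(clusterOf[shared])]
  cl <- factor(clusterOf[keep])
  ca <- factor(cats$category[keep])
  if (nlevels(cl) != 2L || nlevels(ca) != 2L) {
    tab <- matrix(0L, 2, 2)
    tb0 <- table(cl, ca)
    tab[seq_len(nrow(tb0)), seq_len(ncol(tb0))] <- tb0
  } else tab <- unclass(table(cl, ca))
  pf <- phiFit(matrix(as.integer(tab), 2, 2))
  # orientation maximising the main diagonal, for reporting
  if (sum(diag(pf$table)) < pf$table[1, 2] + pf$table[2, 1])
    pf$table <- pf$table[, 2:1]
  modelLab <- if (model == "geology") "geology_lineage" else model
  new("SpeciationTest", model = modelLab, table = pf$table,
      chi2 = if (pf$degenerate) NA_real_ else pf$chi2,
      phi = if (pf$degenerate) NA_real_ else pf$phi,
      p = if (pf$degenerate) NA_real_ else pf$p,
      n = as.integer(pf$n), K = as.integer(K),
      forcedK = !is.na(K) && as.integer(K) != 2L,
      degenerate = pf$degenerate)
}

#' Goodness of fit between geological precursor blocks and mtDNA lineage
#'
#' The 2x2 table of (side of the declared geological boundary) x (mtDNA
#' lineage) over all assigned individuals, with [phiFit()] applied; with
#' no lineage inter-digitation phi approaches 1.
#'
#' @param td a [TransectDataset-class] with lineage assignments.
#' @param geologyBoundaryAfter site index of the last site of the first
#'   precursor block.
#' @return a [SpeciationTest-class] with model \code{"geology_lineage"}.
#' @export
geologyLineageFit <- function(td, geologyBoundaryAfter) {
  stopifnot(is(td, "TransectDataset"))
  lin <- mtdnaLineage(td)
  lin <- lin[!is.na(lin)]
  if (!length(lin)) stop("no mtDNA lineage assignments")
  tb <- sort(table(lin), decreasing = TRUE)
  keepLabs <- names(tb)[seq_len(min(2L, length(tb)))]
  lin <- lin[lin %in% keepLabs]
  testSpeciation(td, setNames(lin, names(lin)), model = "geology",
                 geologyBoundaryAfter = geologyBoundaryAfter, K = NA)
}
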