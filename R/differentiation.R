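#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Distance-based AMOVA on allele copies with the mismatch
#' (infinite-allele) distance: 0 for identical allele codes, 1 otherwise.
#' Sums of squares are partitioned among groups of populations, among
#' populations within groups, and within populations, locus by locus;
#' variance components use the standard unbalanced-design coefficients and
#' are summed over loci before forming the Phi statistics.  The Phi_CT
#' p-value permutes whole populations among groups (group sizes preserved)
#' with the +1/+1 correction, or enumerates all distinct two-group
#' assignments when \code{exact = TRUE}.
#'
#' @param g a [Genotypes-class].
#' @param popOf named character: individual -> population (default: the
#'   genotypes' sites).
#' @param groupOf named character: population -> group (>= 2 groups).
#' @param nPerm number of Monte-Carlo permutations (default 9,999).
#' @param seed integer seed.
#' @param exact enumerate all distinct permutations instead (2 groups
#'   only).
#' @param grouping label stored in the result (e.g. "lineage", "habitat").
#' @return an [AmovaResult-class].
#' @export
amova <- function(g, popOf = siteOf(g), groupOf, nPerm = 9999L, seed = 1L,
                  exact = FALSE, grouping = "custom") {
  stopifnot(is(g, "Genotypes"))
  pops <- unique(popOf)
  if (!all(pops %in% names(groupOf)))
    stop("groupOf must cover every population")
  groups <- unique(unname(groupOf[pops]))
  if (length(groups) < 2L)
    stop("AMOVA needs >= 2 groups; Phi_CT is undefined otherwise")
  if (any(table(factor(unname(groupOf[pops]), levels = groups)) == 0L))
    stop("each group must contain at least one population")

  # per-locus, per-population allele count vectors
  enc <- .encodeAlleles(g)
  nl <- nLoci(g)
  popIdx <- match(popOf, pops)
  countTabs <- vector("list", nl)
  for (l in seq_len(nl)) {
    tab <- matrix(0L, length(pops), enc$nAlleles[l])
    for (p in seq_along(pops)) {
      a <- c(enc$alleles[popIdx == p, 2L * l - 1L],
             enc$alleles[popIdx == p, 2L * l])
      a <- a[a > 0L]
      if (length(a)) tab[p, ] <- tabulate(a, nbins = enc$nAlleles[l])
    }
    countTabs[[l]] <- tab
  }

  popGroups0 <- unname(groupOf[pops])
  obs <- .amovaComponents(countTabs, popGroups0, groups)
  if (obs$totalVar <= 0)
    stop("degenerate data: total molecular variance is zero")

  phiObs <- obs$phi[["PhiCT"]]
  if (exact) {
    if (length(groups) != 2L)
      stop("exact enumeration supports two groups only")
    n1 <- sum(popGroups0 == groups[1])
    combs <- utils::combn(length(pops), n1)
    phis <- apply(combs, 2, function(ix) {
      gr <- rep(groups[2], length(pops)); gr[ix] <- groups[1]
      .amovaComponents(countTabs, gr, groups)$phi[["PhiCT"]]
    })
    p <- mean(phis >= phiObs - 1e-12)
    nP <- ncol(combs)
  } else {
    set.seed(as.integer(seed))
    cnt <- 0L
    for (i in seq_len(nPerm)) {
      gr <- sample(popGroups0)
      if (.amovaComponents(countTabs, gr, groups)$phi[["PhiCT"]] >=
          phiObs - 1e-12) cnt <- cnt + 1L
    }
    p <- (cnt + 1) / (nPerm + 1)
    nP <- as.integer(nPerm)
  }

  new("AmovaResult", sigma = obs$sigma, phi = obs$phi, pPhiCT = p,
      nPerm = nP, grouping = grouping, ss = obs$ss)
}

# SSW of a pooled set of allele copies from its count vector:
# (1/n) * sum_{i<j} d_ij with mismatch distance = (n^2 - sum c_a^2) / (2n)
.sswFromCounts <- function(cnt) {
  n <- sum(cnt)
  if (n == 0) return(0)
  (n^2 - sum(cnt^2)) / (2 * n)
}

.amovaComponents <- function(countTabs, popGroups, groups) {
  sigA <- sigB <- sigC <- 0
  ssa <- ssb <- ssw <- 0
  dfa <- dfb <- dfc <- 0
  G <- length(groups)
  for (tab in countTabs) {
    np <- rowSums(tab)                   # copies per population
    keep <- np > 0
    tabl <- tab[keep, , drop = FALSE]
    pg <- popGroups[keep]
    npl <- np[keep]
    P <- nrow(tabl); N <- sum(npl)
    if (P < 2L || N == 0) next
    sswPop <- sum(apply(tabl, 1, .sswFromCounts))
    grpTabs <- rowsum(tabl, pg)
    ng <- rowSums(grpTabs)
    sswGrp <- sum(apply(grpTabs, 1, .sswFromCounts))
    sswTot <- .sswFromCounts(colSums(tabl))
    SSa <- sswTot - sswGrp
    SSb <- sswGrp - sswPop
    SSw <- sswPop
    Gl <- nrow(grpTabs)
    dfA <- Gl - 1; dfB <- P - Gl; dfC <- N - P
    if (dfA <= 0 || dfC <= 0) next
    msA <- SSa / dfA
    msB <- if (dfB > 0) SSb / dfB else 0
    msC <- SSw / dfC
    sumNp2ByG <- tapply(npl^2, pg, sum) / tapply(npl, pg, sum)
    n1 <- if (dfB > 0) (N - sum(sumNp2ByG)) / dfB else 0
    n2 <- (sum(sumNp2ByG) - sum(npl^2) / N) / dfA
    n3 <- (N - sum(ng^2) / N) / dfA
    sC <- msC
    sB <- if (dfB > 0 && n1 > 0) (msB - sC) / n1 else 0
    sA <- if (n3 > 0) (msA - sC - n2 * sB) / n3 else 0
    sigA <- sigA + sA; sigB <- sigB + sB; sigC <- sigC + sC
    ssa <- ssa + SSa; ssb <- ssb + SSb; ssw <- ssw + SSw
    dfa <- dfa + dfA; dfb <- dfb + dfB; dfc <- dfc + dfC
  }
  tot <- sigA + sigB + sigC
  phi <- c(PhiCT = if (tot != 0) sigA / tot else NA_real_,
           PhiSC = if ((sigB + sigC) != 0) sigB / (sigB + sigC)
                   else NA_real_,
           PhiST = if (tot != 0) (sigA + sigB) / tot else NA_real_)
  # Phi can fall marginally outside [-1,1] with negative components; clamp
  phi <- pmin(pmax(phi, -1), 1)
  ss <- data.frame(
    source = c("among groups", "among populations within groups",
               "within populations"),
    df = c(dfa, dfb, dfc), SS = c(ssa, ssb, ssw),
    sigma = c(sigA, sigB, sigC))
  list(sigma = c(amongGroups = sigA, amongPopsWithin = sigB,
                 withinPops = sigC),
       phi = phi, ss = ss, totalVar = tot)
}

#' Multilocus Weir-Cockerham F_ST between two populations
#'
#' The variance-components estimator theta, with numerator and denominator
#' components summed across loci (and alleles) before the ratio; missing
#' copies are excluded per locus.  Can be negative for undifferentiated
#' data; reported raw.
#'
#' @param g a [Genotypes-class].
#' @param popA,popB population (site) ids.
#' @return scalar theta, or \code{NA} with attribute \code{"flag"} when no
#'   shared polymorphic locus exists.
#' @export
pairwiseFst <- function(g, popA, popB) {
  stopifnot(is(g, "Genotypes"))
  num <- den <- 0
  any_poly <- FALSE
  for (l in seq_len(nLoci(g))) {
    aa <- .calledPairs(g, popA, l)
    bb <- .calledPairs(g, popB, l)
    if (nrow(aa) < 2L || nrow(bb) < 2L) next
    alleles <- sort(unique(c(aa, bb)))
    if (length(alleles) < 2L) next
    any_poly <- TRUE
    r <- 2
    ni <- c(nrow(aa), nrow(bb))
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    for (al in alleles) {
      pi <- c(sum(aa == al), sum(bb == al)) / (2 * ni)
      hi <- c(sum(xor(aa[, 1] == al, aa[, 2] == al)),
              sum(xor(bb[, 1] == al, bb[, 2] == al))) / ni
      pbar <- sum(ni * pi) / sum(ni)
      s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * hi) / sum(ni)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  if (!any_poly || den == 0) {
    out <- NA_real_
    attr(out, "flag") <- "no shared polymorphic locus"
    return(out)
  }
  num / den
}

#' Recode alleles to population-unique code spaces
#'
#' Remaps every allele code so that no two populations share any allele,
#' while preserving within-population genotype structure (and hence
#' observed heterozygosity) exactly.  Computing F_ST on the recoded data
#' gives the maximum F_ST attainable given the within-population
#' diversity, the denominator of the standardized F_ST'.
#'
#' @param g a [Genotypes-class].
#' @param popOf named character individual -> population (default: sites).
#' @return a recoded [Genotypes-class].
#' @export
recodeMax <- function(g, popOf = siteOf(g)) {
  stopifnot(is(g, "Genotypes"))
  pops <- unique(popOf)
  offsetUnit <- max(g@calls, 0L, na.rm = TRUE) + 1L
  calls <- g@calls
  for (p in seq_along(pops)) {
    idx <- popOf == pops[p]
    calls[idx, , ] <- calls[idx, , , drop = FALSE] +
      (p - 1L) * offsetUnit
  }
  new("Genotypes", calls = calls, siteOf = g@siteOf)
}

#' Standardized pairwise F_ST'
#'
#' \code{FST' = theta / theta_max}, where \code{theta_max} is the
#' Weir-Cockerham estimate after [recodeMax()] recoding of the two
#' populations.  A negative raw theta is reported as is but truncated at 0
#' in the ratio.
#'
#' @param g a [Genotypes-class].
#' @param popA,popB population (site) ids.
#' @return list of class \code{FstPair}: \code{fst}, \code{fstMax},
#'   \code{fstPrime}, \code{negative} flag.
#' @export
fstPrime <- function(g, popA, popB) {
  sub <- g[siteOf(g) %in% c(popA, popB)]
  fst <- pairwiseFst(sub, popA, popB)
  fstMax <- pairwiseFst(recodeMax(sub), popA, popB)
  neg <- !is.na(fst) && fst < 0
  prime <- if (is.na(fst) || is.na(fstMax) || fstMax <= 0) NA_real_
           else max(fst, 0) / fstMax
  structure(list(popA = popA, popB = popB, fst = fst, fstMax = fstMax,
                 fstPrime = prime, negative = neg), class = "FstPair")
}

#' Mean standardized F_ST' across a transect boundary
#'
#' Computes per-pair standardized F_ST' for every cross-boundary site pair
#' and averages; the within-block mean is reported as a control analogue.
#'
#' @param td a [TransectDataset-class].
#' @param boundary \code{"lineage"} (blocks = sites by modal mtDNA
#'   lineage), \code{"habitat"} (blocks = sites by habitat label), or an
#'   integer: blocks split after that site index.
#' @param habitat optional [ecotonePartition()] result overriding the
#'   dataset's habitat labels.
#' @return list of class \code{BoundaryFst}: \code{mean}, \code{pairs}
#'   (per-pair table), \code{withinMean}, \code{blocks}.
#' @export
meanBoundaryFstStd <- function(td, boundary = "lineage", habitat = NULL) {
  stopifnot(is(td, "TransectDataset"))
  sites <- siteInfo(td)$site
  if (is.numeric(boundary)) {
    blockOf <- setNames(ifelse(seq_along(sites) <= boundary, "A", "B"),
                        sites)
  } else if (boundary == "lineage") {
    lf <- lineageSiteFrequencies(td)
    modal <- attr(lf, "modal")[sites]
    if (any(is.na(modal)))
      stop("modal lineage undefined (tie or empty) for site(s): ",
           paste(sites[is.na(modal)], collapse = ", "))
    blockOf <- modal
  } else if (boundary == "habitat") {
    blockOf <- if (!is.null(habitat)) habitat$habitat[sites]
               else setNames(siteInfo(td)$habitat, sites)
  } else stop("unknown boundary type: ", boundary)
  blocks <- unique(unname(blockOf))
  if (length(blocks) != 2L)
    stop("boundary must partition sites into exactly two non-empty blocks")
  g <- genotypes(td)
  cross <- expand.grid(a = sites[blockOf == blocks[1]],
                       b = sites[blockOf == blocks[2]],
                       stringsAsFactors = FALSE)
  pairRows <- lapply(seq_len(nrow(cross)), function(i) {
    fp <- fstPrime(g, cross$a[i], cross$b[i])
    data.frame(popA = fp$popA, popB = fp$popB, fst = fp$fst,
               fstMax = fp$fstMax, fstPrime = fp$fstPrime,
               cross = TRUE)
  })
  within <- do.call(rbind, lapply(blocks, function(bl) {
    ss <- sites[blockOf == bl]
    if (length(ss) < 2L) return(NULL)
    t(utils::combn(ss, 2))
  }))
  withinRows <- if (!is.null(within)) lapply(seq_len(nrow(within)),
    function(i) {
      fp <- fstPrime(g, within[i, 1], within[i, 2])
      data.frame(popA = fp$popA, popB = fp$popB, fst = fp$fst,
                 fstMax = fp$fstMax, fstPrime = fp$fstPrime,
                 cross = FALSE)
    }) else list()
  pairs <- do.call(rbind, c(pairRows, withinRows))
  structure(list(
    mean = mean(pairs$fstPrime[pairs$cross], na.rm = TRUE),
    withinMean = if (any(!pairs$cross))
      mean(pairs$fstPrime[!pairs$cross], na.rm = TRUE) else NA_real_,
    pairs = pairs, blocks = setNames(blockOf, sites)),
    class = "BoundaryFst")
}
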