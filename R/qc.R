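#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' The statistic is the absolute deviation of the observed heterozygote
#' count from its expectation under random pairing of the observed allele
#' pool (drawing without replacement).  The null distribution is built by
#' repeatedly shuffling the pooled allele copies into random diploid
#' pairings.  The returned p-value uses randomized tie-breaking, which
#' makes it exactly Uniform(0,1) under the null despite the discrete
#' statistic.
#'
#' @param g a [Genotypes-class].
#' @param site site id.
#' @param locus locus name or index.
#' @param nPerm number of permutations (default 10,000).
#' @param seed integer seed.
#' @return list of class \code{HweTest}: \code{p}, \code{hetObs},
#'   \code{hetExp}, \code{n}, \code{monomorphic} flag.
#' @export
hweTest <- function(g, site, locus, nPerm = 10000L, seed = 1L) {
  a <- .calledPairs(g, site, locus)
  n <- nrow(a)
  if (n < 5L) stop("HWE test needs >= 5 called individuals at the locus")
  pool <- c(a[, 1], a[, 2])
  counts <- table(pool)
  if (length(counts) < 2L)
    return(structure(list(p = 1, hetObs = 0, hetExp = 0, n = n,
                          monomorphic = TRUE), class = "HweTest"))
  m <- 2L * n
  # expected het count under random pairing without replacement
  pSame <- sum(counts * (counts - 1)) / (m * (m - 1))
  hetExp <- n * (1 - pSame)
  hetObs <- sum(a[, 1] != a[, 2])
  tObs <- abs(hetObs - hetExp)
  set.seed(as.integer(seed))
  tPerm <- vapply(seq_len(nPerm), function(i) {
    sh <- sample(pool)
    abs(sum(sh[seq_len(n)] != sh[n + seq_len(n)]) - hetExp)
  }, 0)
  structure(list(p = .randomizedP(tObs, tPerm), hetObs = hetObs,
                 hetExp = hetExp, n = n, monomorphic = FALSE),
            class = "HweTest")
}

#' Permutation test of genotypic linkage disequilibrium
#'
#' A chi-squared-style statistic on the genotype x genotype contingency
#' table of a locus pair, with significance from permuting one locus's
#' genotypes across individuals.  Randomized tie-breaking keeps the
#' p-value exactly uniform under the null.
#'
#' @param g a [Genotypes-class].
#' @param site site id.
#' @param locusA,locusB locus names or indices.
#' @param nPerm number of permutations (default 10,000).
#' @param seed integer seed.
#' @return list of class \code{LdTest}: \code{p}, \code{stat}, \code{n},
#'   \code{monomorphic} flag.
#' @export
ldTest <- function(g, site, locusA, locusB, nPerm = 10000L, seed = 1L) {
  aa <- .calledPairs(g, site, locusA)
  bb <- .calledPairs(g, site, locusB)
  shared <- intersect(rownames(aa), rownames(bb))
  if (length(shared) < 5L)
    stop("LD test needs >= 5 individuals called at both loci")
  aa <- aa[shared, , drop = FALSE]; bb <- bb[shared, , drop = FALSE]
  gtA <- paste(pmin(aa[, 1], aa[, 2]), pmax(aa[, 1], aa[, 2]), sep = "/")
  gtB <- paste(pmin(bb[, 1], bb[, 2]), pmax(bb[, 1], bb[, 2]), sep = "/")
  if (length(unique(gtA)) < 2L || length(unique(gtB)) < 2L)
    return(structure(list(p = 1, stat = 0, n = length(shared),
                          monomorphic = TRUE), class = "LdTest"))
  chi2 <- function(xa, xb) {
    tb <- table(xa, xb)
    e <- outer(rowSums(tb), colSums(tb)) / sum(tb)
    sum((tb - e)^2 / e)
  }
  tObs <- chi2(gtA, gtB)
  set.seed(as.integer(seed))
  tPerm <- vapply(seq_len(nPerm), function(i) chi2(gtA, sample(gtB)), 0)
  structure(list(p = .randomizedP(tObs, tPerm), stat = tObs,
                 n = length(shared), monomorphic = FALSE),
            class = "LdTest")
}

#' Bonferroni adjustment helper for locus(-pair) families
#'
#' @param p numeric vector of raw p-values.
#' @return Bonferroni-adjusted p-values (capped at 1).
#' @export
bonferroniAdjust <- function(p) stats::p.adjust(p, method = "bonferroni")

# individuals at `site` with both copies called at `locus`
.calledPairs <- function(g, site, locus) {
  stopifnot(is(g, "Genotypes"))
  idx <- which(siteOf(g) == site)
  if (!length(idx)) stop("unknown site: ", site)
  a <- g@calls[idx, locus, , drop = FALSE]
  a <- matrix(a, ncol = 2, dimnames = list(individualIds(g)[idx], NULL))
  a[complete.cases(a), , drop = FALSE]
}

# upper-tail permutation p with randomized tie-breaking: exactly U(0,1)
# under the null (Pr computed over permutation AND the auxiliary uniform)
.randomizedP <- function(tObs, tPerm, u = runif(1)) {
  b <- sum(tPerm > tObs)
  e <- sum(tPerm == tObs)
  (b + u * (e + 1)) / (length(tPerm) + 1)
}
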