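# Shared fixtures and independent oracles for the test suite.

# quick Genotypes builder: calls is a list of per-individual integer vectors
# c(a1_l1, a2_l1, a1_l2, a2_l2, ...); NA = missing copy
makeGenotypes <- function(callList, sites, loci = NULL) {
  nl <- length(callList[[1]]) / 2
  if (is.null(loci)) loci <- paste0("L", seq_len(nl))
  calls <- array(NA_integer_, dim = c(length(callList), nl, 2),
                 dimnames = list(names(callList) %||%
                                   paste0("ind", seq_along(callList)),
                                 loci, NULL))
  for (i in seq_along(callList)) {
    v <- callList[[i]]
    calls[i, , 1] <- v[seq(1, 2 * nl, by = 2)]
    calls[i, , 2] <- v[seq(2, 2 * nl, by = 2)]
  }
  Genotypes(calls, siteOf = sites)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two populations of n individuals fixed for different alleles at every locus
fixedDiffGenotypes <- function(n = 50, nl = 9) {
  calls <- c(rep(list(rep(c(1L, 1L), nl)), n),
             rep(list(rep(c(3L, 3L), nl)), n))
  makeGenotypes(calls, sites = rep(c("p1", "p2"), each = n))
}

# random genotypes from one allele pool (panmictic across the given sites)
panmicticGenotypes <- function(n = 20, nl = 4, nAlleles = 5, sites = "p1",
                               missingRate = 0) {
  nTot <- n * length(sites)
  calls <- array(sample.int(nAlleles, nTot * nl * 2, replace = TRUE),
                 dim = c(nTot, nl, 2))
  if (missingRate > 0)
    calls[runif(length(calls)) < missingRate] <- NA_integer_
  storage.mode(calls) <- "integer"
  Genotypes(calls, siteOf = rep(sites, each = n))
}

# bind two individuals x loci x 2 call arrays along the first dimension
abind_simple <- function(a, b) {
  out <- array(NA_integer_, dim = c(dim(a)[1] + dim(b)[1], dim(a)[2], 2),
               dimnames = list(c(rownames(a) %||%
                                   paste0("a", seq_len(dim(a)[1])),
                                 paste0("x", seq_len(dim(b)[1]))),
                               dimnames(a)[[2]], NULL))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

# closed-form phi for a 2x2 table: |ad - bc| / sqrt(marginal product)
phiClosedForm <- function(a, b, c, d) {
  abs(a * d - b * c) /
    sqrt((a + b) * (c + d) * (a + c) * (b + d))
}

# brute-force motif scan (plain character comparison, IUPAC-free motifs)
bruteForceCuts <- function(seq, motif, offset) {
  L <- nchar(seq); m <- nchar(motif)
  hits <- integer(0)
  for (s in seq_len(max(L - m + 1, 0)))
    if (substr(seq, s, s + m - 1) == motif) hits <- c(hits, s)
  cuts <- hits + offset - 1L
  cuts[cuts >= 1L & cuts < L]
}

# random A/C/G-only sequence: cannot contain any motif with a T
motifFreeSequence <- function(len) {
  paste(sample(c("A", "C", "G"), len, replace = TRUE), collapse = "")
}

# implant a motif so its first base sits at `start` (1-based)
implantMotif <- function(seq, motif, start) {
  paste0(substr(seq, 1, start - 1), motif,
         substr(seq, start + nchar(motif), nchar(seq)))
}

# ---- brute-force AMOVA oracle -------------------------------------------
# Computes per-locus sums of squares directly from explicit pairwise
# mismatch-distance matrices over allele copies, then the standard
# unbalanced-design variance components, summed over loci.
bruteForceAmova <- function(g, popOf, groupOf) {
  pops <- unique(popOf)
  sigA <- sigB <- sigC <- 0
  for (l in seq_len(nLoci(g))) {
    copies <- integer(0); popLab <- character(0)
    for (i in seq_len(nInd(g))) {
      for (cpy in 1:2) {
        a <- genotypeCalls(g)[i, l, cpy]
        if (!is.na(a)) {
          copies <- c(copies, a)
          popLab <- c(popLab, popOf[i])
        }
      }
    }
    if (length(unique(popLab)) < 2) next
    d <- outer(copies, copies, FUN = `!=`) * 1
    grpLab <- unname(groupOf[popLab])
    ssOf <- function(sel) {
      if (sum(sel) == 0) return(0)
      sum(d[sel, sel][upper.tri(d[sel, sel])]) / sum(sel)
    }
    N <- length(copies)
    ssTot <- ssOf(rep(TRUE, N))
    ssWithinPops <- sum(vapply(unique(popLab),
                               function(p) ssOf(popLab == p), 0))
    ssWithinGrps <- sum(vapply(unique(grpLab),
                               function(gr) ssOf(grpLab == gr), 0))
    SSa <- ssTot - ssWithinGrps
    SSb <- ssWithinGrps - ssWithinPops
    SSw <- ssWithinPops
    P <- length(unique(popLab)); G <- length(unique(grpLab))
    dfA <- G - 1; dfB <- P - G; dfC <- N - P
    if (dfA <= 0 || dfC <= 0) next
    np <- table(popLab); ng <- table(grpLab)
    popGrp <- tapply(grpLab, popLab, `[`, 1)
    sumNp2g <- vapply(names(ng), function(gr) {
      sum(np[names(popGrp)[popGrp == gr]]^2) / ng[[gr]]
    }, 0)
    n1 <- if (dfB > 0) (N - sum(sumNp2g)) / dfB else 0
    n2 <- (sum(sumNp2g) - sum(np^2) / N) / dfA
    n3 <- (N - sum(ng^2) / N) / dfA
    sC <- SSw / dfC
    sB <- if (dfB > 0 && n1 > 0) (SSb / dfB - sC) / n1 else 0
    sA <- (SSa / dfA - sC - n2 * sB) / n3
    sigA <- sigA + sA; sigB <- sigB + sB; sigC <- sigC + sC
  }
  tot <- sigA + sigB + sigC
  list(sigma = c(amongGroups = sigA, amongPopsWithin = sigB,
                 withinPops = sigC),
       PhiCT = sigA / tot)
}

# exhaustive Phi_CT permutation p for two groups (includes the observed
# assignment; no +1 correction needed)
exhaustivePhiCtP <- function(g, popOf, groupOf) {
  pops <- unique(popOf)
  grp0 <- unname(groupOf[pops])
  gl <- unique(grp0)
  n1 <- sum(grp0 == gl[1])
  obs <- bruteForceAmova(g, popOf, groupOf)$PhiCT
  combs <- combn(length(pops), n1)
  phis <- apply(combs, 2, function(ix) {
    gr <- rep(gl[2], length(pops)); gr[ix] <- gl[1]
    names(gr) <- pops
    bruteForceAmova(g, popOf, gr)$PhiCT
  })
  mean(phis >= obs - 1e-12)
}

# observed heterozygosity per population at every locus
observedHet <- function(g, popOf = siteOf(g)) {
  vapply(unique(popOf), function(p) {
    idx <- which(popOf == p)
    a <- genotypeCalls(g)[idx, , , drop = FALSE]
    het <- a[, , 1, drop = FALSE] != a[, , 2, drop = FALSE]
    mean(het, na.rm = TRUE)
  }, 0)
}

# scaled-down MCMC configuration used across slower tests
testMcmcConfig <- function(...) {
  mcmcConfig(burnin = 300L, iters = 1200L, nRuns = 2L, kRange = 1:3, ...)
}
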