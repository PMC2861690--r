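#' MCMC configuration for the admixture model
#'
#' Defaults are desk-scale (2,000 burn-in, 8,000 post burn-in iterations, 3
#' replicate runs, K from 1 to 4); the field-scale analysis the framework
#' mirrors used a burn-in of 100,000 steps, 400,000 post burn-in
#' iterations, K from 1 to 9 and 10 replicate runs, and is available by
#' passing those values explicitly.
#'
#' @param burnin,iters burn-in and post burn-in Gibbs sweeps.
#' @param nRuns replicate runs per K.
#' @param kRange integer vector of cluster numbers to scan.
#' @param alphaMax upper bound of the uniform prior on the admixture
#'   concentration alpha.
#' @param lambda Dirichlet prior on cluster allele frequencies (1 =
#'   uniform).
#' @param thin posterior-mean accumulation interval (sweeps).
#' @param alphaSd s.d. of the Metropolis random-walk proposal for alpha.
#' @return list of class \code{McmcConfig}.
#' @export
mcmcConfig <- function(burnin = 2000L, iters = 8000L, nRuns = 3L,
                       kRange = 1:4, alphaMax = 10, lambda = 1,
                       thin = 10L, alphaSd = 0.25) {
  stopifnot(burnin > 0, iters > 0, nRuns > 0, thin > 0,
            all(kRange >= 1), alphaMax > 0, lambda > 0)
  structure(list(burnin = as.integer(burnin), iters = as.integer(iters),
                 nRuns = as.integer(nRuns), kRange = as.integer(kRange),
                 alphaMax = alphaMax, lambda = lambda,
                 thin = as.integer(thin), alphaSd = alphaSd),
            class = "McmcConfig")
}

# encode allele codes per locus as 1..A (0 = missing) for the sampler
.encodeAlleles <- function(g) {
  nl <- nLoci(g)
  m <- matrix(0L, nInd(g), 2L * nl)
  nAlleles <- integer(nl)
  codes <- vector("list", nl)
  for (l in seq_len(nl)) {
    a <- g@calls[, l, , drop = FALSE]
    u <- sort(unique(as.vector(a[!is.na(a)])))
    codes[[l]] <- u
    nAlleles[l] <- length(u)
    m[, 2L * l - 1L] <- match(a[, 1L, 1L], u, nomatch = 0L)
    m[, 2L * l]      <- match(a[, 1L, 2L], u, nomatch = 0L)
  }
  list(alleles = m, nAlleles = nAlleles, codes = codes)
}

#' Run the admixture-model Gibbs sampler
#'
#' One MCMC run of the admixture model: each allele copy carries a latent
#' cluster of origin Z, cluster allele frequencies P get
#' Dirichlet(\code{lambda} + counts) conditional updates, individual
#' membership proportions Q get Dirichlet(alpha + counts) updates, and the
#' shared concentration alpha a Metropolis random walk under a
#' Uniform(0, alphaMax] prior.  Missing allele copies contribute to no
#' counts and no likelihood.  Q and P are posterior means over thinned post
#' burn-in samples; the model evidence lnPD is computed from the
#' log-likelihood trace by [lnpdFromTrace()].
#'
#' @param g a [Genotypes-class] object.
#' @param K number of clusters (>= 1).
#' @param config an [mcmcConfig()].
#' @param seed integer seed for this run.
#' @return an [AncestryEstimate-class].
#' @export
admixtureMcmc <- function(g, K, config = mcmcConfig(), seed = 1L) {
  stopifnot(is(g, "Genotypes"), K >= 1)
  if (nInd(g) == 0L) stop("empty genotype set")
  if (K > nInd(g)) stop("K exceeds the number of individuals")
  enc <- .encodeAlleles(g)
  if (any(enc$nAlleles == 0L))
    stop("locus with no observed alleles: ",
         lociNames(g)[which(enc$nAlleles == 0L)[1]])
  set.seed(as.integer(seed))
  res <- .admixtureMcmcCpp(enc$alleles, enc$nAlleles, as.integer(K),
                           config$burnin, config$iters, config$thin,
                           config$lambda, config$alphaMax, config$alphaSd,
                           1.0)
  Q <- res$Q
  rownames(Q) <- individualIds(g)
  colnames(Q) <- paste0("cluster_", seq_len(K))
  P <- res$P
  names(P) <- lociNames(g)
  for (l in seq_along(P)) colnames(P[[l]]) <- as.character(enc$codes[[l]])
  new("AncestryEstimate", K = as.integer(K), Q = Q, P = P,
      alpha = res$alpha, lnPD = lnpdFromTrace(res$trace),
      trace = res$trace)
}

#' Model-evidence score from a log-likelihood trace
#'
#' The harmonic-style approximation used for choosing the number of
#' clusters: the mean of the log-likelihood trace minus half its sample
#' variance (n - 1 denominator).
#'
#' @param trace numeric log-likelihood trace (length >= 2).
#' @return scalar lnPD.
#' @examples
#' lnpdFromTrace(c(0, 2))  # mean 1, variance 2 -> 0
#' @export
lnpdFromTrace <- function(trace) {
  if (length(trace) < 2L) stop("trace must have length >= 2")
  mean(trace) - var(trace) / 2
}

#' Choose the number of clusters by maximum model evidence
#'
#' The chosen K attains the maximal mean lnPD over replicate runs.  When
#' the top two means differ by less than one pooled standard deviation the
#' smaller K is chosen and the tie flag is set.
#'
#' @param runs list of [AncestryEstimate-class] objects (any mix of K
#'   values; replicates are grouped by K).
#' @return list of class \code{KSelection}: \code{table} (per-K mean and sd
#'   of lnPD, number of runs), \code{K}, \code{tie}.
#' @export
selectK <- function(runs) {
  if (!length(runs)) stop("empty run set")
  ks <- vapply(runs, function(r) r@K, 1L)
  ln <- vapply(runs, lnPD, 0)
  tab <- do.call(rbind, lapply(sort(unique(ks)), function(k) {
    v <- ln[ks == k]
    data.frame(K = k, meanLnPD = mean(v),
               sdLnPD = if (length(v) > 1) sd(v) else NA_real_,
               nRuns = length(v))
  }))
  ord <- order(tab$meanLnPD, decreasing = TRUE)
  best <- tab[ord[1], ]
  tie <- FALSE
  chosen <- best$K
  if (nrow(tab) > 1) {
    second <- tab[ord[2], ]
    s1 <- ifelse(is.na(best$sdLnPD), 0, best$sdLnPD)
    s2 <- ifelse(is.na(second$sdLnPD), 0, second$sdLnPD)
    pooled <- sqrt((s1^2 + s2^2) / 2)
    if (best$meanLnPD - second$meanLnPD < pooled) {
      tie <- TRUE
      chosen <- min(best$K, second$K)
    }
  }
  structure(list(table = tab, K = chosen, tie = tie), class = "KSelection")
}

#' @export
print.KSelection <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("chosen K =", x$K, if (x$tie) "(tie: smaller K preferred)", "\n")
  invisible(x)
}

#' Align replicate runs across label switching
#'
#' Cluster labels are arbitrary within a run; alignment applies, per run, a
#' greedy cluster permutation maximising the sum of column-wise
#' correlations of its Q matrix with the first run's, then averages.
#'
#' @param qs list of individuals x K membership matrices (equal shapes), or
#'   a list of [AncestryEstimate-class] objects.
#' @return list: \code{aligned} (permuted Q matrices), \code{meanQ},
#'   \code{permutations} (one integer vector per run; new column j is old
#'   column perm[j]).
#' @export
alignRuns <- function(qs) {
  qs <- lapply(qs, function(q) if (is(q, "AncestryEstimate")) q@Q else q)
  d <- dim(qs[[1]])
  if (!all(vapply(qs, function(q) identical(dim(q), d), TRUE)))
    stop("all Q matrices must have identical shape")
  K <- d[2]
  ref <- qs[[1]]
  perms <- vector("list", length(qs))
  perms[[1]] <- seq_len(K)
  aligned <- qs
  for (r in seq_along(qs)[-1]) {
    cc <- suppressWarnings(cor(ref, qs[[r]]))
    cc[!is.finite(cc)] <- 0
    perm <- integer(K)
    used <- rep(FALSE, K)
    for (step in seq_len(K)) {
      cand <- cc
      cand[perm != 0, ] <- -Inf
      cand[, used] <- -Inf
      ij <- arrayInd(which.max(cand), dim(cand))
      perm[ij[1]] <- ij[2]
      used[ij[2]] <- TRUE
    }
    aligned[[r]] <- qs[[r]][, perm, drop = FALSE]
    colnames(aligned[[r]]) <- colnames(ref)
    perms[[r]] <- perm
  }
  meanQ <- Reduce(`+`, aligned) / length(aligned)
  list(aligned = aligned, meanQ = meanQ, permutations = perms)
}

#' Scan K with replicate runs, select K, and align
#'
#' Runs [admixtureMcmc()] for every K in \code{config$kRange} with
#' \code{config$nRuns} replicates each (sub-seeds derived
#' deterministically from \code{seed}), selects K by [selectK()], aligns
#' the replicate runs at the selected K and, for the comparative tests, at
#' a forced K = 2.
#'
#' @param g a [Genotypes-class].
#' @param config an [mcmcConfig()].
#' @param seed integer master seed.
#' @return list: \code{runs}, \code{selection} (a \code{KSelection}),
#'   \code{meanQ} (aligned mean at the selected K), \code{meanQ2} (aligned
#'   mean at K = 2), \code{forcedK2} flag, \code{hardAssignment} (argmax of
#'   \code{meanQ2}, ties to the lower cluster index).
#' @export
runStructureScan <- function(g, config = mcmcConfig(), seed = 1L) {
  set.seed(as.integer(seed))
  subSeeds <- sample.int(.Machine$integer.max - 1L,
                         length(config$kRange) * config$nRuns)
  runs <- list()
  i <- 0L
  for (K in config$kRange)
    for (r in seq_len(config$nRuns)) {
      i <- i + 1L
      runs[[i]] <- admixtureMcmc(g, K, config, seed = subSeeds[i])
    }
  sel <- selectK(runs)
  kRuns <- Filter(function(x) x@K == sel$K, runs)
  meanQ <- alignRuns(kRuns)$meanQ
  if (2L %in% vapply(runs, function(r) r@K, 1L)) {
    runs2 <- Filter(function(x) x@K == 2L, runs)
  } else {
    runs2 <- lapply(seq_len(config$nRuns), function(r)
      admixtureMcmc(g, 2L, config,
                    seed = subSeeds[r]))
  }
  meanQ2 <- alignRuns(runs2)$meanQ
  hard <- max.col(meanQ2, ties.method = "first")
  names(hard) <- rownames(meanQ2)
  list(runs = runs, selection = sel, meanQ = meanQ, meanQ2 = meanQ2,
       forcedK2 = sel$K != 2L, hardAssignment = hard)
}

#' Per-site allele frequency table
#'
#' Frequencies within each locus sum to 1 per site; missing copies are
#' excluded from the denominators.
#'
#' @param g a [Genotypes-class].
#' @param siteOrder site ids in transect order (default: first-appearance
#'   order).
#' @return numeric matrix sites x (locus, allele) columns.
#' @export
siteAlleleFrequencies <- function(g, siteOrder = unique(siteOf(g))) {
  enc <- .encodeAlleles(g)
  cols <- unlist(lapply(seq_len(nLoci(g)), function(l)
    paste0(lociNames(g)[l], ".", enc$codes[[l]])))
  out <- matrix(0, length(siteOrder), length(cols),
                dimnames = list(siteOrder, cols))
  off <- c(0L, cumsum(enc$nAlleles))
  for (s in seq_along(siteOrder)) {
    idx <- which(siteOf(g) == siteOrder[s])
    for (l in seq_len(nLoci(g))) {
      a <- c(enc$alleles[idx, 2L * l - 1L], enc$alleles[idx, 2L * l])
      a <- a[a > 0L]
      if (length(a)) {
        tb <- tabulate(a, nbins = enc$nAlleles[l])
        out[s, off[l] + seq_len(enc$nAlleles[l])] <- tb / sum(tb)
      } else {
        out[s, off[l] + seq_len(enc$nAlleles[l])] <- NA_real_
      }
    }
  }
  out
}

#' PCA of per-site allele frequencies
#'
#' Column-centered PCA of the site x (locus, allele) frequency table, with
#' PC1 site scores sign-oriented to correlate positively with site
#' position; an independent, non-model-based view of population structure
#' to compare against the Bayesian cluster frequencies.
#'
#' @param g a [Genotypes-class].
#' @param positions site positions in transect order.
#' @param siteOrder site ids in transect order.
#' @return list of class \code{AlleleFreqPca}: \code{scores} (PC1 per
#'   site), \code{allScores}, \code{propVar}, \code{excluded} (sites with
#'   no called copies at any locus).
#' @export
alleleFreqPca <- function(g, positions = NULL,
                          siteOrder = unique(siteOf(g))) {
  if (length(siteOrder) < 3L) stop("allele-frequency PCA needs >= 3 sites")
  if (is.null(positions)) positions <- seq_along(siteOrder)
  freq <- siteAlleleFrequencies(g, siteOrder)
  bad <- apply(freq, 1, function(x) all(is.na(x)))
  if (any(bad)) {
    warning("excluding site(s) with no called copies: ",
            paste(siteOrder[bad], collapse = ", "))
    freq <- freq[!bad, , drop = FALSE]
    positions <- positions[!bad]
  }
  pc <- prcomp(freq, center = TRUE, scale. = FALSE)
  s1 <- pc$x[, 1]
  r <- suppressWarnings(cor(s1, positions))
  if (!is.na(r) && r < 0) s1 <- -s1
  structure(list(scores = setNames(s1, rownames(freq)),
                 allScores = pc$x,
                 propVar = pc$sdev[1]^2 / max(sum(pc$sdev^2), 1e-300),
                 excluded = siteOrder[bad]),
            class = "AlleleFreqPca")
}
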