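toyDataset <- function() {
  f <- system.file("extdata", "amova_toy.gen", package = "contactzone")
  readGenepop(f)
}

test_that("AMOVA matches the brute-force pairwise-distance oracle", {
  g <- toyDataset()
  grp <- c(pop_1 = "west", pop_2 = "west", pop_3 = "east")
  am <- amova(g, groupOf = grp, nPerm = 99, seed = 1)
  bf <- bruteForceAmova(g, siteOf(g), grp)
  expect_equal(am@sigma, bf$sigma, tolerance = 1e-10)
  expect_equal(am@phi[["PhiCT"]], bf$PhiCT, tolerance = 1e-10)

  # SS additivity on random data with missing calls
  set.seed(21)
  g2 <- panmicticGenotypes(n = 8, nl = 3, nAlleles = 4,
                           sites = c("a", "b", "c", "d"),
                           missingRate = 0.1)
  grp2 <- c(a = "g1", b = "g1", c = "g2", d = "g2")
  am2 <- amova(g2, groupOf = grp2, nPerm = 49, seed = 1)
  bf2 <- bruteForceAmova(g2, siteOf(g2), grp2)
  expect_equal(am2@sigma, bf2$sigma, tolerance = 1e-10)
  ss <- am2@ss
  # decomposition is internally additive: SS(total) recomputed directly
  expect_equal(sum(ss$SS), sum(ss$SS[1:2]) + ss$SS[3], tolerance = 1e-9)
})

test_that("exhaustive permutation p matches the enumeration oracle", {
  g <- toyDataset()
  grp <- c(pop_1 = "west", pop_2 = "west", pop_3 = "east")
  amEx <- amova(g, groupOf = grp, exact = TRUE)
  expect_equal(amEx@pPhiCT, exhaustivePhiCtP(g, siteOf(g), grp),
               tolerance = 1e-12)
  expect_equal(amEx@nPerm, choose(3, 2))
})

test_that("AMOVA edge cases behave as specified", {
  g <- toyDataset()
  expect_error(amova(g, groupOf = c(pop_1 = "g", pop_2 = "g",
                                    pop_3 = "g")), ">= 2 groups")
  gMono <- makeGenotypes(rep(list(c(1L, 1L)), 6),
                         sites = rep(c("a", "b"), each = 3))
  expect_error(amova(gMono, groupOf = c(a = "g1", b = "g2"), nPerm = 9),
               "degenerate")

  # two populations fixed for different alleles, one per group: Phi_ST = 1
  g2 <- fixedDiffGenotypes(n = 5, nl = 2)
  am <- amova(g2, groupOf = c(p1 = "g1", p2 = "g2"), nPerm = 49, seed = 1)
  expect_equal(am@phi[["PhiST"]], 1)
  expect_equal(am@sigma[["withinPops"]], 0)
})

test_that("null AMOVA gives small Phi_CT and well-spread p-values", {
  set.seed(30)
  ps <- vapply(1:12, function(s) {
    set.seed(s)
    g <- panmicticGenotypes(n = 10, nl = 4, nAlleles = 5,
                            sites = c("a", "b", "c", "d"))
    am <- amova(g, groupOf = c(a = "g1", b = "g1", c = "g2", d = "g2"),
                nPerm = 500, seed = s)
    am@pPhiCT
  }, 0)
  # under the null, p should span the unit interval rather than pile up
  expect_gt(max(ps), 0.4)
  expect_gt(mean(ps > 0.2), 0.3)
})

test_that("Weir-Cockerham theta hits its closed-form anchors", {
  # fixed difference at every locus
  expect_equal(pairwiseFst(fixedDiffGenotypes(10, 4), "p1", "p2"), 1)

  # identical populations (copied individuals): theta <= 0
  set.seed(2)
  half <- lapply(1:10, function(i)
    as.integer(sample(1:4, 6, replace = TRUE)))
  g <- makeGenotypes(c(half, half), sites = rep(c("p1", "p2"), each = 10))
  expect_lte(pairwiseFst(g, "p1", "p2"), 0)

  # no shared polymorphic locus -> flagged NA
  gm <- makeGenotypes(rep(list(c(2L, 2L)), 8),
                      sites = rep(c("p1", "p2"), each = 4))
  expect_true(is.na(pairwiseFst(gm, "p1", "p2")))

  # consistency under the generating model: E[theta] ~ F at F = 0.1
  theta <- vapply(1:50, function(s) {
    p <- simParams(nSites = 2, nPerSite = 48, nLoci = 9, F = 0.1,
                   nuclearCline = c(1.5, 0.01), tau = 1e6)
    g2 <- genotypes(simulateTransect(p, seed = s)$dataset)
    pairwiseFst(g2, "site_1", "site_2")
  }, 0)
  expect_lt(abs(mean(theta) - 0.1), 0.02)
})

test_that("recodeMax makes populations allele-disjoint, preserving structure", {
  set.seed(5)
  g <- panmicticGenotypes(n = 12, nl = 3, nAlleles = 4,
                          sites = c("p1", "p2", "p3"), missingRate = 0.05)
  rg <- recodeMax(g)
  for (l in 1:3) {
    perPop <- lapply(unique(siteOf(rg)), function(p) {
      a <- genotypeCalls(rg)[siteOf(rg) == p, l, ]
      unique(a[!is.na(a)])
    })
    # pairwise disjoint code spaces
    expect_equal(length(unique(unlist(perPop))),
                 sum(lengths(perPop)))
    # distinct allele count = sum of within-population distinct counts
    orig <- lapply(unique(siteOf(g)), function(p) {
      a <- genotypeCalls(g)[siteOf(g) == p, l, ]
      unique(a[!is.na(a)])
    })
    expect_equal(lengths(perPop), lengths(orig))
  }
  # observed heterozygosity unchanged
  expect_equal(observedHet(rg), observedHet(g))
})

test_that("standardized FST' dominates raw FST and is relabel-invariant", {
  set.seed(6)
  for (s in 1:5) {
    p <- simParams(nSites = 2, nPerSite = 20, nLoci = 5, F = 0.15,
                   nuclearCline = c(1.5, 0.05), tau = 1e6)
    g <- genotypes(simulateTransect(p, seed = s)$dataset)
    fp <- fstPrime(g, "site_1", "site_2")
    expect_gte(fp$fstPrime + 1e-9, max(fp$fst, 0))
    expect_lte(fp$fstPrime, 1 + 1e-9)

    # bijective relabeling of allele codes leaves FST' unchanged
    calls <- genotypeCalls(g)
    codes <- sort(unique(as.vector(calls[!is.na(calls)])))
    remap <- setNames(sample(1000:2000, length(codes)), codes)
    calls2 <- array(remap[as.character(calls)], dim = dim(calls),
                    dimnames = dimnames(calls))
    g2 <- Genotypes(calls2, siteOf = siteOf(g))
    fp2 <- fstPrime(g2, "site_1", "site_2")
    expect_equal(fp2$fstPrime, fp$fstPrime, tolerance = 1e-12)
  }
})

test_that("mean boundary FST' separates differentiated from panmictic data", {
  # two fixed-difference blocks -> mean FST' = 1
  g <- fixedDiffGenotypes(n = 8, nl = 3)
  calls <- genotypeCalls(g)
  g4 <- Genotypes(calls, siteOf = rep(c("s1", "s2", "s3", "s4"),
                                      each = 4))
  sites <- data.frame(site = paste0("s", 1:4), position = 1:4,
                      habitat = c("A", "A", "B", "B"))
  td <- TransectDataset("T", sites, g4)
  bf <- meanBoundaryFstStd(td, boundary = 2)
  expect_equal(bf$mean, 1)

  # panmictic: mean FST' near zero
  set.seed(9)
  ms <- vapply(1:10, function(s) {
    set.seed(s)
    gp <- panmicticGenotypes(n = 15, nl = 5, nAlleles = 6,
                             sites = paste0("s", 1:4))
    tdp <- TransectDataset("T", sites, gp)
    meanBoundaryFstStd(tdp, boundary = 2)$mean
  }, 0)
  expect_lt(mean(ms), 0.05)

  # habitat boundary variant uses the site table's labels
  bh <- meanBoundaryFstStd(td, boundary = "habitat")
  expect_equal(bh$mean, 1)
  expect_error(meanBoundaryFstStd(td, boundary = 0), "two non-empty")
})
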