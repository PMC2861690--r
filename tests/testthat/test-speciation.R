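test_that("phiFit reproduces closed-form anchors and invariances", {
  expect_equal(phiFit(c(10, 0, 0, 10))$phi, 1)     # perfect association
  z <- phiFit(c(5, 5, 5, 5))
  expect_equal(z$chi2, 0)
  expect_equal(z$phi, 0)
  f <- phiFit(c(30, 10, 10, 30))
  expect_equal(f$chi2, 20)
  expect_equal(f$phi, 0.5)
  expect_equal(f$phi, phiClosedForm(30, 10, 10, 30), tolerance = 1e-12)

  # invariance under row and column label swaps
  tab <- matrix(c(17, 4, 6, 23), 2, 2)
  expect_equal(phiFit(tab)$phi, phiFit(tab[2:1, ])$phi)
  expect_equal(phiFit(tab)$phi, phiFit(tab[, 2:1])$phi)

  # degenerate marginals flag rather than error
  expect_true(phiFit(c(5, 5, 0, 0))$degenerate)
  expect_true(phiFit(c(5, 0, 5, 0))$degenerate)
  expect_error(phiFit(c(0, 0, 0, 0)), "empty")
})

test_that("phi is monotone as off-diagonal counts move to the diagonal", {
  # exhaustive over diagonal-oriented tables, moderate n (the full n <= 40
  # sweep runs in the acceptance suite)
  for (n in c(7, 12, 20)) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      if (a * d < b * cc) next
      p0 <- phiFit(c(a, b, cc, d))
      if (p0$degenerate) next
      moves <- list(c(a + 1, b - 1, cc, d), c(a, b, cc - 1, d + 1))
      for (mv in moves) {
        if (any(mv < 0)) next
        p1 <- phiFit(mv)
        if (p1$degenerate) next
        expect_gte(p1$phi, p0$phi - 1e-12)
      }
    }
  }
})

test_that("assignCategories inherits site categories and handles ties", {
  g <- panmicticGenotypes(n = 4, sites = c("s1", "s2", "s3"))
  lin <- setNames(c(rep("central", 4),                 # s1: modal central
                    rep(c("central", "south"), 2),     # s2: 2/2 tie
                    rep("south", 4)),                  # s3: modal south
                  individualIds(g))
  sites <- data.frame(site = c("s1", "s2", "s3"), position = 1:3,
                      habitat = c("A", "A", "B"))
  td <- TransectDataset("T", sites, g, mtdnaLineage = lin)

  ca <- assignCategories(td, "allopatric")
  expect_equal(unname(ca$category[1:4]), rep("central", 4))
  expect_true(all(is.na(ca$category[5:8])))   # tied site excluded
  expect_equal(ca$excludedSites, "s2")
  expect_equal(ca$nExcluded, 4L)

  ge <- assignCategories(td, "geology", geologyBoundaryAfter = 2)
  expect_equal(unname(ge$category[9:12]), rep("precursor_B", 4))

  # ecological from the site table's habitat labels
  ec <- assignCategories(td, "ecological")
  expect_equal(unname(ec$category[1:4]), rep("A", 4))

  # ecological with a no-ecotone partition: explicit not-applicable
  hp <- structure(list(habitat = setNames(rep("A", 3), sites$site),
                       isEcotone = FALSE, noEcotone = TRUE),
                  class = "HabitatPartition")
  expect_true(assignCategories(td, "ecological",
                               habitat = hp)$notApplicable)
})

test_that("testSpeciation builds the 2x2 table and flags forced K", {
  g <- panmicticGenotypes(n = 10, sites = c("s1", "s2"))
  lin <- setNames(rep(c("central", "south"), each = 10),
                  individualIds(g))
  sites <- data.frame(site = c("s1", "s2"), position = 1:2)
  td <- TransectDataset("T", sites, g, mtdnaLineage = lin)

  # clusters identical to categories -> phi = 1
  cl <- setNames(rep(c(1L, 2L), each = 10), individualIds(g))
  st <- testSpeciation(td, cl, model = "allopatric", K = 2)
  expect_equal(st@phi, 1)
  expect_false(st@forcedK)
  expect_equal(st@n, 20L)

  # forced-K flag when selection chose a different K
  st1 <- testSpeciation(td, cl, model = "allopatric", K = 1)
  expect_true(st1@forcedK)

  # independent clusters -> small phi, table preserved
  set.seed(12)
  clr <- setNames(sample(1:2, 20, replace = TRUE), individualIds(g))
  str <- testSpeciation(td, clr, model = "allopatric", K = 2)
  if (!str@degenerate) expect_lt(str@phi, 0.6)
})

test_that("geologyLineageFit is phi = 1 without inter-digitation", {
  g <- panmicticGenotypes(n = 12, sites = c("s1", "s2"))
  sites <- data.frame(site = c("s1", "s2"), position = 1:2)
  lin <- setNames(rep(c("central", "northwest"), each = 12),
                  individualIds(g))
  td <- TransectDataset("T", sites, g, mtdnaLineage = lin)
  fit <- geologyLineageFit(td, geologyBoundaryAfter = 1)
  expect_equal(fit@phi, 1)
  expect_equal(fit@model, "geology_lineage")

  # fully mixed lineages -> phi near 0
  linMix <- setNames(rep(c("central", "northwest"), 12),
                     individualIds(g))
  tdMix <- TransectDataset("T", sites, g, mtdnaLineage = linMix)
  expect_lt(geologyLineageFit(tdMix, 1)@phi, 0.2)
})

test_that("analyzeTransect is deterministic and degrades gracefully", {
  sim <- simulateTransect(
    simParams(nSites = 4, nPerSite = 12, nTraitPerSite = 6, nLoci = 4,
              F = 0.25, nuclearCline = c(2.5, 0.3),
              mtdnaCline = c(2.5, 0.2)), seed = 31)
  cfg <- mcmcConfig(burnin = 100, iters = 400, nRuns = 2, kRange = 1:2)
  # few trait individuals relative to traits: the ridge warning is expected
  r1 <- suppressWarnings(
    analyzeTransect(sim$dataset, cfg, seed = 77, nPermAmova = 99))
  r2 <- suppressWarnings(
    analyzeTransect(sim$dataset, cfg, seed = 77, nPermAmova = 99))
  expect_identical(r1, r2)
  expect_s4_class(r1$phiGeology, "SpeciationTest")
  expect_true(is(r1$scan$selection, "KSelection"))

  # a dataset without traits or climate still yields a report
  tdBare <- TransectDataset("bare", siteInfo(sim$dataset),
                            genotypes(sim$dataset),
                            mtdnaLineage = mtdnaLineage(sim$dataset))
  rb <- analyzeTransect(tdBare, cfg, seed = 5, nPermAmova = 49)
  expect_null(rb$cva)
  expect_false(is.null(rb$scan))
  expect_true("climate" %in% names(rb$errors))
})
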