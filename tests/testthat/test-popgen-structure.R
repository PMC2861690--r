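test_that("K = 1 membership is exactly the trivial simplex", {
  g <- panmicticGenotypes(n = 10, nl = 3, sites = "p1")
  est <- admixtureMcmc(g, 1, mcmcConfig(burnin = 50, iters = 200), seed = 1)
  expect_true(all(membershipQ(est) == 1))
  expect_true(is.finite(lnPD(est)))
  # simplex invariants on posterior means
  for (pl in clusterFreqP(est))
    expect_equal(rowSums(pl), rep(1, nrow(pl)), tolerance = 1e-9)
})

test_that("admixtureMcmc validates inputs", {
  g <- panmicticGenotypes(n = 4, nl = 2)
  expect_error(admixtureMcmc(g, 5), "exceeds")
  gEmpty <- makeGenotypes(list(c(NA, NA)), sites = "s1")
  expect_error(admixtureMcmc(gEmpty, 1), "no observed alleles")
})

test_that("lnpdFromTrace is mean minus half the sample variance", {
  expect_equal(lnpdFromTrace(c(-10, -10, -10)), -10)   # constant trace
  expect_equal(lnpdFromTrace(c(0, 2)), 0)              # mean 1, var 2
  tr <- rnorm(50, -100, 3)
  expect_equal(lnpdFromTrace(tr + 7), lnpdFromTrace(tr) + 7,
               tolerance = 1e-9)                       # shift equivariance
  expect_error(lnpdFromTrace(numeric(0)), "length")
  expect_error(lnpdFromTrace(-5), "length")
})

test_that("selectK maximises mean lnPD with the tie-to-smaller-K rule", {
  mkRun <- function(K, lnpd) {
    tr <- c(lnpd, lnpd)   # constant trace -> lnPD = lnpd
    new("AncestryEstimate", K = as.integer(K),
        Q = matrix(1 / K, 2, K), P = list(matrix(1, K, 1)),
        alpha = 1, lnPD = lnpd, trace = tr)
  }
  sel <- selectK(list(mkRun(1, -100), mkRun(2, -91), mkRun(2, -89)))
  expect_equal(sel$K, 2)
  expect_false(sel$tie)

  # means -90.0 vs -90.1 with sd ~2: closer than one pooled sd -> K = 1
  sel2 <- selectK(list(mkRun(1, -89), mkRun(1, -91),
                       mkRun(2, -88.1), mkRun(2, -92.1)))
  expect_equal(sel2$K, 1)
  expect_true(sel2$tie)
  expect_error(selectK(list()), "empty")
})

test_that("alignRuns undoes label switching and beats no alignment", {
  set.seed(4)
  q1 <- t(apply(matrix(rgamma(30 * 3, 1), 30), 1, function(x) x / sum(x)))
  # column-swapped copy aligns back exactly
  al <- alignRuns(list(q1, q1[, c(3, 1, 2)]))
  expect_equal(al$aligned[[2]], q1, ignore_attr = TRUE)
  expect_equal(al$meanQ, q1, ignore_attr = TRUE)
  # mean of identical runs equals each run
  expect_equal(alignRuns(list(q1, q1, q1))$meanQ, q1, ignore_attr = TRUE)

  # greedy alignment never loses to the unaligned matrices, and is
  # sandwiched by the exhaustive-best permutation at K = 3
  agree <- function(a, b) -mean(abs(a - b))
  for (s in 1:10) {
    set.seed(s)
    qa <- t(apply(matrix(rgamma(20 * 3, 1), 20), 1, function(x) x / sum(x)))
    qb <- t(apply(matrix(rgamma(20 * 3, 1), 20), 1, function(x) x / sum(x)))
    al2 <- alignRuns(list(qa, qb))
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
    best <- max(vapply(perms, function(p) agree(qa, qb[, p]), 0))
    expect_gte(agree(qa, al2$aligned[[2]]) + 1e-12, agree(qa, qb))
    expect_lte(agree(qa, al2$aligned[[2]]), best + 1e-12)
  }
})

test_that("posterior recovers ancestry for fully diverged populations", {
  g <- fixedDiffGenotypes(n = 50, nl = 9)
  cfg <- mcmcConfig(burnin = 2000, iters = 8000)
  est <- admixtureMcmc(g, 2, cfg, seed = 13)
  qTrue <- rep(c(1, 0), each = 50)
  q <- membershipQ(est)[, 1]
  if (mean(abs(q - qTrue)) > 0.5) q <- 1 - q   # label orientation
  expect_lt(mean(abs(q - qTrue)), 0.05)

  # an appended F1 individual sits near q = 0.5 by symmetry
  callsF1 <- array(rep(c(1L, 3L), 9), dim = c(1, 9, 2))
  calls <- abind_simple(genotypeCalls(g), callsF1)
  gF1 <- Genotypes(calls, siteOf = c(siteOf(g), "f1"))
  estF1 <- admixtureMcmc(gF1, 2, cfg, seed = 13)
  qf <- membershipQ(estF1)[101, 1]
  expect_gte(qf, 0.35)
  expect_lte(qf, 0.65)
})

test_that("admixtureMcmc is exchangeable over individual order", {
  g <- fixedDiffGenotypes(n = 20, nl = 6)
  cfg <- mcmcConfig(burnin = 1000, iters = 4000)
  est1 <- admixtureMcmc(g, 2, cfg, seed = 5)
  perm <- sample(40)
  gp <- g[perm]
  est2 <- admixtureMcmc(gp, 2, cfg, seed = 6)
  al <- alignRuns(list(membershipQ(est1)[perm, ], membershipQ(est2)))
  expect_lt(max(abs(al$aligned[[1]] - al$aligned[[2]])), 0.02 * 4)
  expect_lt(mean(abs(al$aligned[[1]] - al$aligned[[2]])), 0.02)
})

test_that("siteAlleleFrequencies and alleleFreqPca behave on block data", {
  # all sites identical in frequency: PC1 scores all 0
  calls <- rep(list(c(1L, 2L, 3L, 3L)), 12)
  g <- makeGenotypes(calls, sites = rep(c("s1", "s2", "s3"), each = 4))
  fr <- siteAlleleFrequencies(g)
  expect_equal(unname(fr[1, ]), unname(fr[3, ]))
  expect_true(all(abs(alleleFreqPca(g)$scores) < 1e-12))

  # two site-blocks fixed for different alleles: PC1 separates them with
  # zero within-block spread
  calls2 <- c(rep(list(c(1L, 1L)), 8), rep(list(c(2L, 2L)), 8))
  g2 <- makeGenotypes(calls2, sites = rep(c("s1", "s2", "s3", "s4"),
                                          each = 4))
  pc <- alleleFreqPca(g2)
  expect_lt(max(abs(diff(pc$scores[c("s1", "s2")]))), 1e-12)
  expect_lt(max(abs(diff(pc$scores[c("s3", "s4")]))), 1e-12)
  expect_gt(abs(pc$scores[["s3"]] - pc$scores[["s1"]]), 0.1)
  # orientation: increases with position
  expect_gt(cor(pc$scores, 1:4), 0)

  # frequencies within each locus sum to 1 per site
  sums <- rowSums(fr[, grep("^L1", colnames(fr)), drop = FALSE])
  expect_equal(unname(sums), rep(1, 3))
})

test_that("PC1 tracks the K = 2 cluster frequencies on a simulated cline", {
  sim <- simulateTransect(scenarioPreset("rainforest_ecotone"), seed = 17)
  g <- genotypes(sim$dataset)
  est <- admixtureMcmc(g, 2, mcmcConfig(burnin = 400, iters = 1600),
                       seed = 2)
  siteQ <- tapply(membershipQ(est)[, 2], siteOf(g), mean)[
    paste0("site_", 1:7)]
  pc <- alleleFreqPca(g, siteOrder = paste0("site_", 1:7))
  expect_gt(abs(cor(pc$scores, siteQ)), 0.9)
})

test_that("hweTest calibrates to the pairing null", {
  # exact HWE proportions: statistic at the null mode, large p
  calls <- c(rep(list(c(1L, 1L)), 25), rep(list(c(1L, 2L)), 50),
             rep(list(c(2L, 2L)), 25))
  g <- makeGenotypes(calls, sites = "s1")
  hw <- hweTest(g, "s1", 1, nPerm = 2000, seed = 1)
  expect_gt(hw$p, 0.5)
  expect_equal(hw$hetObs, 50)

  # all homozygotes at 0.5/0.5: extreme heterozygote deficit
  calls2 <- c(rep(list(c(1L, 1L)), 25), rep(list(c(2L, 2L)), 25))
  g2 <- makeGenotypes(calls2, sites = "s1")
  expect_lt(hweTest(g2, "s1", 1, nPerm = 5000, seed = 1)$p, 0.001)

  # monomorphic locus: p = 1 with flag
  g3 <- makeGenotypes(rep(list(c(1L, 1L)), 10), sites = "s1")
  hw3 <- hweTest(g3, "s1", 1)
  expect_equal(hw3$p, 1)
  expect_true(hw3$monomorphic)
  expect_error(hweTest(g3[1:3], "s1", 1), ">= 5")
})

test_that("ldTest detects perfect association and respects monomorphism", {
  set.seed(8)
  a <- sample(1:3, 40, replace = TRUE)
  b <- sample(1:3, 40, replace = TRUE)
  calls <- lapply(1:40, function(i) c(a[i], b[i], a[i], b[i]))
  g <- makeGenotypes(calls, sites = "s1")  # locus 2 duplicates locus 1
  ld <- ldTest(g, "s1", 1, 2, nPerm = 999, seed = 3)
  expect_lte(ld$p, 2 / 1000)

  # independent loci: p should not be extreme (single draw sanity check)
  g2 <- panmicticGenotypes(n = 40, nl = 2, nAlleles = 3, sites = "s1")
  expect_gt(ldTest(g2, "s1", 1, 2, nPerm = 999, seed = 3)$p, 0.001)

  gMono <- makeGenotypes(rep(list(c(1L, 1L, 2L, 3L)), 10), sites = "s1")
  ldM <- ldTest(gMono, "s1", 1, 2)
  expect_equal(ldM$p, 1)
  expect_true(ldM$monomorphic)
})
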