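test_that("climatePca identifies an exact rank-1 gradient", {
  set.seed(1)
  f <- seq(0, 3, length.out = 6)
  b <- runif(19, 0.2, 0.6)
  # exp construction makes the ln-transformed matrix exactly rank 1
  climate <- exp(outer(f, b) + rep(runif(19), each = 6))
  rownames(climate) <- paste0("s", 1:6)
  colnames(climate) <- climateVariableNames()
  cp <- climatePca(climate)
  expect_equal(cp$propVar, 1, tolerance = 1e-9)
  expect_equal(cp$rWithPosition, 1, tolerance = 1e-9)
  expect_equal(cp$component, 1L)

  # identical sites: all columns constant -> magnitude 0 with warning
  flat <- matrix(2, 4, 19, dimnames = list(paste0("s", 1:4),
                                           climateVariableNames()))
  expect_warning(cp0 <- climatePca(flat), "constant")
  expect_equal(cp0$magnitude, 0)

  expect_error(climatePca(climate[1:2, ]), ">= 3 sites")
})

test_that("step magnitude matches the closed-form rank-1 + noise oracle", {
  set.seed(5)
  f <- c(0, 0, 0, 0, 3, 3, 3, 3)     # sites 1-4 low, 5-8 high, 3-sd step
  b <- runif(19, 0.5, 1.5)
  # closed form for the standardized-PCA score magnitude: per-column
  # attenuation b*step/sd_col combined over columns, plus the expected
  # widening of the site range by score noise (E[max of 4 N(0,1)] = 1.0294)
  sdCol <- sqrt(b^2 * var(f) + 1)
  sep <- sqrt(sum((3 * b / sdCol)^2))
  noiseSd <- sqrt(mean(1 / sdCol^2))
  expected <- sep + 2 * 1.0294 * noiseSd
  mags <- vapply(1:20, function(s) {
    set.seed(200 + s)
    noisy <- exp(outer(f, b) + matrix(rnorm(8 * 19), 8))
    rownames(noisy) <- paste0("s", 1:8)
    climatePca(noisy)$magnitude
  }, 0)
  expect_lt(abs(mean(mags) / expected - 1), 0.1)
})

test_that("climatePca scores are invariant (up to sign) under column reorder", {
  sim <- simulateTransect(scenarioPreset("rainforest_ecotone"), seed = 4)
  cl <- climateData(sim$dataset)
  cp1 <- climatePca(cl)
  perm <- sample(ncol(cl))
  cp2 <- climatePca(cl[, perm])
  expect_equal(abs(cor(cp1$scores, cp2$scores)), 1, tolerance = 1e-9)
  expect_equal(cp2$magnitude, cp1$magnitude, tolerance = 1e-9)
})

test_that("ecotonePartition places the midpoint cut and boundary", {
  mkProfile <- function(sc, pv = 0.9)
    structure(list(scores = setNames(sc, paste0("s", seq_along(sc))),
                   propVar = pv), class = "ClimateProfile")
  hp <- ecotonePartition(mkProfile(0:7))
  expect_equal(hp$cutPoint, 3.5)
  expect_equal(hp$boundaryAfter, 4L)
  expect_false(hp$multipleBoundaries)

  hp2 <- ecotonePartition(mkProfile(c(-1, -1, -1, -1, 1, 1, 1)))
  expect_equal(hp2$boundaryAfter, 4L)
  expect_equal(unname(hp2$habitat), c(rep("A", 4), rep("B", 3)))
  expect_true(hp2$isEcotone)   # clean step: infinite abruptness

  # cut-point lies strictly between min and max whenever scores differ
  for (s in 1:10) {
    set.seed(s)
    sc <- rnorm(7)
    hp3 <- ecotonePartition(mkProfile(sc))
    expect_gt(hp3$cutPoint, min(sc))
    expect_lt(hp3$cutPoint, max(sc))
  }

  # all-equal scores: no-ecotone result, not an error
  hp4 <- ecotonePartition(mkProfile(rep(1, 5)))
  expect_true(hp4$noEcotone)
  expect_equal(unname(hp4$habitat), rep("A", 5))

  # smooth gradient is split but not called an ecotone
  hp5 <- ecotonePartition(mkProfile(seq(0, 3, length.out = 8)))
  expect_false(hp5$isEcotone)
})

test_that("cvaTraits honours the unit within-group s.d. contract", {
  set.seed(2)
  tr <- lapply(1:5, function(i)
    matrix(rnorm(12 * 6, mean = i), 12, 6))
  names(tr) <- paste0("s", 1:5)
  cv <- cvaTraits(tr)
  expect_equal(cv$method, "cva")
  grp <- rep(names(tr), each = 12)
  ssw <- sum(vapply(split(cv$scores, grp), function(v)
    sum((v - mean(v))^2), 0))
  expect_equal(sqrt(ssw / (60 - 5)), 1, tolerance = 1e-6)
  # orientation: site means increase with position
  expect_gt(cor(cv$siteMeans, 1:5), 0)
})

test_that("CVA magnitude is near zero on null data and recovers separation", {
  nullMag <- vapply(1:20, function(s) {
    set.seed(s)
    tr <- lapply(1:8, function(i) matrix(rnorm(30 * 5), 30, 5))
    names(tr) <- paste0("s", 1:8)
    cvaTraits(tr)$magnitude
  }, 0)
  expect_lt(max(nullMag), 1.5)

  # two blocks of sites 10 within-group s.d. apart on one latent trait
  sep <- vapply(1:20, function(s) {
    set.seed(s)
    tr <- lapply(1:6, function(i) {
      m <- matrix(rnorm(30 * 5), 30, 5)
      if (i > 3) m[, 1] <- m[, 1] + 10
      m
    })
    names(tr) <- paste0("s", 1:6)
    cvaTraits(tr)$magnitude
  }, 0)
  expect_lt(abs(mean(sep) / 10 - 1), 0.15)
})

test_that("CVA site-mean scores are affine-invariant", {
  set.seed(9)
  tr <- lapply(1:5, function(i)
    matrix(rnorm(15 * 4, mean = c(0, i / 2, 0, -i)[1:4]), 15, 4,
           byrow = TRUE))
  names(tr) <- paste0("s", 1:5)
  cv1 <- cvaTraits(tr)
  A <- matrix(rnorm(16), 4, 4)
  while (abs(det(A)) < 0.1) A <- matrix(rnorm(16), 4, 4)
  shift <- rnorm(4)
  tr2 <- lapply(tr, function(m) sweep(m %*% A, 2, shift, "+"))
  cv2 <- cvaTraits(tr2)
  expect_equal(unname(cv2$siteMeans), unname(cv1$siteMeans),
               tolerance = 1e-6)
  expect_equal(cv2$magnitude, cv1$magnitude, tolerance = 1e-6)
})

test_that("heteroscedastic transects fall back to PCA of site means", {
  set.seed(3)
  tr <- lapply(1:5, function(i)
    matrix(rnorm(12 * 6, mean = i, sd = ifelse(i <= 2, 0.3, 3)), 12, 6))
  names(tr) <- paste0("s", 1:5)
  cv <- cvaTraits(tr)
  expect_equal(cv$method, "pca_site_means")
  expect_gt(cv$heteroSpread, log(2))
  # forcing CVA still works and tags accordingly
  expect_equal(cvaTraits(tr, method = "cva")$method, "cva")
  # missing values are imputed and counted
  tr[[1]][1, 2] <- NA
  expect_equal(cvaTraits(tr)$imputed, 1L)
})

test_that("siteCorrelation implements the exact t-transform", {
  x <- 1:8
  sc <- siteCorrelation(x, 2 * x + 1)
  expect_equal(sc$r, 1)
  expect_equal(sc$p, 0)

  # construct data with cor exactly 0.707 and check against cor.test
  xs <- scale(1:8)[, 1]
  e <- scale(resid(lm(rnorm(8) ~ xs)))[, 1]
  y <- 0.707 * xs + sqrt(1 - 0.707^2) * e
  sc2 <- siteCorrelation(xs, y)
  expect_equal(sc2$r, 0.707, tolerance = 1e-12)
  ct <- cor.test(xs, y)
  expect_equal(sc2$t, unname(ct$statistic), tolerance = 1e-9)
  expect_equal(sc2$p, ct$p.value, tolerance = 1e-9)
  # the t transform at r = 0.707, n = 8: t = 2.449, p = 0.0498
  expect_equal(sc2$t, 2.4495, tolerance = 1e-3)
  expect_equal(sc2$p, 0.0499, tolerance = 1e-3)

  # degenerate input
  expect_true(siteCorrelation(rep(1, 5), 1:5)$undefined)
  expect_error(siteCorrelation(1:2, 1:2), ">= 3")
})
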