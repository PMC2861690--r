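#' Canonical variate summary of quantitative traits along a transect
#'
#' Canonical variate analysis with sites as groups: axes maximise
#' between-site relative to pooled within-site variance, and scores are
#' scaled so that the pooled within-group standard deviation of each
#' retained axis is unity.  Axis signs are oriented so that site-mean
#' scores correlate positively with site position.  When the within-site
#' covariances are flagged heteroscedastic (spread of per-site mean
#' log-variances above \code{heteroThreshold}), the method falls back to a
#' PCA of column-standardized site-mean vectors (method tag
#' \code{"pca_site_means"}); fallback scores are rescaled to unit pooled
#' within-group s.d. so magnitudes stay comparable.
#'
#' @param traits named list (by site) of individuals x traits matrices, or
#'   a [TransectDataset-class].
#' @param positions site positions (default 1..n or the dataset's).
#' @param heteroThreshold heteroscedasticity cut-off on the max - min
#'   spread, over sites, of the mean log trait variance (default
#'   \code{log(2)}: a two-fold geometric-mean variance ratio).
#' @param method \code{"auto"} (default), or force \code{"cva"} /
#'   \code{"pca_site_means"}.
#' @return list of class \code{CvaResult}: \code{scores} (per-individual
#'   axis-1 scores), \code{siteMeans}, \code{magnitude} (max site mean -
#'   min site mean, axis 1), \code{withinSd} (pooled within-group s.d. of
#'   axis-1 scores), \code{method}, \code{heteroSpread}, \code{imputed}
#'   (count of imputed missing values).
#' @export
cvaTraits <- function(traits, positions = NULL, heteroThreshold = log(2),
                      method = c("auto", "cva", "pca_site_means")) {
  method <- match.arg(method)
  if (is(traits, "TransectDataset")) {
    positions <- siteInfo(traits)$position[
      match(names(traitData(traits)), siteInfo(traits)$site)]
    traits <- traitData(traits)
  }
  k <- length(traits)
  if (k < 2L) stop("CVA needs >= 2 sites")
  if (any(vapply(traits, nrow, 1L) < 2L))
    stop("CVA needs >= 2 individuals per site")
  if (is.null(positions)) positions <- seq_len(k)
  p <- ncol(traits[[1]])
  if (p < 1L) stop("need at least one trait")

  # site-mean imputation of missing values
  imputed <- 0L
  traits <- lapply(traits, function(m) {
    if (anyNA(m)) {
      for (j in seq_len(ncol(m))) {
        bad <- is.na(m[, j])
        if (any(bad)) {
          m[bad, j] <- mean(m[, j], na.rm = TRUE)
          imputed <<- imputed + sum(bad)
        }
      }
    }
    m
  })

  X <- do.call(rbind, traits)
  grp <- factor(rep(names(traits), vapply(traits, nrow, 1L)),
                levels = names(traits))
  N <- nrow(X)
  grand <- colMeans(X)
  siteMeansMat <- t(vapply(traits, colMeans, numeric(p)))
  ns <- vapply(traits, nrow, 1L)

  # heteroscedasticity proxy: spread of per-site mean log variances
  meanLogVar <- vapply(traits, function(m) {
    v <- apply(m, 2, var)
    mean(log(pmax(v, 1e-12)))
  }, 0)
  heteroSpread <- max(meanLogVar) - min(meanLogVar)
  useFallback <- method == "pca_site_means" ||
    (method == "auto" && heteroSpread > heteroThreshold)

  W <- matrix(0, p, p)
  for (s in seq_len(k)) {
    d <- sweep(traits[[s]], 2, siteMeansMat[s, ])
    W <- W + crossprod(d)
  }
  W <- W / (N - k)

  if (!useFallback) {
    ew <- eigen(W, symmetric = TRUE)
    tol <- 1e-10 * max(ew$values, 1e-300)
    if (any(ew$values < tol)) {
      warning("singular pooled within-group covariance; ridge applied")
      lambda <- 1e-6 * sum(diag(W)) / p
      W <- W + diag(lambda, p)
      ew <- eigen(W, symmetric = TRUE)
    }
    Wi2 <- ew$vectors %*% diag(1 / sqrt(ew$values), p) %*% t(ew$vectors)
    B <- matrix(0, p, p)
    for (s in seq_len(k)) {
      d <- siteMeansMat[s, ] - grand
      B <- B + ns[s] * tcrossprod(d)
    }
    B <- B / max(k - 1, 1)
    M <- Wi2 %*% B %*% Wi2
    eb <- eigen((M + t(M)) / 2, symmetric = TRUE)
    a1 <- Wi2 %*% eb$vectors[, 1]          # a1' W a1 = 1 by construction
    scores <- drop(sweep(X, 2, grand) %*% a1)
    tag <- "cva"
  } else {
    sm <- siteMeansMat
    sdm <- apply(sm, 2, sd)
    keep <- sdm > 0
    smStd <- sweep(sweep(sm[, keep, drop = FALSE], 2,
                         colMeans(sm[, keep, drop = FALSE])),
                   2, sdm[keep], "/")
    pc <- prcomp(smStd, center = FALSE, scale. = FALSE)
    load <- pc$rotation[, 1]
    full <- numeric(p); full[keep] <- load / sdm[keep]
    scores <- drop(sweep(X, 2, grand) %*% full)
    tag <- "pca_site_means"
  }

  # pooled within-group s.d. of scores; rescale to the unit-s.d. contract
  ssw <- sum(vapply(split(scores, grp), function(v)
    sum((v - mean(v))^2), 0))
  wsd <- sqrt(ssw / (N - k))
  if (wsd > 0) scores <- scores / wsd
  siteMeans <- vapply(split(scores, grp), mean, 0)

  r <- suppressWarnings(cor(siteMeans, positions))
  if (!is.na(r) && r < 0) { scores <- -scores; siteMeans <- -siteMeans }

  names(scores) <- rownames(X)
  structure(list(scores = scores, siteMeans = siteMeans,
                 magnitude = max(siteMeans) - min(siteMeans),
                 withinSd = 1, method = tag, heteroSpread = heteroSpread,
                 imputed = imputed),
            class = "CvaResult")
}

#' @export
print.CvaResult <- function(x, ...) {
  cat("CvaResult (", x$method, "): magnitude = ",
      format(x$magnitude, digits = 4), " within-group s.d. units\n",
      sep = "")
  invisible(x)
}

#' Pearson correlation between two per-site summaries
#'
#' Pearson r with the two-sided p-value from the t transform
#' \code{t = r * sqrt(n - 2) / sqrt(1 - r^2)} on n - 2 degrees of freedom,
#' with n (the number of sites) reported alongside.
#'
#' @param x,y paired numeric vectors (one value per site, >= 3 sites).
#' @return list of class \code{SiteCorrelation}: \code{r}, \code{t},
#'   \code{p}, \code{n}, \code{undefined} (TRUE when either vector has zero
#'   variance).
#' @export
siteCorrelation <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("site correlation needs >= 3 paired sites")
  if (sd(x) == 0 || sd(y) == 0)
    return(structure(list(r = NA_real_, t = NA_real_, p = NA_real_,
                          n = n, undefined = TRUE),
                     class = "SiteCorrelation"))
  r <- cor(x, y)
  if (abs(r) >= 1) {
    tt <- Inf * sign(r); pv <- 0
  } else {
    tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
    pv <- 2 * pt(-abs(tt), df = n - 2)
  }
  structure(list(r = r, t = tt, p = pv, n = n, undefined = FALSE),
            class = "SiteCorrelation")
}

#' @export
print.SiteCorrelation <- function(x, ...) {
  if (x$undefined) cat("SiteCorrelation: undefined (zero variance)\n")
  else cat(sprintf("SiteCorrelation: r = %.3f, p = %.4g, n = %d\n",
                   x$r, x$p, x$n))
  invisible(x)
}
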