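#' Climate PCA along a transect with trend-component selection
#'
#' Each climate variable is natural-log transformed (\code{ln(x + 1)} for
#' variables containing zeros, \code{ln(x)} otherwise), column-standardized,
#' and the sites are subjected to PCA.  The component defining the climatic
#' trend along the transect is the one whose site scores have maximal
#' absolute Pearson correlation with site position (not necessarily PC1);
#' the magnitude of climatic change is the range (max - min) of that
#' component's site scores.
#'
#' @param climate sites x variables numeric matrix (rownames = site ids) or
#'   a [TransectDataset-class].
#' @param positions site positions (default: 1..n, or the dataset's
#'   positions).
#' @return list of class \code{ClimateProfile}: \code{component} (index of
#'   the trend component), \code{scores} (per-site scores of that
#'   component), \code{allScores}, \code{propVar}, \code{magnitude},
#'   \code{loading} (unit-norm direction), \code{rWithPosition},
#'   \code{dropped} (constant columns removed).
#' @export
climatePca <- function(climate, positions = NULL) {
  if (is(climate, "TransectDataset")) {
    positions <- siteInfo(climate)$position
    climate <- climateData(climate)
  }
  if (nrow(climate) < 3L) stop("climate PCA needs >= 3 sites")
  if (ncol(climate) == 0L) stop("no climate variables present")
  if (is.null(positions)) positions <- seq_len(nrow(climate))
  if (any(climate < 0))
    stop("climate PCA expects non-negative values (log transform)")
  hasZero <- apply(climate, 2, function(x) any(x == 0))
  lx <- log(sweep(climate, 2, as.numeric(hasZero), "+"))
  sds <- apply(lx, 2, sd)
  dropped <- colnames(lx)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant climate column(s): ",
            paste(dropped, collapse = ", "))
    lx <- lx[, sds > 0, drop = FALSE]
  }
  if (ncol(lx) == 0L) {
    sc <- setNames(rep(0, nrow(climate)), rownames(climate))
    return(structure(list(component = NA_integer_, scores = sc,
                          allScores = NULL, propVar = NA_real_,
                          magnitude = 0, loading = NULL,
                          rWithPosition = NA_real_, dropped = dropped),
                     class = "ClimateProfile"))
  }
  pc <- prcomp(lx, center = TRUE, scale. = TRUE)
  # only components carrying real variance are trend candidates; numerically
  # null components (sdev ~ machine noise) would give spurious correlations
  real <- pc$sdev^2 > 1e-8 * sum(pc$sdev^2)
  rs <- vapply(seq_along(pc$sdev), function(j) {
    if (!real[j] || sd(pc$x[, j]) == 0) return(0)
    abs(cor(pc$x[, j], positions))
  }, 0)
  comp <- which.max(rs)
  scores <- setNames(pc$x[, comp], rownames(climate))
  propVar <- pc$sdev[comp]^2 / sum(pc$sdev^2)
  structure(list(component = unname(comp), scores = scores,
                 allScores = pc$x, propVar = propVar,
                 magnitude = max(scores) - min(scores),
                 loading = pc$rotation[, comp],
                 rWithPosition = unname(rs[comp]), dropped = dropped),
            class = "ClimateProfile")
}

#' @export
print.ClimateProfile <- function(x, ...) {
  cat("ClimateProfile: trend component PC", x$component,
      sprintf(" (%.1f%% variance, |r| with position = %.3f)\n",
              100 * x$propVar, x$rWithPosition), sep = "")
  cat(sprintf("  magnitude (max - min score): %.3f\n", x$magnitude))
  invisible(x)
}

#' Partition sites into two habitat types at the ecotone midpoint
#'
#' The cut-point is the midpoint between the maximum and minimum trend
#' component scores; each site is labelled by the side its score falls on
#' and the habitat boundary is placed between the adjacent site pair where
#' the label first changes.
#'
#' The partition alone does not establish that an ecotone (an abrupt,
#' high-magnitude habitat transition) exists: any noisy score vector can be
#' split at its midpoint.  The \code{isEcotone} field therefore also
#' requires a single boundary crossing and an abruptness (between-side mean
#' separation over the larger within-side score range) above
#' \code{minAbruptness}; a smooth gradient or a flat noisy profile fails
#' this while a genuine step passes it.
#'
#' @param profile a \code{ClimateProfile} from [climatePca()].
#' @param minAbruptness abruptness threshold for declaring an ecotone
#'   (default 2: the step must exceed twice the within-side score range).
#' @param minPropVar minimum share of total climatic variance the trend
#'   component must explain for an ecotone call (default 0.5): a real step
#'   imprints most of the 19 variables, while a spurious noise component
#'   does not.
#' @return list of class \code{HabitatPartition}: \code{cutPoint},
#'   \code{habitat} (named "A"/"B" per site, "A" = low-score side),
#'   \code{boundaryAfter} (index of the last site before the first label
#'   change; \code{NA} when all labels are equal), \code{multipleBoundaries}
#'   flag, \code{abruptness}, \code{isEcotone}, \code{noEcotone} flag (all
#'   scores equal).
#' @export
ecotonePartition <- function(profile, minAbruptness = 2,
                             minPropVar = 0.5) {
  sc <- profile$scores
  if (length(sc) < 2L) stop("need >= 2 site scores")
  if (max(sc) == min(sc)) {
    return(structure(list(cutPoint = unname(sc[1]),
                          habitat = setNames(rep("A", length(sc)), names(sc)),
                          boundaryAfter = NA_integer_,
                          multipleBoundaries = FALSE,
                          abruptness = 0, isEcotone = FALSE,
                          noEcotone = TRUE),
                     class = "HabitatPartition"))
  }
  cut <- (max(sc) + min(sc)) / 2
  lab <- ifelse(sc > cut, "B", "A")
  changes <- which(lab[-1] != lab[-length(lab)])
  sep <- mean(sc[lab == "B"]) - mean(sc[lab == "A"])
  withinRange <- max(vapply(split(sc, lab), function(v)
    diff(range(v)), 0))
  abrupt <- sep / max(withinRange, 1e-9 * sep)
  structure(list(cutPoint = cut, habitat = lab,
                 boundaryAfter = unname(changes[1]),
                 multipleBoundaries = length(changes) > 1L,
                 abruptness = abrupt,
                 isEcotone = length(changes) == 1L &&
                   abrupt > minAbruptness &&
                   isTRUE(profile$propVar > minPropVar),
                 noEcotone = FALSE),
            class = "HabitatPartition")
}

#' @export
print.HabitatPartition <- function(x, ...) {
  if (x$noEcotone) cat("HabitatPartition: no ecotone (all scores equal)\n")
  else cat("HabitatPartition: cut-point", format(x$cutPoint, digits = 4),
           "boundary after site", x$boundaryAfter,
           if (x$multipleBoundaries) "(multiple crossings)" else "", "\n")
  invisible(x)
}
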