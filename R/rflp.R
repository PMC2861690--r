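#' Restriction enzyme specification
#'
#' @param name enzyme name.
#' @param motif recognition motif as an IUPAC string (length >= 4).
#' @param cutOffset bases from motif start to the cut, 0-based (a cut after
#'   base 3 of the motif has offset 3).
#' @return list of class \code{EnzymeSpec}.
#' @examples
#' enzymeSpec("SspI", "AATATT", 3)
#' @export
enzymeSpec <- function(name, motif, cutOffset) {
  motif <- toupper(motif)
  if (nchar(motif) < 4L) stop("motif length must be >= 4")
  if (cutOffset < 0 || cutOffset > nchar(motif))
    stop("cut offset must lie within the motif")
  structure(list(name = name, motif = motif, cutOffset = as.integer(cutOffset)),
            class = "EnzymeSpec")
}

#' Default enzymes of the lineage-assignment assay
#'
#' SspI (AAT|ATT) and DraI (TTT|AAA), both blunt cutters with the cut after
#' base 3 of a 6-bp palindromic site.
#'
#' @return named list of [enzymeSpec()] objects.
#' @export
defaultEnzymes <- function() {
  list(SspI = enzymeSpec("SspI", "AATATT", 3L),
       DraI = enzymeSpec("DraI", "TTTAAA", 3L))
}

#' In-silico restriction digest
#'
#' Scans the given strand of a linear sequence for the enzyme's recognition
#' motif (IUPAC ambiguity codes in the motif match their base classes;
#' ambiguity codes in the sequence never match) and reports cut positions
#' and fragment lengths.  Overlapping motif occurrences are all reported.
#' The default assay motifs are palindromic, so a single-strand scan
#' suffices.
#'
#' @param sequence a single DNA string (A/C/G/T; case-insensitive).
#' @param enzyme an [enzymeSpec()].
#' @return list of class \code{DigestResult}: \code{enzyme}, \code{cuts}
#'   (1-based index of the last base 5' of each cut, ascending),
#'   \code{fragments} (bp, summing to the sequence length).
#' @examples
#' digestSequence(paste0("GGGG", "AATATT", "CCCC"), defaultEnzymes()$SspI)
#' @export
digestSequence <- function(sequence, enzyme) {
  stopifnot(inherits(enzyme, "EnzymeSpec"))
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L == 0L) stop("empty sequence")
  cuts <- integer(0)
  if (nchar(enzyme$motif) <= L) {
    subj <- Biostrings::DNAString(sequence)
    hits <- Biostrings::matchPattern(enzyme$motif, subj, fixed = FALSE)
    starts <- Biostrings::start(hits)
    if (length(starts)) {
      # fixed=FALSE also lets ambiguity codes in the SEQUENCE match; the
      # assay treats those as uncallable, so require exact A/C/G/T there
      ok <- vapply(starts, function(s) {
        grepl("^[ACGT]+$", substr(sequence, s, s + nchar(enzyme$motif) - 1L))
      }, TRUE)
      starts <- starts[ok]
    }
    cuts <- sort(starts + enzyme$cutOffset - 1L)
    cuts <- cuts[cuts >= 1L & cuts < L]   # cut at 0 or L cuts nothing off
  }
  fragments <- diff(c(0L, cuts, L))
  structure(list(enzyme = enzyme$name, cuts = cuts, fragments = fragments),
            class = "DigestResult")
}

#' The four-lineage PCR-RFLP decision tree
#'
#' Ordered decision rules on SspI/DraI digest patterns of the cytochrome-b
#' amplicon: SspI uncut -> central; SspI cut at ~598 -> south; SspI cut at
#' ~166 then DraI cut at ~227 -> northwest, DraI uncut -> southwest.  Cut
#' positions are matched within a tolerance window.
#'
#' @param tolerance half-width of the cut-position window (bp).
#' @param enzymes named list with SspI and DraI [enzymeSpec()]s.
#' @return list of class \code{LineageRuleSet}.
#' @export
defaultLineageRules <- function(tolerance = 5L, enzymes = defaultEnzymes()) {
  structure(list(tolerance = as.integer(tolerance), enzymes = enzymes,
                 sspiSouth = 598L, sspiWestern = 166L, draiNorthwest = 227L),
            class = "LineageRuleSet")
}

#' Assign an mtDNA lineage from restriction digest patterns
#'
#' Applies the decision tree of [defaultLineageRules()] to one sequence.
#' A digest pattern matching no rule returns \code{"unassigned"}.
#'
#' @param sequence a single DNA string.
#' @param rules a [defaultLineageRules()] rule set.
#' @return one of \code{"central"}, \code{"south"}, \code{"southwest"},
#'   \code{"northwest"}, \code{"unassigned"}.
#' @export
assignLineage <- function(sequence, rules = defaultLineageRules()) {
  tol <- rules$tolerance
  sspi <- digestSequence(sequence, rules$enzymes$SspI)
  near <- function(cuts, pos) any(abs(cuts - pos) <= tol)
  if (length(sspi$cuts) == 0L) return("central")
  if (near(sspi$cuts, rules$sspiSouth) &&
      !near(sspi$cuts, rules$sspiWestern)) return("south")
  if (near(sspi$cuts, rules$sspiWestern) &&
      !near(sspi$cuts, rules$sspiSouth)) {
    drai <- digestSequence(sequence, rules$enzymes$DraI)
    if (length(drai$cuts) == 0L) return("southwest")
    if (near(drai$cuts, rules$draiNorthwest)) return("northwest")
    return("unassigned")
  }
  "unassigned"
}

#' Per-site mtDNA lineage frequencies along a transect
#'
#' @param td a [TransectDataset-class] with lineage assignments.
#' @return data.frame: one row per (site, lineage) with \code{freq}, plus
#'   per-site modal lineage and a tie flag in attributes \code{"modal"} and
#'   \code{"tie"} (named by site); sites with no assigned individual are
#'   flagged in attribute \code{"empty"}.
#' @export
lineageSiteFrequencies <- function(td) {
  stopifnot(is(td, "TransectDataset"))
  sites <- siteInfo(td)$site
  lin <- mtdnaLineage(td)
  siteMap <- siteOf(genotypes(td))
  rows <- list(); modal <- character(0); tie <- logical(0)
  empty <- character(0)
  for (s in sites) {
    ls <- lin[names(siteMap)[siteMap == s]]
    ls <- ls[!is.na(ls)]
    if (!length(ls)) {
      empty <- c(empty, s)
      modal[s] <- NA_character_; tie[s] <- NA
      next
    }
    tb <- table(ls)
    fr <- as.numeric(tb) / sum(tb)
    rows[[s]] <- data.frame(site = s, lineage = names(tb), freq = fr,
                            n = as.integer(tb), stringsAsFactors = FALSE)
    top <- names(tb)[tb == max(tb)]
    tie[s] <- length(top) > 1L
    modal[s] <- if (tie[s]) NA_character_ else top
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(site = character(0), lineage = character(0),
                      freq = numeric(0), n = integer(0))
  attr(out, "modal") <- modal
  attr(out, "tie") <- tie
  attr(out, "empty") <- empty
  out
}
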