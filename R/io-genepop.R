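#' Read genotypes from Genepop-formatted text
#'
#' Parses the de-facto exchange format for co-dominant multiallelic markers:
#' a title line, locus names (one per line or a single comma-separated
#' line), populations delimited by lines equal to \code{Pop}
#' (case-insensitive), and individuals written as
#' \code{"label , 001002 003003"} with 2- or 3-digit per-allele encoding.
#' \code{"00"}/\code{"000"} encodes a missing allele copy.  The digit width
#' is detected from the data and must be consistent throughout the file.
#'
#' @param text character: either a single string (possibly with embedded
#'   newlines), a character vector of lines, or the path of an existing
#'   file.
#' @return A [Genotypes-class] object; sites are the populations, labelled
#'   \code{pop_1 ... pop_n} in file order.
#' @examples
#' txt <- c("title", "locA", "locB", "Pop", "ind1 , 001002 003003")
#' g <- readGenepop(txt)
#' genotypeCalls(g)["ind1", , ]
#' @export
readGenepop <- function(text) {
  lines <- .asLines(text)
  # strip trailing blank lines, keep internal structure
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (length(lines) < 3L)
    stop("Genepop parse error: file too short (need title, loci, Pop)")
  isPop <- toupper(trimws(lines)) == "POP"
  if (!any(isPop))
    stop("Genepop parse error: no 'Pop' delimiter found (zero populations)")
  firstPop <- which(isPop)[1]
  if (firstPop < 3L)
    stop("Genepop parse error: no locus names before first 'Pop'")
  lociLines <- trimws(lines[2:(firstPop - 1L)])
  lociLines <- lociLines[nzchar(lociLines)]
  loci <- if (length(lociLines) == 1L && grepl(",", lociLines))
    trimws(strsplit(lociLines, ",")[[1]]) else lociLines
  nl <- length(loci)
  if (nl == 0L) stop("Genepop parse error: zero loci")

  popOf <- integer(0); ids <- character(0); rows <- list()
  pop <- 0L; width <- NA_integer_
  for (k in seq(firstPop, length(lines))) {
    ln <- trimws(lines[k])
    if (!nzchar(ln)) next
    if (toupper(ln) == "POP") { pop <- pop + 1L; next }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2L)
      stop("Genepop parse error at line ", k,
           ": expected 'label , genotypes'")
    id <- trimws(parts[1])
    gt <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                   "[[:space:]]+")[[1]]
    if (length(gt) != nl)
      stop("Genepop parse error at line ", k, ": individual '", id,
           "' has ", length(gt), " loci, expected ", nl)
    w <- unique(nchar(gt))
    if (length(w) != 1L || !(w %in% c(4L, 6L)))
      stop("Genepop parse error at line ", k,
           ": inconsistent allele-string widths (", paste(w, collapse = ","),
           "); expected uniform 4 (2-digit) or 6 (3-digit)")
    w <- w / 2L
    if (is.na(width)) width <- w
    else if (width != w)
      stop("Genepop parse error at line ", k,
           ": allele digit width ", w, " conflicts with earlier ", width)
    a1 <- as.integer(substr(gt, 1L, width))
    a2 <- as.integer(substr(gt, width + 1L, 2L * width))
    if (anyNA(a1) || anyNA(a2))
      stop("Genepop parse error at line ", k, ": non-numeric allele string")
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    ids <- c(ids, id); popOf <- c(popOf, pop)
    rows[[length(rows) + 1L]] <- c(a1, a2)
  }
  if (!length(rows))
    stop("Genepop parse error: no individuals found")
  if (anyDuplicated(ids))
    ids <- make.unique(ids, sep = "_")
  calls <- array(NA_integer_, dim = c(length(ids), nl, 2L),
                 dimnames = list(ids, loci, NULL))
  for (i in seq_along(rows)) {
    calls[i, , 1L] <- rows[[i]][seq_len(nl)]
    calls[i, , 2L] <- rows[[i]][nl + seq_len(nl)]
  }
  Genotypes(calls, siteOf = paste0("pop_", popOf))
}

#' Write genotypes as Genepop-formatted text
#'
#' Output is deterministic and byte-stable for identical input: individuals
#' are emitted in their stored order, populations in first-appearance order
#' of their site ids, alleles zero-padded to the chosen digit width.
#'
#' @param g a [Genotypes-class] object.
#' @param title title line (first line of the file).
#' @param digits per-allele digit width, 2 or 3.
#' @return character vector of lines.
#' @export
writeGenepop <- function(g, title = "contactzone export", digits = 3L) {
  stopifnot(is(g, "Genotypes"))
  if (!digits %in% c(2L, 3L)) stop("digits must be 2 or 3")
  if (nInd(g) == 0L) stop("cannot write Genepop with zero populations")
  mx <- suppressWarnings(max(g@calls, na.rm = TRUE))
  if (is.finite(mx) && mx > 10^digits - 1)
    stop("allele code ", mx, " does not fit in ", digits, " digits")
  fmt <- paste0("%0", digits, "d")
  pops <- unique(g@siteOf)
  out <- c(title, lociNames(g))
  for (p in pops) {
    out <- c(out, "Pop")
    for (i in which(g@siteOf == p)) {
      a <- g@calls[i, , , drop = FALSE]
      a[is.na(a)] <- 0L
      gt <- paste0(sprintf(fmt, a[1, , 1]), sprintf(fmt, a[1, , 2]))
      out <- c(out, paste(individualIds(g)[i], ",", paste(gt, collapse = " ")))
    }
  }
  out
}

#' Export genotypes as a flat numeric matrix for clustering
#'
#' One row per individual: a site index column followed by one column pair
#' per locus; missing allele copies are coded -9.
#'
#' @param g a [Genotypes-class] object.
#' @return integer matrix with rownames = individual ids.
#' @export
exportStructureMatrix <- function(g) {
  stopifnot(is(g, "Genotypes"))
  siteIdx <- as.integer(factor(g@siteOf, levels = unique(g@siteOf)))
  nl <- nLoci(g)
  m <- matrix(NA_integer_, nrow = nInd(g), ncol = 1L + 2L * nl)
  m[, 1] <- siteIdx
  for (l in seq_len(nl)) {
    m[, 2L * l]      <- g@calls[, l, 1]
    m[, 2L * l + 1L] <- g@calls[, l, 2]
  }
  m[is.na(m)] <- -9L
  rownames(m) <- individualIds(g)
  colnames(m) <- c("site", paste0(rep(lociNames(g), each = 2), c("_1", "_2")))
  m
}

.asLines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readChar(text, file.info(text)$size, useBytes = TRUE)
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  # tolerate CRLF line endings
  sub("\r$", "", text)
}
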