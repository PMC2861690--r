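#' Read DNA sequences from FASTA
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet}: sequences are
#' uppercased, ids are the first whitespace-delimited token of each header,
#' and non-IUPAC characters are rejected.
#'
#' @param text a file path, or FASTA text (single string or vector of
#'   lines).
#' @return a named character vector of uppercase sequences.
#' @examples
#' readFasta(c(">a desc", "acgt"))
#' @export
readFasta <- function(text) {
  lines <- .asLines(text)
  if (!length(lines) || !any(startsWith(trimws(lines), ">")))
    stop("FASTA parse error: no '>' record found")
  tf <- tempfile(fileext = ".fa")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  ss <- withCallingHandlers(
    tryCatch(Biostrings::readDNAStringSet(tf),
             error = function(e)
               stop("FASTA parse error: ", conditionMessage(e))),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes",
                conditionMessage(w)))
        stop("FASTA parse error: sequence characters outside the IUPAC set")
      invokeRestart("muffleWarning")
    })
  if (any(Biostrings::width(ss) == 0L))
    stop("FASTA parse error: empty record")
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "[[:space:]]+"), `[`, "", 1L)
  seqs
}

#' Read a transect site table from CSV
#'
#' Expects a header row with \code{transect}, \code{site}, optional
#' \code{position}, and the 19 named climate columns (checked against
#' \code{climateVariableNames()} unless \code{climateCols} overrides).  Row
#' order defines site order unless an explicit \code{position} column
#' overrides it, in which case rows are sorted by position.
#'
#' @param text CSV file path or CSV text.
#' @param climateCols character: required climate column names.
#' @return data.frame keyed by (transect, site) with \code{position} and the
#'   climate columns; attribute \code{"climateCols"} records which columns
#'   are climate variables.
#' @export
readTransectTable <- function(text, climateCols = climateVariableNames()) {
  lines <- .asLines(text)
  df <- read.csv(text = paste(lines, collapse = "\n"),
                 check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("transect", "site")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("site table format error: missing column(s) ",
         paste(miss, collapse = ", "))
  miss <- setdiff(climateCols, names(df))
  if (length(miss))
    stop("site table format error: missing climate column(s) ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df[c("transect", "site")]))
    stop("site table format error: duplicate (transect, site) key")
  cl <- as.matrix(df[climateCols])
  if (!all(is.finite(cl)))
    stop("site table validation error: non-finite climate value")
  prec <- grep("precip", climateCols, value = TRUE)
  if (length(prec) && any(cl[, prec] < 0))
    stop("site table validation error: negative precipitation value")
  if (!"position" %in% names(df)) {
    df$position <- stats::ave(seq_len(nrow(df)), df$transect,
                              FUN = seq_along)
  } else {
    df <- df[order(df$transect, df$position), , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "climateCols") <- climateCols
  df
}

#' The 19 bioclimatic variable names used throughout the package
#'
#' Worldclim-style bioclimatic summaries: eleven temperature and eight
#' precipitation variables.
#'
#' @return character vector of length 19.
#' @export
climateVariableNames <- function() {
  c("annual_mean_temp", "mean_diurnal_range", "isothermality",
    "temp_seasonality", "max_temp_warmest_month", "min_temp_coldest_month",
    "temp_annual_range", "mean_temp_wettest_q", "mean_temp_driest_q",
    "mean_temp_warmest_q", "mean_temp_coldest_q", "annual_precip",
    "precip_wettest_month", "precip_driest_month", "precip_seasonality",
    "precip_wettest_q", "precip_driest_q", "precip_warmest_q",
    "precip_coldest_q")
}
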