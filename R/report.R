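#' Render the per-residue prediction report
#'
#' Fixed-width text report in the style of a binding-site server result
#' page: the sequence in 60-residue blocks with a 1-based position label,
#' and under each sequence line one symbol line per method. Base-method
#' positives are marked \code{"+"}, meta-classifier positives \code{"*"},
#' and non-binding residues \code{"-"}.
#'
#' @param sequence amino-acid sequence (single string).
#' @param calls named list of 0/1 (or -1/+1) call vectors, each as long
#'   as the sequence; the entry named \code{metaName} is rendered with
#'   \code{"*"}.
#' @param metaName name of the meta-classifier track (default "meta").
#' @param width residues per block (default 60).
#' @return character scalar holding the formatted report.
#' @seealso [parseReport()] for the lossless inverse.
#' @export
renderReport <- function(sequence, calls, metaName = "meta", width = 60L) {
  n <- nchar(sequence)
  .stop_if(!length(calls) || is.null(names(calls)),
           "calls must be a named list")
  for (m in names(calls))
    .stop_if(length(calls[[m]]) != n,
             "track ", dQuote(m), " has ", length(calls[[m]]),
             " calls for ", n, " residues")
  lab_w <- max(nchar(names(calls)), nchar(as.character(n)), 8L)
  fmt <- function(label, body) sprintf("%*s %s", lab_w, label, body)
  blocks <- character()
  for (s in seq(1L, n, by = width)) {
    e <- min(n, s + width - 1L)
    lines <- fmt(s, substr(sequence, s, e))
    for (m in names(calls)) {
      y <- .as_pm1(calls[[m]][s:e])
      sym <- ifelse(y == 1L, if (m == metaName) "*" else "+", "-")
      lines <- c(lines, fmt(m, paste(sym, collapse = "")))
    }
    blocks <- c(blocks, paste(lines, collapse = "\n"))
  }
  paste0(paste(blocks, collapse = "\n\n"), "\n")
}

#' Parse a rendered prediction report
#'
#' Inverse of [renderReport()]: recovers the sequence and the per-method
#' 0/1 call tracks from the formatted text.
#'
#' @param text report text as returned by [renderReport()].
#' @return list with \code{sequence} and \code{calls} (named list of 0/1
#'   integer vectors).
#' @export
parseReport <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  seq_parts <- character()
  calls <- list()
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    m <- regmatches(ln, regexec("^\\s*(\\S+) (.*)$", ln))[[1]]
    .stop_if(length(m) != 3L, "unparseable report line: ", dQuote(ln))
    label <- m[2]
    body <- m[3]
    if (grepl("^[0-9]+$", label)) {
      seq_parts <- c(seq_parts, body)
    } else {
      calls[[label]] <- c(calls[[label]],
                          as.integer(strsplit(body, "")[[1]] %in% c("+", "*")))
    }
  }
  list(sequence = paste(seq_parts, collapse = ""), calls = calls)
}
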