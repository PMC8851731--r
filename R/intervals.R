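#' Genomic interval (0-based half-open)
#'
#' Light-weight interval container used throughout the package. Internally all
#' coordinates are 0-based half-open, the BED convention; browser-style text
#' such as `"chr8:41654877-41655984"` is 1-based fully-closed and is converted
#' losslessly by [format_interval()] / [parse_interval()].
#'
#' @param chrom chromosome name.
#' @param start,end 0-based half-open bounds; `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return an object of class `"genomic_interval"`.
#' @examples
#' gi <- genomic_interval("chr8", 41654876, 41655984)
#' format_interval(gi)
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (!isTRUE(start < end))
    stop("invalid interval: start (", start, ") must be < end (", end, ")")
  if (start < 0) stop("invalid interval: start must be >= 0")
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-', got '", strand, "'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat("<genomic_interval> ", format_interval(x), " (", x$strand, ")  [",
      x$end - x$start, " bp]\n", sep = "")
  invisible(x)
}

#' Interval width in bases
#' @param x a `genomic_interval`.
#' @return integer width.
#' @export
interval_width <- function(x) {
  stopifnot(inherits(x, "genomic_interval"))
  as.integer(x$end - x$start)
}

#' Display an interval as 1-based inclusive browser text
#'
#' @param x a `genomic_interval`.
#' @return a string `"chrom:start-end"` in 1-based fully-closed coordinates.
#' @seealso [parse_interval()] for the inverse.
#' @export
format_interval <- function(x) {
  stopifnot(inherits(x, "genomic_interval"))
  sprintf("%s:%d-%d", x$chrom, as.integer(x$start) + 1L, as.integer(x$end))
}

#' Parse 1-based inclusive browser text into a 0-based half-open interval
#'
#' Accepts `"chr8:41654877-41655984"`; thousands separators (commas) in the
#' coordinates are tolerated, as printed by genome browsers.
#'
#' @param text a single interval string.
#' @param strand strand to attach (`"+"` default).
#' @return a `genomic_interval`. Round-trips with [format_interval()].
#' @export
parse_interval <- function(text, strand = "+") {
  stopifnot(is.character(text), length(text) == 1L)
  text2 <- gsub(",", "", text, fixed = TRUE)
  m <- regmatches(text2, regexec("^([^:]+):([0-9]+)-([0-9]+)$", text2))[[1]]
  if (length(m) != 4L)
    stop("cannot parse interval text '", text, "'")
  genomic_interval(m[2], as.numeric(m[3]) - 1, as.numeric(m[4]),
                   strand = strand)
}

#' Test whether positions fall inside an interval
#' @param pos 0-based positions.
#' @param x a `genomic_interval`.
#' @return logical vector.
#' @export
in_interval <- function(pos, x) {
  stopifnot(inherits(x, "genomic_interval"))
  pos >= x$start & pos < x$end
}
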