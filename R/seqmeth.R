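# -- sequence utilities -------------------------------------------------------

.check_dna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0L)
    stop("non-IUPAC character '", substr(s, bad, bad),
         "' at 0-based position ", bad - 1L)
  s
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Locate CpG dinucleotides in a sequence
#'
#' Scans the plus strand for `CG` dinucleotides, the substrate of DNA
#' methylation. A CpG containing `N` is not a site.
#'
#' @param seq DNA string (A/C/G/T/N, case-insensitive).
#' @return ascending integer vector of 0-based positions `p` with
#'   `substr(seq, p+1, p+2) == "CG"`.
#' @examples
#' find_cpg_sites("ACGCGT")  # 1, 3
#' @export
find_cpg_sites <- function(seq) {
  s <- .check_dna(seq)
  hits <- gregexpr("CG", s, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

# -- methylation patterns -----------------------------------------------------

#' Per-CpG methylation pattern over a sequence
#'
#' Records, for CpG sites of a sequence, whether each is methylated. Positions
#' are 0-based plus-strand coordinates of the CpG cytosine.
#'
#' @param positions 0-based CpG positions.
#' @param methylated logical vector parallel to `positions`.
#' @param interval optional `genomic_interval` the pattern lives on; when
#'   given, all positions must fall inside it.
#' @param seq optional sequence to validate positions against (every position
#'   must be a CpG site of `seq`).
#' @return object of class `"methylation_pattern"`.
#' @export
methylation_pattern <- function(positions, methylated, interval = NULL,
                                seq = NULL) {
  positions <- as.integer(positions)
  stopifnot(is.logical(methylated), length(methylated) == length(positions))
  if (anyDuplicated(positions)) stop("duplicated CpG positions in pattern")
  o <- order(positions)
  positions <- positions[o]; methylated <- methylated[o]
  if (!is.null(seq)) {
    cpgs <- find_cpg_sites(seq)
    bad <- setdiff(positions, cpgs)
    if (length(bad))
      stop("pattern position(s) not CpG sites: ", paste(bad, collapse = ", "))
  }
  if (!is.null(interval)) {
    if (!all(in_interval(positions, interval)))
      stop("pattern positions outside interval ", format_interval(interval))
  }
  structure(list(positions = positions, methylated = methylated,
                 interval = interval),
            class = "methylation_pattern")
}

#' @export
print.methylation_pattern <- function(x, ...) {
  cat("<methylation_pattern> ", length(x$positions), " CpG sites, ",
      sum(x$methylated), " methylated\n", sep = "")
  invisible(x)
}

# -- bisulfite conversion -----------------------------------------------------

#' In-silico bisulfite conversion
#'
#' Applies the bisulfite chemistry rules to a sequence: every cytosine is
#' deaminated to (read as) thymine except 5-methyl-cytosines, which only occur
#' at methylated CpG sites. For the minus strand the same rule is applied to
#' the reverse complement -- the bottom-strand cytosine of a plus-strand CpG
#' (the complement of its G) is protected iff that CpG is methylated -- and
#' the result is reported 5'->3' of the converted bottom strand itself.
#' `N` bases pass through unchanged.
#'
#' @param seq DNA string.
#' @param pattern either a [methylation_pattern()] or an integer vector of
#'   0-based plus-strand positions of *methylated* CpG cytosines; CpG sites
#'   not listed are treated as unmethylated. Positions that are not CpG sites
#'   of `seq` are an error.
#' @param strand `"+"` (default) or `"-"`.
#' @return converted DNA string.
#' @examples
#' bisulfite_convert("TACGTC", 2)           # "TACGTT"
#' bisulfite_convert("TACGTC", integer(0))  # "TATGTT"
#' @export
bisulfite_convert <- function(seq, pattern = integer(0), strand = "+") {
  s <- .check_dna(seq)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  meth <- if (inherits(pattern, "methylation_pattern")) {
    # validate every key, methylated or not, against the sequence
    cpgs <- find_cpg_sites(s)
    bad <- setdiff(pattern$positions, cpgs)
    if (length(bad))
      stop("pattern position(s) not CpG sites of the sequence: ",
           paste(bad, collapse = ", "))
    pattern$positions[pattern$methylated]
  } else {
    as.integer(pattern)
  }
  cpgs <- find_cpg_sites(s)
  bad <- setdiff(meth, cpgs)
  if (length(bad))
    stop("pattern position(s) not CpG sites of the sequence: ",
         paste(bad, collapse = ", "))

  if (strand == "-") {
    L <- nchar(s)
    # bottom-strand C of plus-strand CpG at p sits opposite the G at p+1,
    # i.e. at reverse-complement coordinate L - p - 2 (CG is its own revcomp)
    return(bisulfite_convert(.revcomp(s), L - meth - 2L, "+"))
  }

  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  is_c <- chars == "C"
  keep <- rep(FALSE, length(chars))
  if (length(meth)) keep[meth + 1L] <- TRUE
  chars[is_c & !keep] <- "T"
  paste(chars, collapse = "")
}

#' Fully methylated / unmethylated MSP templates for both strands
#'
#' Generates the four bisulfite-converted templates that MSP primer pairs are
#' designed against: each strand converted under an all-methylated and an
#' all-unmethylated pattern. For a CpG-containing sequence the two templates
#' of a strand differ at exactly the CpG-cytosine positions.
#'
#' @param seq DNA string, non-empty.
#' @return named list with elements `plus_methylated`, `plus_unmethylated`,
#'   `minus_methylated`, `minus_unmethylated`.
#' @export
make_msp_templates <- function(seq) {
  s <- .check_dna(seq)
  if (nchar(s) == 0L) stop("empty sequence")
  cpgs <- find_cpg_sites(s)
  list(plus_methylated   = bisulfite_convert(s, cpgs, "+"),
       plus_unmethylated = bisulfite_convert(s, integer(0), "+"),
       minus_methylated   = bisulfite_convert(s, cpgs, "-"),
       minus_unmethylated = bisulfite_convert(s, integer(0), "-"))
}

#' Exact primer matches against a template
#'
#' Reports every position where the primer, or its reverse complement, matches
#' the template exactly. No mismatch tolerance: MSP specificity is expressed
#' as perfect-match/no-match of the methylated- versus unmethylated-converted
#' template.
#'
#' @param primer DNA string, length >= 10.
#' @param template DNA string.
#' @return sorted integer vector of 0-based match start positions (empty when
#'   the primer cannot anneal perfectly in either orientation).
#' @export
primer_matches <- function(primer, template) {
  p <- .check_dna(primer); t <- .check_dna(template)
  if (nchar(p) < 10L) stop("primer length must be >= 10")
  tmpl <- Biostrings::DNAString(t)
  hits <- function(q)
    Biostrings::start(Biostrings::matchPattern(Biostrings::DNAString(q), tmpl))
  sort(unique(c(hits(p), hits(.revcomp(p))))) - 1L
}

# -- bisulfite-sequencing trace quantification --------------------------------

#' Methylation ratio from Sanger trace peak heights
#'
#' Semi-quantitative degree of methylation at a CpG site after direct
#' bisulfite sequencing: the cytosine peak height relative to the sum of the
#' cytosine and thymine peaks, `C / (C + T)`.
#'
#' @param c_height,t_height non-negative peak intensities (arbitrary units);
#'   vectorised. A site where both peaks are zero is undefined and raises an
#'   error (use [call_traces()] for table-level no-call handling).
#' @return ratio(s) in \[0, 1\].
#' @examples
#' quantify_trace(900, 100)  # 0.9
#' @export
quantify_trace <- function(c_height, t_height) {
  stopifnot(length(c_height) == length(t_height))
  if (any(c_height < 0 | t_height < 0))
    stop("peak heights must be non-negative")
  tot <- c_height + t_height
  if (any(tot == 0))
    stop("undefined site: cytosine and thymine peaks both zero at index ",
         which(tot == 0)[1])
  c_height / tot
}

#' Classify a bisulfite-sequencing methylation ratio
#'
#' Three-class call used to draw lollipop diagrams: ratios up to 0.20 are
#' unmethylated, above 0.20 and up to 0.80 partially methylated, above 0.80
#' methylated. The printed two-decimal bands 0-0.2 / 0.21-0.8 / 0.81-1.0 are
#' generalised to real ratios as half-open intervals preserving the membership
#' of every two-decimal value.
#'
#' @param ratio numeric vector in \[0, 1\].
#' @return character vector in `c("unmethylated", "partial", "methylated")`.
#' @export
classify_bs_ratio <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio < 0 | ratio > 1))
    stop("ratio must lie in [0, 1]")
  ifelse(ratio <= 0.20, "unmethylated",
         ifelse(ratio <= 0.80, "partial", "methylated"))
}

#' Call a trace table
#'
#' Applies [quantify_trace()] and [classify_bs_ratio()] to a per-CpG peak
#' height table. Sites with both peaks zero are reported as `"no-call"` with
#' an `NA` ratio rather than dropped or zeroed.
#'
#' @param traces data.frame with columns `site`, `c_height`, `t_height`.
#' @return data.frame `site`, `ratio`, `call`.
#' @export
call_traces <- function(traces) {
  stopifnot(all(c("site", "c_height", "t_height") %in% names(traces)))
  tot <- traces$c_height + traces$t_height
  ratio <- rep(NA_real_, nrow(traces))
  ok <- tot > 0
  ratio[ok] <- quantify_trace(traces$c_height[ok], traces$t_height[ok])
  call <- rep("no-call", nrow(traces))
  call[ok] <- classify_bs_ratio(ratio[ok])
  if (any(!ok))
    message(sum(!ok), " site(s) with zero total signal reported as no-call")
  data.frame(site = traces$site, ratio = ratio, call = call)
}

# -- qualitative MSP ----------------------------------------------------------

#' Score a methylation-specific PCR result
#'
#' MSP runs one primer pair specific for the methylated-converted template (M
#' band) and one for the unmethylated-converted template (U band). Both bands
#' present means the locus is hemimethylated (or a mixed population); neither
#' band means the reaction failed.
#'
#' @param m_band,u_band logical; band presence. Vectorised.
#' @return character vector in
#'   `c("methylated", "unmethylated", "hemimethylated", "failed")` and, for
#'   scalar input, an object of class `"msp_call"` with the band booleans.
#' @examples
#' call_msp(TRUE, FALSE)  # methylated
#' call_msp(TRUE, TRUE)   # hemimethylated
#' @export
call_msp <- function(m_band, u_band) {
  stopifnot(is.logical(m_band), is.logical(u_band),
            length(m_band) == length(u_band))
  status <- ifelse(m_band & u_band, "hemimethylated",
                   ifelse(m_band, "methylated",
                          ifelse(u_band, "unmethylated", "failed")))
  if (length(status) == 1L)
    return(structure(list(m_band = m_band, u_band = u_band, status = status),
                     class = "msp_call"))
  status
}

#' @export
print.msp_call <- function(x, ...) {
  cat("<msp_call> M:", x$m_band, " U:", x$u_band, " -> ", x$status, "\n",
      sep = "")
  invisible(x)
}
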