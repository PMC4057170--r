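# Genomic intervals and overlap queries.
#
# Every coordinate in this package is 0-based half-open [start, end), the
# native BED convention. Intervals are plain data frames with columns
# chrom / start / end / name / score / strand; strand "*" means unknown.

#' Construct a set of genomic intervals
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; 0-based half-open coordinates with
#'   `end > start`.
#' @param name Optional interval names.
#' @param score Optional numeric scores.
#' @param strand Strand, one of `"+"`, `"-"`, `"*"` (unknown).
#' @return A data frame of intervals.
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              score = NA_real_, strand = "*") {
  n <- length(chrom)
  name <- rep_len(as.character(name), n)
  score <- rep_len(as.numeric(score), n)
  strand <- rep_len(as.character(strand), n)
  x <- data.frame(chrom = as.character(chrom),
                  start = as.integer(start),
                  end = as.integer(end),
                  name = as.character(name),
                  score = as.numeric(score),
                  strand = as.character(strand),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

validate_intervals <- function(x, what = "interval set") {
  abort_if(!is.data.frame(x) ||
             !all(c("chrom", "start", "end") %in% names(x)),
           what, " must be a data frame with chrom/start/end columns")
  if (nrow(x) == 0L) return(invisible(x))
  abort_if(any(!is.finite(x$start)) || any(!is.finite(x$end)),
           what, ": non-finite coordinates")
  abort_if(any(x$start < 0), what, ": negative start coordinate")
  abort_if(any(x$end <= x$start), what, ": empty or inverted interval")
  if ("strand" %in% names(x)) {
    abort_if(!all(x$strand %in% c("+", "-", "*")),
             what, ": strand must be one of +, -, *")
  }
  invisible(x)
}

#' Interval lengths in base pairs
#' @param x An interval data frame.
#' @return Integer vector `end - start`.
#' @export
interval_width <- function(x) x$end - x$start

# All overlapping (query, subject) index pairs under half-open semantics.
# The 0-based half-open [start, end) maps onto the 1-based closed
# IRanges [start + 1, end].
overlap_pairs <- function(query, subject) {
  q_idx <- integer(0)
  s_idx <- integer(0)
  if (nrow(query) && nrow(subject)) {
    for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
      qi <- which(query$chrom == ch)
      si <- which(subject$chrom == ch)
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi]),
        IRanges::IRanges(start = subject$start[si] + 1L, end = subject$end[si]))
      q_idx <- c(q_idx, qi[S4Vectors::queryHits(hits)])
      s_idx <- c(s_idx, si[S4Vectors::subjectHits(hits)])
    }
  }
  data.frame(query = q_idx, subject = s_idx)
}

# Pairs between genomic point positions (width-1 features such as tag 5'
# ends or CpG cytosines) and an interval set.
point_overlap_pairs <- function(chrom, pos, subject) {
  pts <- data.frame(chrom = chrom, start = pos, end = pos + 1L)
  overlap_pairs(pts, subject)
}

#' Does each query interval overlap any subject interval?
#'
#' @param query,subject Interval data frames.
#' @return Logical vector, one entry per query row; overlap means sharing
#'   at least one base under half-open semantics.
#' @export
overlaps_any <- function(query, subject) {
  out <- logical(nrow(query))
  hits <- overlap_pairs(query, subject)
  out[unique(hits$query)] <- TRUE
  out
}

#' Query all intervals overlapping a probe
#'
#' Returns every interval in `intervals` sharing at least one base with the
#' probe. Touching end-to-start under half-open coordinates is not an
#' overlap. An empty result is not an error.
#'
#' @param intervals Interval data frame to search.
#' @param probe A single-row interval data frame.
#' @return The overlapping subset of `intervals`, in original order.
#' @export
query_overlaps <- function(intervals, probe) {
  validate_intervals(intervals)
  validate_intervals(probe, "probe")
  abort_if(nrow(probe) != 1L, "probe must be a single interval")
  hits <- overlap_pairs(probe, intervals)
  intervals[sort(unique(hits$subject)), , drop = FALSE]
}
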