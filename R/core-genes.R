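# Gene models, CpG tables, tag tracks and the genome annotation container.

#' Construct a gene model table
#'
#' Genes are stored BED12-style: one row per gene with the transcript span
#' and the exon structure encoded as comma-separated block sizes and
#' gene-relative block starts. The TSS is `start` on the plus strand and
#' `end - 1` on the minus strand; the TES is the opposite end.
#'
#' @param gene_id Character gene identifiers (unique).
#' @param chrom,start,end Transcript span, 0-based half-open.
#' @param strand `"+"` or `"-"` (required: the TSS is undefined otherwise).
#' @param exon_starts,exon_sizes Comma-separated integers; starts are
#'   relative to `start`. Exons must be sorted, non-overlapping and
#'   contained in the span.
#' @return A gene table data frame.
#' @export
gene_table <- function(gene_id, chrom, start, end, strand,
                       exon_starts, exon_sizes) {
  g <- data.frame(gene_id = as.character(gene_id),
                  chrom = as.character(chrom),
                  start = as.integer(start),
                  end = as.integer(end),
                  strand = as.character(strand),
                  exon_starts = as.character(exon_starts),
                  exon_sizes = as.character(exon_sizes),
                  stringsAsFactors = FALSE)
  validate_genes(g)
  g
}

split_ints <- function(s) lapply(strsplit(s, ",", fixed = TRUE),
                                 function(v) as.integer(v[nzchar(v)]))

validate_genes <- function(g) {
  abort_if(!all(c("gene_id", "chrom", "start", "end", "strand",
                  "exon_starts", "exon_sizes") %in% names(g)),
           "gene table is missing required columns")
  if (nrow(g) == 0L) return(invisible(g))
  abort_if(anyDuplicated(g$gene_id) > 0, "duplicate gene ids")
  abort_if(!all(g$strand %in% c("+", "-")),
           "gene strand must be '+' or '-' (TSS undefined otherwise)")
  abort_if(any(g$end <= g$start) || any(g$start < 0),
           "gene spans must be non-empty with start >= 0")
  st <- split_ints(g$exon_starts)
  sz <- split_ints(g$exon_sizes)
  for (i in seq_len(nrow(g))) {
    abort_if(length(st[[i]]) != length(sz[[i]]) || length(st[[i]]) == 0L,
             "gene ", g$gene_id[i], ": inconsistent exon blocks")
    ends <- st[[i]] + sz[[i]]
    abort_if(any(sz[[i]] <= 0) || is.unsorted(st[[i]], strictly = TRUE) ||
               any(st[[i]][-1] < ends[-length(ends)]) ||
               any(ends > g$end[i] - g$start[i]) || any(st[[i]] < 0),
             "gene ", g$gene_id[i],
             ": exons must be sorted, non-overlapping and within the span")
  }
  invisible(g)
}

#' Transcription start sites (0-based position of the first transcribed base)
#' @param genes A gene table.
#' @return Integer vector of TSS positions.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

#' Transcription end sites (0-based position of the last transcribed base)
#' @param genes A gene table.
#' @return Integer vector of TES positions.
#' @export
gene_tes <- function(genes) {
  ifelse(genes$strand == "+", genes$end - 1L, genes$start)
}

#' Expand a gene table into one interval per exon
#' @param genes A gene table.
#' @return Interval data frame with a `gene_id` column.
#' @export
gene_exons <- function(genes) {
  if (nrow(genes) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gene_id = character(0)))
  }
  st <- split_ints(genes$exon_starts)
  sz <- split_ints(genes$exon_sizes)
  n <- lengths(st)
  data.frame(chrom = rep(genes$chrom, n),
             start = rep(genes$start, n) + unlist(st),
             end = rep(genes$start, n) + unlist(st) + unlist(sz),
             gene_id = rep(genes$gene_id, n),
             stringsAsFactors = FALSE)
}

#' Bundle chromosome sizes, gene models and CpG islands
#'
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param genes A gene table.
#' @param cgis CpG islands as an interval data frame.
#' @return A `genome_annotation` object.
#' @export
genome_annotation <- function(chrom_sizes, genes, cgis) {
  abort_if(is.null(names(chrom_sizes)) || any(chrom_sizes <= 0),
           "chrom_sizes must be a named vector of positive lengths")
  validate_genes(genes)
  validate_intervals(cgis, "CGI set")
  check_bounds <- function(x, what) {
    abort_if(!all(x$chrom %in% names(chrom_sizes)),
             what, " on a chromosome absent from chrom_sizes")
    abort_if(any(x$end > chrom_sizes[x$chrom]),
             what, " extends past the chromosome end")
  }
  if (nrow(genes)) check_bounds(genes, "gene")
  if (nrow(cgis)) check_bounds(cgis, "CGI")
  structure(list(chrom_sizes = chrom_sizes, genes = genes, cgis = cgis),
            class = "genome_annotation")
}

#' Construct a per-CpG methylation table
#'
#' One row per CpG dinucleotide (position of the plus-strand cytosine),
#' already strand-merged. Rows are sorted by (chrom, pos) and duplicate
#' positions are rejected.
#'
#' @param chrom,pos CpG locations (0-based).
#' @param meth Methylation fraction in `[0, 1]`.
#' @param coverage Non-negative read counts.
#' @return A `cpg_table` data frame.
#' @export
cpg_table <- function(chrom, pos, meth, coverage) {
  x <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  meth = as.numeric(meth), coverage = as.integer(coverage),
                  stringsAsFactors = FALSE)
  abort_if(any(x$pos < 0), "CpG positions must be >= 0")
  abort_if(any(x$meth < 0 | x$meth > 1), "meth_fraction outside [0, 1]")
  abort_if(any(x$coverage < 0), "coverage must be >= 0")
  x <- x[order(x$chrom, x$pos), , drop = FALSE]
  abort_if(anyDuplicated(x[c("chrom", "pos")]) > 0, "duplicate CpG positions")
  rownames(x) <- NULL
  class(x) <- c("cpg_table", "data.frame")
  x
}

#' Construct a tag track
#'
#' A named set of aligned-read 5' positions with a total-mapped-read count
#' used for depth normalization.
#'
#' @param name Track name.
#' @param chrom,pos,strand Per-tag location of the read 5' end.
#' @param total_mapped Total uniquely mapped reads; defaults to the number
#'   of tags and must not be smaller than it.
#' @return A `tag_track` object.
#' @export
tag_track <- function(name, chrom, pos, strand, total_mapped = NULL) {
  tags <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                     strand = as.character(strand), stringsAsFactors = FALSE)
  abort_if(any(tags$pos < 0), "tag positions must be >= 0")
  abort_if(!all(tags$strand %in% c("+", "-")), "tag strand must be + or -")
  total_mapped <- as.double(total_mapped %||% nrow(tags))
  abort_if(total_mapped < nrow(tags),
           "total_mapped must be >= number of tags")
  structure(list(name = name, tags = tags, total_mapped = total_mapped),
            class = "tag_track")
}
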