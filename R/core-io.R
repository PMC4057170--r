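# Readers and writers for the on-disk dialects the pipeline touches:
# BED3/6 intervals, BED6 tag files, BED12 gene models, the methcounts
# per-CpG table, bedGraph window tracks and the cohort matrix TSV.
# All files are tab-separated; gzip is handled transparently by R
# connections; "track", "browser" and "#" lines are ignored.

bed_lines <- function(path) {
  abort_if(!file.exists(path), "file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  list(lines = lines[keep], lineno = which(keep))
}

parse_int_col <- function(x, lineno, path, what) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v) & !is.na(x))
  abort_if(length(bad) > 0, path, " line ", lineno[bad[1]],
           ": non-integer ", what, " ('", x[bad[1]], "')")
  v
}

read_bed_fields <- function(path, min_fields) {
  b <- bed_lines(path)
  if (length(b$lines) == 0L) {
    return(list(fields = list(), lineno = integer(0)))
  }
  fields <- strsplit(b$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < min_fields)
  abort_if(length(bad) > 0, path, " line ", b$lineno[bad[1]], ": expected >= ",
           min_fields, " tab-separated fields, found ", nf[bad[1]])
  list(fields = fields, lineno = b$lineno)
}

field_matrix <- function(fields, k) {
  vapply(fields, function(f) if (length(f) >= k) f[k] else NA_character_,
         character(1))
}

#' Read intervals from a BED file
#'
#' BED3 through BED6 columns are recognised; coordinates are kept 0-based
#' half-open as in the file. A missing strand column (or `"."`) becomes
#' `"*"` (unknown). Malformed lines raise an error naming the line number.
#'
#' @param path BED file (optionally gzipped).
#' @return Interval data frame in file order.
#' @export
read_bed <- function(path) {
  p <- read_bed_fields(path, 3L)
  if (length(p$fields) == 0L) {
    return(genomic_intervals(character(0), integer(0), integer(0)))
  }
  chrom <- field_matrix(p$fields, 1L)
  start <- parse_int_col(field_matrix(p$fields, 2L), p$lineno, path, "start")
  end <- parse_int_col(field_matrix(p$fields, 3L), p$lineno, path, "end")
  bad <- which(end <= start | start < 0)
  abort_if(length(bad) > 0, path, " line ", p$lineno[bad[1]],
           ": invalid interval [", start[bad[1]], ", ", end[bad[1]], ")")
  name <- field_matrix(p$fields, 4L)
  score <- suppressWarnings(as.numeric(field_matrix(p$fields, 5L)))
  strand <- field_matrix(p$fields, 6L)
  strand[is.na(strand) | strand == "."] <- "*"
  abort_if(!all(strand %in% c("+", "-", "*")),
           path, ": invalid strand field")
  genomic_intervals(chrom, start, end, name, score, strand)
}

#' Write intervals as BED6
#' @param x Interval data frame.
#' @param path Output file.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  out <- data.frame(x$chrom, x$start, x$end,
                    ifelse(is.na(x$name), ".", x$name),
                    ifelse(is.na(x$score), ".", as.character(x$score)),
                    ifelse(x$strand == "*", ".", x$strand))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a methcounts-style per-CpG methylation table
#'
#' Dialect: tab-separated columns chrom, pos (0-based), strand, context,
#' meth_fraction (0-1), coverage. Only CpG-context rows are retained; the
#' number of skipped non-CpG rows is reported via `message()` and attached
#' as attribute `n_skipped`.
#'
#' @param path Methcounts file (optionally gzipped).
#' @return A `cpg_table`, sorted by (chrom, pos).
#' @export
read_methcounts <- function(path) {
  p <- read_bed_fields(path, 6L)
  if (length(p$fields) == 0L) {
    out <- cpg_table(character(0), integer(0), numeric(0), integer(0))
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  chrom <- field_matrix(p$fields, 1L)
  pos <- parse_int_col(field_matrix(p$fields, 2L), p$lineno, path, "position")
  context <- field_matrix(p$fields, 4L)
  meth <- suppressWarnings(as.numeric(field_matrix(p$fields, 5L)))
  bad <- which(is.na(meth) | meth < 0 | meth > 1)
  abort_if(length(bad) > 0, path, " line ", p$lineno[bad[1]],
           ": meth_fraction outside [0, 1]")
  cov <- parse_int_col(field_matrix(p$fields, 6L), p$lineno, path, "coverage")
  keep <- toupper(context) %in% c("CPG", "CG")
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message("read_methcounts: skipped ", n_skipped, " non-CpG context rows")
  }
  out <- cpg_table(chrom[keep], pos[keep], meth[keep], cov[keep])
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a CpG table in the methcounts dialect
#' @param cpgs A `cpg_table`.
#' @param path Output file.
#' @export
write_methcounts <- function(cpgs, path) {
  out <- data.frame(cpgs$chrom, cpgs$pos, "+", "CpG",
                    format(cpgs$meth, digits = 15, trim = TRUE,
                           scientific = FALSE),
                    cpgs$coverage)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a BED12 file
#'
#' Exons are reconstructed from blockSizes/blockStarts. Strand is required
#' (the TSS is undefined without it) and blocks must be internally
#' consistent.
#'
#' @param path BED12 file.
#' @return A gene table.
#' @export
read_gene_table <- function(path) {
  p <- read_bed_fields(path, 12L)
  if (length(p$fields) == 0L) {
    return(gene_table(character(0), character(0), integer(0), integer(0),
                      character(0), character(0), character(0)))
  }
  chrom <- field_matrix(p$fields, 1L)
  start <- parse_int_col(field_matrix(p$fields, 2L), p$lineno, path, "start")
  end <- parse_int_col(field_matrix(p$fields, 3L), p$lineno, path, "end")
  name <- field_matrix(p$fields, 4L)
  strand <- field_matrix(p$fields, 6L)
  abort_if(!all(strand %in% c("+", "-")),
           path, ": gene records require strand '+' or '-'")
  n_blocks <- parse_int_col(field_matrix(p$fields, 10L), p$lineno, path,
                            "blockCount")
  sizes <- field_matrix(p$fields, 11L)
  starts <- field_matrix(p$fields, 12L)
  sz <- split_ints(sizes)
  st <- split_ints(starts)
  bad <- which(lengths(sz) != n_blocks | lengths(st) != n_blocks)
  abort_if(length(bad) > 0, path, " line ", p$lineno[bad[1]],
           ": blockCount does not match blockSizes/blockStarts")
  gene_table(name, chrom, start, end, strand,
             vapply(st, paste, character(1), collapse = ","),
             vapply(sz, paste, character(1), collapse = ","))
}

#' Write a gene table as BED12
#' @param genes A gene table.
#' @param path Output file.
#' @export
write_gene_table <- function(genes, path) {
  validate_genes(genes)
  st <- split_ints(genes$exon_starts)
  out <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id, 0,
                    genes$strand, genes$start, genes$end, "0,0,0",
                    lengths(st),
                    paste0(genes$exon_sizes, ","),
                    paste0(genes$exon_starts, ","))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read aligned-read tags from a BED6 file
#'
#' Each record is one aligned read; the tag is the 5' end, i.e. `start` on
#' the plus strand and `end - 1` on the minus strand.
#'
#' @param path BED6 file.
#' @param name Track name (defaults to the file name).
#' @param total_mapped Total mapped reads; defaults to the record count.
#' @return A `tag_track`.
#' @export
read_tags <- function(path, name = basename(path), total_mapped = NULL) {
  x <- read_bed(path)
  abort_if(nrow(x) > 0 && any(x$strand == "*"),
           path, ": tag records require strand")
  pos <- ifelse(x$strand == "+", x$start, x$end - 1L)
  tag_track(name, x$chrom, pos, x$strand, total_mapped)
}

#' Write a tag track as BED6 (one 1-bp record per tag)
#' @param track A `tag_track`.
#' @param path Output file.
#' @export
write_tags <- function(track, path) {
  t <- track$tags
  out <- data.frame(t$chrom, t$pos, t$pos + 1L, track$name, 0, t$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a window track as bedGraph
#' @param track A `window_track` data frame (chrom/start/end/value).
#' @param path Output file.
#' @param name Track name for the header line.
#' @export
write_bedgraph <- function(track, path, name = "track") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  utils::write.table(
    data.frame(track$chrom, track$start, track$end,
               format(track$value, digits = 10, trim = TRUE)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a cohort methylation matrix
#'
#' Layout: a header row of sample ids, a second row of tumor/normal group
#' labels, then one row per site (`chrom:start-end`, one value per sample).
#'
#' @param m A `cohort_matrix`.
#' @param path Output file.
#' @export
write_cohort_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("site", m$samples), collapse = "\t"), con)
  writeLines(paste(c("group", m$groups), collapse = "\t"), con)
  keys <- sprintf("%s:%d-%d", m$sites$chrom, m$sites$start, m$sites$end)
  vals <- t(m$values)  # sites x samples on disk
  body <- apply(cbind(keys, format(vals, digits = 15, trim = TRUE,
                                   scientific = FALSE)),
                1, paste, collapse = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a cohort methylation matrix
#' @param path File written in the layout of [write_cohort_matrix()].
#' @return A `cohort_matrix`.
#' @export
read_cohort_matrix <- function(path) {
  lines <- readLines(path)
  abort_if(length(lines) < 3L, path, ": cohort matrix needs a sample row, ",
           "a group row and at least one site row")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  groups <- strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1]
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  keys <- vapply(body, `[`, character(1), 1L)
  km <- regmatches(keys, regexec("^(.+):([0-9]+)-([0-9]+)$", keys))
  abort_if(any(lengths(km) != 4L), path, ": malformed site key")
  sites <- genomic_intervals(
    chrom = vapply(km, `[`, character(1), 2L),
    start = as.integer(vapply(km, `[`, character(1), 3L)),
    end = as.integer(vapply(km, `[`, character(1), 4L)))
  vals <- vapply(body, function(f) {
    suppressWarnings(as.numeric(f[-1]))
  }, numeric(length(header)))
  # vapply stacks one column per site, so vals is already samples x sites
  vals <- if (is.null(dim(vals))) matrix(vals, nrow = length(header)) else vals
  cohort_matrix(values = vals, samples = header, groups = groups,
                sites = sites)
}
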