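# Expression / coverage based gene stratification: RPKM, tertile tiers,
# gene-body densities, and the comparison of a gene subset to the tiers.

#' RPKM from read counts
#'
#' `RPKM = count / (length/1e3 * total/1e6)` - reads per kilobase of gene
#' model per million (uniquely) mapped reads.
#'
#' @param counts Per-gene read counts.
#' @param gene_length Gene lengths in bp (all > 0).
#' @param total_mapped Total mapped reads (> 0).
#' @return Numeric RPKM vector.
#' @export
compute_rpkm <- function(counts, gene_length, total_mapped) {
  abort_if(any(gene_length <= 0), "gene lengths must be positive")
  abort_if(total_mapped <= 0, "total_mapped must be positive")
  counts / ((gene_length / 1e3) * (total_mapped / 1e6))
}

#' Split genes into high / medium / low tertiles
#'
#' Ineligible genes (default: `value <= 0`, i.e. not expressed) are
#' excluded and keep an `NA` tier. The remainder are ranked descending
#' (ties broken by stable input order) and cut into three equal bins;
#' remainder genes go to "high" first, then "medium".
#'
#' @param gene_id Gene identifiers.
#' @param value Per-gene values (RPKM, tags per bp, ...).
#' @param eligible Logical eligibility mask; default `value > 0`.
#' @return Data frame gene_id / value / tier (factor high/medium/low, NA if
#'   ineligible), in input order.
#' @export
tertile_bins <- function(gene_id, value, eligible = value > 0) {
  abort_if(length(gene_id) != length(value), "gene_id/value length mismatch")
  idx <- which(eligible)
  abort_if(length(idx) < 3L, "need at least 3 eligible genes")
  ord <- idx[order(-value[idx])]  # stable: ties keep input order
  n <- length(ord)
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- c(high = base + (rem >= 1), medium = base + (rem >= 2),
             low = base)
  tier_ranked <- rep(c("high", "medium", "low"), times = sizes)
  tier <- rep(NA_character_, length(gene_id))
  tier[ord] <- tier_ranked
  data.frame(gene_id = gene_id, value = value,
             tier = factor(tier, levels = c("high", "medium", "low")),
             stringsAsFactors = FALSE)
}

#' Tag or methylated-CpG density over gene bodies
#'
#' For a `tag_track`: tag 5' positions within `[start, end)` divided by
#' gene length (tags per bp). For a `cpg_table`: the sum of methylation
#' fractions within the span divided by gene length (methylated-CpG
#' equivalents per bp).
#'
#' @param x A `tag_track` or `cpg_table`.
#' @param genes Gene table.
#' @return Numeric vector, one density per gene.
#' @export
genebody_density <- function(x, genes) {
  spans <- data.frame(chrom = genes$chrom, start = genes$start,
                      end = genes$end)
  out <- numeric(nrow(genes))
  if (inherits(x, "tag_track")) {
    hits <- point_overlap_pairs(x$tags$chrom, x$tags$pos, spans)
    if (nrow(hits)) {
      s <- table(hits$subject)
      out[as.integer(names(s))] <- as.numeric(s)
    }
  } else if (inherits(x, "cpg_table")) {
    hits <- point_overlap_pairs(x$chrom, x$pos, spans)
    if (nrow(hits)) {
      s <- tapply(x$meth[hits$query], hits$subject, sum)
      out[as.integer(names(s))] <- as.numeric(s)
    }
  } else {
    stop("genebody_density expects a tag_track or cpg_table", call. = FALSE)
  }
  out / (genes$end - genes$start)
}

#' Compare a gene subset against the tertile tiers
#'
#' Five-number summaries of the subset and of each tier, plus the tier
#' whose median is nearest the subset's median.
#'
#' @param subset_ids Gene ids of the subset (non-empty after intersection).
#' @param tiers Output of [tertile_bins()].
#' @return List: `summaries` (data frame set/n/min/q1/median/q3/max) and
#'   `nearest_tier`.
#' @export
compare_subset_to_tiers <- function(subset_ids, tiers) {
  sub <- tiers[tiers$gene_id %in% subset_ids & !is.na(tiers$tier), ,
               drop = FALSE]
  abort_if(nrow(sub) == 0L, "empty subset after intersection with tiers")
  one <- function(label, v) {
    q <- five_number(v)
    data.frame(set = label, n = length(v), min = q[["min"]], q1 = q[["q1"]],
               median = q[["median"]], q3 = q[["q3"]], max = q[["max"]],
               stringsAsFactors = FALSE)
  }
  rows <- list(one("subset", sub$value))
  for (tr in levels(tiers$tier)) {
    v <- tiers$value[!is.na(tiers$tier) & tiers$tier == tr]
    if (length(v)) rows[[length(rows) + 1L]] <- one(tr, v)
  }
  summaries <- do.call(rbind, rows)
  tier_rows <- summaries[summaries$set != "subset", , drop = FALSE]
  nearest <- tier_rows$set[which.min(abs(tier_rows$median -
                                           summaries$median[1]))]
  list(summaries = summaries, nearest_tier = nearest)
}
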