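# Anchor-centred tag-density matrices, k-means clustering across marks
# with mirrored-cluster merging, averaged profiles with percentile bands,
# TSS / metagene profiles and methylation/CpG-density profiles.
#
# A profile matrix has one row per anchor and one column per bin; bins run
# left to right across [center - flank, center + flank). Minus-strand
# anchors are row-reversed when strand_aware is set, so "right" always
# means "downstream". Tag counts are normalised to reads-per-10-million,
# which makes every profile invariant to sequencing depth.

anchor_centers <- function(anchors) {
  (anchors$start + anchors$end) %/% 2L
}

#' Tag-density matrix around anchors
#'
#' Counts tag 5' positions per bin in `[center - flank, center + flank)`,
#' scaled by `1e7 / total_mapped`. Anchors closer than `flank` to a
#' chromosome edge are dropped (count reported in `n_dropped`).
#'
#' @param track A `tag_track`.
#' @param anchors Interval data frame (peak intervals or 1-bp TSS anchors);
#'   the anchor point is the interval centre.
#' @param flank Half-window (bp) each side of the anchor.
#' @param bin Bin width (bp); must divide `2 * flank`.
#' @param strand_aware Reverse rows of minus-strand anchors.
#' @param chrom_sizes Optional named chromosome lengths for right-edge
#'   clipping.
#' @return A `profile_matrix`: list with `mat` (anchors x bins), `anchors`
#'   (kept rows), `flank`, `bin`, `n_dropped`, `track`.
#' @export
tag_density_matrix <- function(track, anchors, flank = 5000L, bin = 20L,
                               strand_aware = FALSE, chrom_sizes = NULL) {
  abort_if((2L * flank) %% bin != 0L, "bin must divide 2*flank")
  validate_intervals(anchors, "anchor set")
  centers <- anchor_centers(anchors)
  keep <- centers - flank >= 0
  if (!is.null(chrom_sizes)) {
    keep <- keep & (centers + flank <= chrom_sizes[anchors$chrom])
  }
  n_dropped <- sum(!keep)
  anchors <- anchors[keep, , drop = FALSE]
  centers <- centers[keep]
  n_anchor <- nrow(anchors)
  nbins <- as.integer(2L * flank / bin)
  mat <- matrix(0, nrow = n_anchor, ncol = nbins)
  if (n_anchor > 0 && nrow(track$tags) > 0) {
    win <- data.frame(chrom = anchors$chrom, start = centers - flank,
                      end = centers + flank)
    hits <- point_overlap_pairs(track$tags$chrom, track$tags$pos, win)
    if (nrow(hits)) {
      b <- (track$tags$pos[hits$query] - win$start[hits$subject]) %/% bin + 1L
      enc <- (hits$subject - 1L) * nbins + b
      counts <- tabulate(enc, nbins = n_anchor * nbins)
      mat <- matrix(counts, nrow = n_anchor, ncol = nbins, byrow = TRUE)
    }
  }
  mat <- mat * (1e7 / track$total_mapped)
  if (strand_aware && n_anchor > 0 && "strand" %in% names(anchors)) {
    rev_rows <- which(anchors$strand == "-")
    if (length(rev_rows)) {
      mat[rev_rows, ] <- mat[rev_rows, rev(seq_len(nbins)), drop = FALSE]
    }
  }
  structure(list(mat = mat, anchors = anchors, flank = flank, bin = bin,
                 n_dropped = n_dropped, track = track$name,
                 strand_aware = strand_aware),
            class = "profile_matrix")
}

scale_to_p95 <- function(m) {
  q <- quantile7(as.vector(m), 0.95)
  if (is.na(q) || q <= 0) q <- max(m, 1e-12)
  m / q
}

#' k-means clustering of anchors on concatenated multi-mark profiles
#'
#' The per-anchor feature vector concatenates the rows of every
#' participating mark's profile matrix, each mark scaled to unit 95th
#' percentile so deep marks do not dominate the Euclidean metric. Lloyd's
#' k-means with 20 random restarts under the given seed. Display-only marks
#' never enter the feature vector but their per-cluster mean profiles are
#' reported.
#'
#' @param matrices Named list of `profile_matrix` over identical anchors.
#' @param k Number of clusters (`<=` number of anchors).
#' @param seed Integer seed.
#' @param display_only Names of marks excluded from the feature vector.
#' @return A `cluster_assignment`: list with `cluster` (ids 1..k),
#'   `k`, `reversed` (per-anchor orientation flags, all FALSE before
#'   merging), `profiles` (mark -> k x bins mean-profile matrix),
#'   `sizes`, `merge_history`, plus the matrices and metadata needed by
#'   [merge_mirrored()].
#' @export
kmeans_cluster <- function(matrices, k, seed, display_only = character(0)) {
  abort_if(length(matrices) == 0, "no profile matrices supplied")
  n_anchor <- nrow(matrices[[1]]$mat)
  abort_if(!all(vapply(matrices, function(m) nrow(m$mat), 0L) == n_anchor),
           "profile matrices must share anchors")
  abort_if(k > n_anchor, "k exceeds the number of anchors")
  participating <- setdiff(names(matrices), display_only)
  abort_if(length(participating) == 0, "no participating marks left")
  scales <- vapply(matrices[participating], function(m) {
    q <- quantile7(as.vector(m$mat), 0.95)
    if (is.na(q) || q <= 0) max(m$mat, 1e-12) else q
  }, numeric(1))
  feats <- do.call(cbind, lapply(participating, function(mk) {
    matrices[[mk]]$mat / scales[[mk]]
  }))
  set.seed(as.integer(seed %% 2147483647))
  # Lloyd restarts can transiently hit an empty cluster; those starts are
  # discarded by kmeans itself, so the warning carries no information
  km <- withCallingHandlers(
    stats::kmeans(feats, centers = k, nstart = 20L, iter.max = 100L,
                  algorithm = "Lloyd"),
    warning = function(w) {
      if (grepl("empty cluster", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  asg <- structure(list(cluster = km$cluster, k = k,
                        reversed = rep(FALSE, n_anchor),
                        matrices = matrices,
                        scales = scales,
                        participating = participating,
                        display_only = display_only,
                        merge_history = list()),
                   class = "cluster_assignment")
  refresh_cluster_profiles(asg)
}

row_means_oriented <- function(mat, rows, reversed) {
  m <- mat[rows, , drop = FALSE]
  flip <- reversed[rows]
  if (any(flip)) {
    m[flip, ] <- m[flip, rev(seq_len(ncol(m))), drop = FALSE]
  }
  colMeans(m)
}

refresh_cluster_profiles <- function(asg) {
  ids <- sort(unique(asg$cluster))
  asg$profiles <- lapply(asg$matrices, function(pm) {
    do.call(rbind, lapply(ids, function(cid) {
      row_means_oriented(pm$mat, which(asg$cluster == cid), asg$reversed)
    }))
  })
  for (mk in names(asg$profiles)) rownames(asg$profiles[[mk]]) <- ids
  asg$sizes <- stats::setNames(
    as.integer(table(factor(asg$cluster, levels = ids))), ids)
  asg$ids <- ids
  asg
}

# Mirror correlation between two cluster mean profiles, computed on the
# concatenation of the participating marks' profiles in the same
# p95-scaled space the clustering uses. This weights marks by their signal
# variance: a no-signal track (e.g. input) contributes nearly constant
# values and cannot veto a merge the signal marks support, which a plain
# per-mark average of correlations would.
mirror_correlation <- function(asg, a, b) {
  pa <- unlist(lapply(asg$participating, function(mk) {
    asg$profiles[[mk]][as.character(a), ] / asg$scales[[mk]]
  }), use.names = FALSE)
  pb <- unlist(lapply(asg$participating, function(mk) {
    rev(asg$profiles[[mk]][as.character(b), ]) / asg$scales[[mk]]
  }), use.names = FALSE)
  if (stats::sd(pa) == 0 || stats::sd(pb) == 0) return(0)
  stats::cor(pa, pb)
}

#' Merge mirrored k-means clusters
#'
#' Peak-centred matrices ignore transcription direction, so an asymmetric
#' signal produces two clusters whose mean profiles are bin-reversed images
#' of each other. For every cluster pair the correlation between one mean
#' profile and the bin-reversed other, averaged over participating marks,
#' is computed; pairs exceeding `threshold` are merged (members of the
#' absorbed cluster are flagged reversed orientation), iterating to
#' closure on the best pair first.
#'
#' @param asg A `cluster_assignment` from [kmeans_cluster()].
#' @param threshold Mirror-correlation threshold for merging.
#' @return The updated `cluster_assignment`; `merge_history` records each
#'   merge as (from, into, correlation).
#' @export
merge_mirrored <- function(asg, threshold = 0.8) {
  repeat {
    ids <- asg$ids
    if (length(ids) < 2L) break
    best <- NULL
    best_cor <- threshold
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i >= j) next
        mc <- mirror_correlation(asg, ids[i], ids[j])
        if (mc > best_cor) {
          best_cor <- mc
          best <- c(ids[i], ids[j])
        }
      }
    }
    if (is.null(best)) break
    from <- best[2]; into <- best[1]
    members <- asg$cluster == from
    asg$cluster[members] <- into
    asg$reversed[members] <- !asg$reversed[members]
    asg$merge_history[[length(asg$merge_history) + 1L]] <-
      list(from = from, into = into, correlation = best_cor)
    asg <- refresh_cluster_profiles(asg)
  }
  # renumber 1..k' by decreasing size, deterministically
  ord <- order(-asg$sizes, as.integer(names(asg$sizes)))
  remap <- stats::setNames(seq_along(ord), names(asg$sizes)[ord])
  asg$cluster <- unname(remap[as.character(asg$cluster)])
  asg$k <- length(remap)
  refresh_cluster_profiles(asg)
}

#' Average profile of a cluster with percentile bands
#'
#' Column-wise mean, median (50th) and 90th percentile over the member
#' rows of a profile matrix.
#'
#' @param pm A `profile_matrix`.
#' @param members Row indices (or logical mask) of the cluster members;
#'   defaults to all anchors.
#' @return Data frame: bin offset (bp, bin midpoint relative to anchor),
#'   mean, p50, p90.
#' @export
average_profile <- function(pm, members = NULL) {
  m <- pm$mat
  if (!is.null(members)) m <- m[members, , drop = FALSE]
  abort_if(nrow(m) == 0L, "empty member set")
  offset <- -pm$flank + (seq_len(ncol(m)) - 1) * pm$bin + pm$bin / 2
  data.frame(offset = offset,
             mean = colMeans(m),
             p50 = apply(m, 2, function(v) quantile7(v, 0.5)),
             p90 = apply(m, 2, function(v) quantile7(v, 0.9)))
}

tss_anchors <- function(genes) {
  tss <- gene_tss(genes)
  genomic_intervals(genes$chrom, tss, tss + 1L, name = genes$gene_id,
                    strand = genes$strand)
}

tes_anchors <- function(genes) {
  tes <- gene_tes(genes)
  genomic_intervals(genes$chrom, tes, tes + 1L, name = genes$gene_id,
                    strand = genes$strand)
}

#' Strand-aware average tag profile around TSSs
#'
#' @param track A `tag_track`.
#' @param genes Gene table supplying the TSS anchors.
#' @param flank,bin Window half-width and bin width (bp).
#' @param strand_aware Reverse minus-strand rows so positive offsets are
#'   downstream of the TSS.
#' @param chrom_sizes Optional chromosome lengths for edge clipping.
#' @return List: `profile` (offset/mean/p50/p90), `max_offset` (bp of the
#'   profile maximum, bin midpoint), `max_bin`, `n_anchors`.
#' @export
tss_profile <- function(track, genes, flank = 5000L, bin = 100L,
                        strand_aware = TRUE, chrom_sizes = NULL) {
  pm <- tag_density_matrix(track, tss_anchors(genes), flank = flank,
                           bin = bin, strand_aware = strand_aware,
                           chrom_sizes = chrom_sizes)
  prof <- average_profile(pm)
  imax <- which.max(prof$mean)
  list(profile = prof, max_bin = imax, max_offset = prof$offset[imax],
       n_anchors = nrow(pm$anchors), n_dropped = pm$n_dropped)
}

#' Meta-gene profile anchored at TSS and TES
#'
#' Two strand-aware anchored profiles (TSS +/- flank and TES +/- flank)
#' side by side. Genes shorter than `min_gene_length` are excluded (their
#' count is reported); `min_gene_length` must be at least `2 * flank` so
#' the two windows cannot overlap.
#'
#' @param track A `tag_track`.
#' @param genes Gene table.
#' @param anchor_flank Half-window around each anchor (bp).
#' @param min_gene_length Minimum transcript length (bp).
#' @param bin Bin width (bp).
#' @param chrom_sizes Optional chromosome lengths.
#' @return List: `tss`, `tes` (offset/mean data frames), `n_used`,
#'   `n_excluded`.
#' @export
metagene_profile <- function(track, genes, anchor_flank = 2000L,
                             min_gene_length = 4000L, bin = 100L,
                             chrom_sizes = NULL) {
  abort_if(min_gene_length < 2L * anchor_flank,
           "min_gene_length must be >= 2 * anchor_flank")
  len <- genes$end - genes$start
  keep <- len >= min_gene_length
  n_excluded <- sum(!keep)
  genes <- genes[keep, , drop = FALSE]
  abort_if(nrow(genes) == 0L, "no gene passes the length filter")
  prof_at <- function(anchors) {
    pm <- tag_density_matrix(track, anchors, flank = anchor_flank,
                             bin = bin, strand_aware = TRUE,
                             chrom_sizes = chrom_sizes)
    average_profile(pm)[c("offset", "mean")]
  }
  list(tss = prof_at(tss_anchors(genes)),
       tes = prof_at(tes_anchors(genes)),
       n_used = nrow(genes), n_excluded = n_excluded)
}

#' Average methylation and CpG density around anchors
#'
#' Per bin across all anchors: the unweighted mean of CpG methylation
#' fractions and the CpG count per bp. Bins containing no CpG get `NA`
#' methylation and 0 density.
#'
#' @param cpgs A `cpg_table`.
#' @param anchors Interval data frame (anchor = interval centre).
#' @param flank,bin Window half-width and bin width (bp).
#' @param strand_aware Reverse minus-strand anchors.
#' @return Data frame: offset, meth, cpg_density, n_cpg.
#' @export
methylation_cpg_profile <- function(cpgs, anchors, flank = 5000L,
                                    bin = 100L, strand_aware = FALSE) {
  abort_if((2L * flank) %% bin != 0L, "bin must divide 2*flank")
  centers <- anchor_centers(anchors)
  keep <- centers - flank >= 0
  anchors <- anchors[keep, , drop = FALSE]
  centers <- centers[keep]
  nbins <- as.integer(2L * flank / bin)
  n_anchor <- nrow(anchors)
  abort_if(n_anchor == 0L, "no usable anchors")
  win <- data.frame(chrom = anchors$chrom, start = centers - flank,
                    end = centers + flank)
  hits <- point_overlap_pairs(cpgs$chrom, cpgs$pos, win)
  meth_sum <- numeric(nbins)
  n_cpg <- numeric(nbins)
  if (nrow(hits)) {
    b <- (cpgs$pos[hits$query] - win$start[hits$subject]) %/% bin + 1L
    if (strand_aware && "strand" %in% names(anchors)) {
      flip <- anchors$strand[hits$subject] == "-"
      b[flip] <- nbins + 1L - b[flip]
    }
    meth_sum <- as.numeric(tapply(cpgs$meth[hits$query],
                                  factor(b, levels = seq_len(nbins)), sum,
                                  default = 0))
    n_cpg <- as.numeric(table(factor(b, levels = seq_len(nbins))))
  }
  offset <- -flank + (seq_len(nbins) - 1) * bin + bin / 2
  data.frame(offset = offset,
             meth = ifelse(n_cpg > 0, meth_sum / n_cpg, NA_real_),
             cpg_density = n_cpg / (n_anchor * bin),
             n_cpg = n_cpg)
}
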