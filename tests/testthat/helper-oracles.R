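# Independent oracles and shared fixtures. Oracles deliberately use naive
# loop-based computations, not the package's code paths.

# quadratic all-pairs overlap scan (half-open semantics)
oracle_overlaps <- function(intervals, probe) {
  hit <- logical(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    hit[i] <- intervals$chrom[i] == probe$chrom &&
      intervals$start[i] < probe$end &&
      probe$start < intervals$end[i]
  }
  intervals[hit, , drop = FALSE]
}

# per-rule site classifier: each rule checked independently with plain
# coordinate arithmetic
oracle_classify <- function(site, genome, flank = 1000L) {
  genes <- genome$genes
  exons <- gene_exons(genes)
  tss <- gene_tss(genes)
  olap <- function(chrom, s, e) {
    site$chrom == chrom && s < site$end && site$start < e
  }
  in_prom <- FALSE; in_exon <- FALSE; in_span <- FALSE
  for (i in seq_len(nrow(genes))) {
    if (olap(genes$chrom[i], max(0L, tss[i] - flank), tss[i] + flank)) {
      in_prom <- TRUE
    }
    if (olap(genes$chrom[i], genes$start[i], genes$end[i])) in_span <- TRUE
  }
  for (i in seq_len(nrow(exons))) {
    if (olap(exons$chrom[i], exons$start[i], exons$end[i])) in_exon <- TRUE
  }
  in_cgi <- FALSE
  for (i in seq_len(nrow(genome$cgis))) {
    if (olap(genome$cgis$chrom[i], genome$cgis$start[i],
             genome$cgis$end[i])) in_cgi <- TRUE
  }
  feature <- if (in_prom) "promoter" else if (in_exon) "exon" else
    if (in_span) "intron" else "intergenic"
  list(feature = feature, cgi = in_cgi)
}

# exact Mann-Whitney two-sided p by full enumeration of group assignments
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * length(b) / 2
  sets <- utils::combn(n, na)
  us <- apply(sets, 2, function(s) sum(r[s]) - na * (na + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# Spearman rho via midranks and the product-moment formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# small genome used by fuzz tests (fast to annotate)
small_config <- function(seed = 7L, ...) {
  args <- list(seed = seed, n_chroms = 2L, chrom_length = 1.5e6,
               n_genes = 60L, n_peaks = 30L, n_cluster4 = 8L,
               cohort_n_tumor = 20L, cohort_n_normal = 10L)
  args <- utils::modifyList(args, list(...))
  do.call(synthetic_config, args)
}

# the default dataset is shared across test files; built once
default_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) {
      ds <<- suppressMessages(simulate_dataset(synthetic_config()))
    }
    ds
  }
})

# category_counts object with prescribed counts, for fold arithmetic tests
make_counts <- function(counts) {
  tmpl <- annotate_sites(
    genomic_intervals(character(0), integer(0), integer(0)),
    genome_annotation(c(chr1 = 1000L),
                      gene_table(character(0), character(0), integer(0),
                                 integer(0), character(0), character(0),
                                 character(0)),
                      genomic_intervals(character(0), integer(0),
                                        integer(0))))
  tmpl$count <- as.integer(counts[tmpl$category])
  tmpl$count[is.na(tmpl$count)] <- 0L
  attr(tmpl, "total") <- sum(tmpl$count)
  tmpl$percent <- if (attr(tmpl, "total") > 0) {
    100 * tmpl$count / attr(tmpl, "total")
  } else NA_real_
  tmpl
}
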