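# Synthetic data generator.
#
# Emits a toy genome (genes + CpG islands), a base-resolution methylome in
# which CGIs are bimodally methylated, ChIP tag tracks whose enrichment is
# coupled to methylation density, a gene expression table, and a
# tumor/normal cohort with elevated methylation planted at binding sites.
# Every generator seeds its own random stream derived from the single
# config seed, so outputs are reproducible bit-for-bit and adding one
# track never perturbs another.

#' Configuration for the synthetic dataset
#'
#' Defaults describe a desk-scale genome that reproduces the qualitative
#' structures the analysis targets: most binding sites sit on
#' hypermethylated CpG islands, a "cluster 4" subset sits ~1 kb downstream
#' of the TSS of lowly-to-moderately expressed CGI promoters flanked by
#' active marks, and tumor cohort samples carry a methylation gain at the
#' binding sites only.
#'
#' Beta-distribution parameters are length-2 vectors `c(shape1, shape2)`;
#' a length-1 value is treated as a point mass (degenerate distribution).
#'
#' @param seed Master seed; all generator streams derive from it.
#' @param n_chroms,chrom_length Genome shape.
#' @param n_genes Number of genes (2-20 kb, 2-8 exons, non-overlapping).
#' @param cgi_promoter_fraction,cgi_exon_fraction Probability that a gene
#'   carries a promoter CGI / an internal-exon CGI.
#' @param cgi_hyper_fraction Probability that a non-cluster-4 promoter CGI
#'   is hypermethylated.
#' @param meth_background_dist,meth_cgi_unmeth_dist,meth_cgi_hyper_dist
#'   Beta parameters for background, unmethylated-CGI and
#'   hypermethylated-CGI CpGs.
#' @param n_peaks Number of planted binding sites.
#' @param frac_peaks_hypermeth Fraction of peaks planted on hypermethylated
#'   DNA (includes the cluster-4 sites); the remainder are background sites.
#' @param n_cluster4 Number of downstream-of-TSS ("cluster 4") sites.
#' @param cluster4_offset_mean,cluster4_offset_sd TSS-to-site offset (bp).
#' @param tag_background_rate Background tag rate (tags per bp).
#' @param peak_fold Peak enrichment multiple over background.
#' @param mbd2_meth_coupling Expected MBD2 tags per methylated-CpG
#'   equivalent, planting the genome-wide coupling of MBD2 enrichment to
#'   methyl-CpG density (0 disables it, leaving focal peaks only).
#' @param peak_kernel_halfwidth Half-width of the triangular tag kernel at
#'   binding sites (400 bp support by default).
#' @param tss_kernel_halfwidth Half-width of active-mark TSS kernels.
#' @param peak_width_mean,peak_width_sd Planted peak interval width (bp).
#' @param cpg_spacing_background,cpg_spacing_cgi,cpg_spacing_body Mean bp
#'   per CpG outside CGIs, inside CGIs, and in cluster-4 gene bodies.
#' @param coverage_mean Mean Poisson read coverage per CpG.
#' @param rpkm_meanlog,rpkm_sdlog Log-normal expression parameters.
#' @param h3k36_tier_mult Gene-body H3K36me3 enrichment multiplier per
#'   expression tier (low/medium/high), times the background rate.
#' @param cohort_n_tumor,cohort_n_normal Cohort sizes.
#' @param cohort_effect_delta Methylation gain in tumor samples at binding
#'   sites.
#' @param cohort_noise_sd Per-sample-per-site Gaussian noise.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 42L,
                             n_chroms = 2L,
                             chrom_length = 5e6,
                             n_genes = 300L,
                             cgi_promoter_fraction = 0.7,
                             cgi_exon_fraction = 0.2,
                             cgi_hyper_fraction = 0.5,
                             meth_background_dist = c(5, 5),
                             meth_cgi_unmeth_dist = c(1, 20),
                             meth_cgi_hyper_dist = c(20, 2),
                             n_peaks = 150L,
                             frac_peaks_hypermeth = 0.9,
                             n_cluster4 = 40L,
                             cluster4_offset_mean = 1000,
                             cluster4_offset_sd = 150,
                             tag_background_rate = 0.01,
                             peak_fold = 15,
                             mbd2_meth_coupling = 1,
                             peak_kernel_halfwidth = 200,
                             tss_kernel_halfwidth = 500,
                             peak_width_mean = 600,
                             peak_width_sd = 100,
                             cpg_spacing_background = 100,
                             cpg_spacing_cgi = 10,
                             cpg_spacing_body = 30,
                             coverage_mean = 30,
                             rpkm_meanlog = 1,
                             rpkm_sdlog = 1.5,
                             h3k36_tier_mult = c(low = 1, medium = 3,
                                                 high = 8),
                             cohort_n_tumor = 100L,
                             cohort_n_normal = 30L,
                             cohort_effect_delta = 0.05,
                             cohort_noise_sd = 0.02) {
  cfg <- as.list(environment())
  fracs <- c(cfg$cgi_promoter_fraction, cfg$cgi_exon_fraction,
             cfg$cgi_hyper_fraction, cfg$frac_peaks_hypermeth)
  abort_if(any(fracs < 0 | fracs > 1), "fractions must lie in [0, 1]")
  abort_if(cfg$tag_background_rate <= 0 || cfg$peak_fold <= 0,
           "rates must be positive")
  abort_if(cfg$cohort_effect_delta < 0, "cohort_effect_delta must be >= 0")
  abort_if(!is_count(cfg$seed %% 2^31), "seed must be an integer")
  class(cfg) <- "synthetic_config"
  cfg
}

# Beta draw with a point-mass escape hatch (length-1 parameter).
draw_beta <- function(n, par) {
  if (length(par) == 1L) return(rep(as.numeric(par), n))
  stats::rbeta(n, par[1], par[2])
}

#' Generate the toy genome annotation
#'
#' Genes are packed without overlap on alternating strands (2-20 kb, 2-8
#' exons); CGIs of 300-1500 bp are placed over `cgi_promoter_fraction` of
#' promoters (centred on the TSS) and an internal exon of
#' `cgi_exon_fraction` of genes. A subset of `n_cluster4` genes with
#' promoter CGIs is flagged as the downstream-binding class: their promoter
#' CGI stays unmethylated (active promoter) while the gene body downstream
#' of the first 300 bp is flagged as a hypermethylated, CpG-enriched
#' domain. Exon CGIs and a `cgi_hyper_fraction` share of the remaining
#' promoter CGIs are flagged hypermethylated.
#'
#' @param config A [synthetic_config()].
#' @return A `genome_annotation`; its `genes` gain `cluster4`,
#'   `hyper_body_start`, `hyper_body_end` columns and its `cgis` gain
#'   `type`, `hyper`, `gene_id` columns.
#' @export
generate_genome <- function(config) {
  set.seed(derive_seed(config$seed, "genome"))
  L <- as.integer(config$chrom_length)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  chrom_sizes <- stats::setNames(rep(L, config$n_chroms), chroms)
  per_chrom <- diff(round(seq(0, config$n_genes,
                              length.out = config$n_chroms + 1)))
  margin <- 20000L

  rows <- list()
  gid <- 0L
  for (ci in seq_along(chroms)) {
    n <- per_chrom[ci]
    if (n == 0L) next
    len <- round(stats::runif(n, 2000, 20000))
    avail <- L - 2 * margin - sum(len)
    abort_if(avail < 100 * (n + 1),
             "infeasible packing: ", n, " genes do not fit on a ",
             L, " bp chromosome")
    w <- stats::rexp(n + 1)
    gaps <- floor(avail * w / sum(w))
    starts <- margin + cumsum(gaps[seq_len(n)]) +
      cumsum(c(0, len[-n]))
    for (i in seq_len(n)) {
      gid <- gid + 1L
      n_ex <- sample(2:8, 1)
      m <- 2L * n_ex - 1L
      sw <- stats::rexp(m)
      seg <- 50 + floor((len[i] - 50 * m) * sw / sum(sw))
      seg[m] <- len[i] - sum(seg[-m])
      offs <- cumsum(c(0, seg[-m]))
      ex_idx <- seq(1, m, by = 2)
      rows[[gid]] <- data.frame(
        gene_id = sprintf("g%04d", gid),
        chrom = chroms[ci],
        start = as.integer(starts[i]),
        end = as.integer(starts[i] + len[i]),
        strand = if (gid %% 2L == 1L) "+" else "-",
        exon_starts = paste(offs[ex_idx], collapse = ","),
        exon_sizes = paste(seg[ex_idx], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, rows)
  validate_genes(genes)

  tss <- gene_tss(genes)
  has_prom_cgi <- stats::runif(nrow(genes)) < config$cgi_promoter_fraction
  has_exon_cgi <- stats::runif(nrow(genes)) < config$cgi_exon_fraction

  prom_idx <- which(has_prom_cgi)
  abort_if(length(prom_idx) < config$n_cluster4,
           "cannot plant ", config$n_cluster4, " cluster-4 genes: only ",
           length(prom_idx), " genes carry a promoter CGI")
  c4_idx <- if (config$n_cluster4 > 0) {
    sort(sample(prom_idx, config$n_cluster4))
  } else integer(0)
  genes$cluster4 <- seq_len(nrow(genes)) %in% c4_idx

  # hypermethylated gene-body domain of cluster-4 genes (skips the first
  # 300 bp downstream of the TSS, which belongs to the promoter CGI)
  genes$hyper_body_start <- NA_integer_
  genes$hyper_body_end <- NA_integer_
  plus <- genes$strand == "+"
  genes$hyper_body_start[genes$cluster4 & plus] <-
    genes$start[genes$cluster4 & plus] + 300L
  genes$hyper_body_end[genes$cluster4 & plus] <-
    genes$end[genes$cluster4 & plus]
  genes$hyper_body_start[genes$cluster4 & !plus] <-
    genes$start[genes$cluster4 & !plus]
  genes$hyper_body_end[genes$cluster4 & !plus] <-
    genes$end[genes$cluster4 & !plus] - 300L

  cgi_rows <- list()
  k <- 0L
  for (i in prom_idx) {
    k <- k + 1L
    w <- round(stats::runif(1, 300, 1500))
    s <- max(0L, as.integer(tss[i] - w %/% 2))
    cgi_rows[[k]] <- data.frame(
      chrom = genes$chrom[i], start = s, end = as.integer(s + w),
      type = "promoter", gene_id = genes$gene_id[i],
      stringsAsFactors = FALSE)
  }
  for (i in which(has_exon_cgi)) {
    ex <- gene_exons(genes[i, , drop = FALSE])
    if (nrow(ex) < 2L) next
    e <- ex[sample(2:nrow(ex), 1), ]
    k <- k + 1L
    w <- round(stats::runif(1, 300, 1500))
    mid <- (e$start + e$end) %/% 2
    s <- max(0L, as.integer(mid - w %/% 2))
    cgi_rows[[k]] <- data.frame(
      chrom = e$chrom, start = s, end = as.integer(s + w),
      type = "exon", gene_id = genes$gene_id[i],
      stringsAsFactors = FALSE)
  }
  cgis <- if (k > 0) do.call(rbind, cgi_rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               type = character(0), gene_id = character(0))
  if (nrow(cgis)) {
    cgis$end <- pmin(cgis$end, chrom_sizes[cgis$chrom])
    cgis$name <- sprintf("cgi%04d", seq_len(nrow(cgis)))
    cgis$score <- NA_real_
    cgis$strand <- "*"
    is_c4_prom <- cgis$type == "promoter" &
      cgis$gene_id %in% genes$gene_id[genes$cluster4]
    cgis$hyper <- ifelse(
      cgis$type == "exon", TRUE,
      ifelse(is_c4_prom, FALSE,
             stats::runif(nrow(cgis)) < config$cgi_hyper_fraction))
  } else {
    cgis$name <- character(0); cgis$score <- numeric(0)
    cgis$strand <- character(0); cgis$hyper <- logical(0)
  }
  genome_annotation(chrom_sizes, genes, cgis)
}

#' Generate the base-resolution methylome
#'
#' CpG sites are placed at elevated density inside CGIs (~1 per
#' `cpg_spacing_cgi` bp), at intermediate density in cluster-4 gene-body
#' domains, and at background density elsewhere. Methylation fractions are
#' drawn per CpG from the hypermethylated-CGI distribution inside
#' hypermethylated CGIs and cluster-4 body domains, from the
#' unmethylated-CGI distribution inside other CGIs, and from the background
#' distribution elsewhere. Coverage is Poisson(`coverage_mean`).
#'
#' @param genome A `genome_annotation` from [generate_genome()].
#' @param config The same [synthetic_config()].
#' @return A `cpg_table`.
#' @export
generate_methylome <- function(genome, config) {
  set.seed(derive_seed(config$seed, "methylome"))
  genes <- genome$genes
  cgis <- genome$cgis
  chrom <- character(0); pos <- integer(0)
  for (ch in names(genome$chrom_sizes)) {
    Lc <- genome$chrom_sizes[[ch]]
    n_bg <- stats::rpois(1, Lc / config$cpg_spacing_background)
    p <- sample.int(Lc, min(n_bg, Lc)) - 1L
    chrom <- c(chrom, rep(ch, length(p))); pos <- c(pos, p)
  }
  place_in <- function(iv, spacing) {
    for (i in seq_len(nrow(iv))) {
      w <- iv$end[i] - iv$start[i]
      n <- max(1L, stats::rpois(1, w / spacing))
      p <- iv$start[i] + sample.int(w, min(n, w)) - 1L
      chrom <<- c(chrom, rep(iv$chrom[i], length(p)))
      pos <<- c(pos, p)
    }
  }
  if (nrow(cgis)) place_in(cgis, config$cpg_spacing_cgi)
  bodies <- genes[genes$cluster4, , drop = FALSE]
  if (nrow(bodies)) {
    place_in(data.frame(chrom = bodies$chrom,
                        start = bodies$hyper_body_start,
                        end = bodies$hyper_body_end),
             config$cpg_spacing_body)
  }
  keep <- !duplicated(paste(chrom, pos))
  chrom <- chrom[keep]; pos <- pos[keep]
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  n <- length(pos)

  pts <- data.frame(chrom = chrom, start = pos, end = pos + 1L)
  in_hyper_cgi <- if (nrow(cgis)) {
    overlaps_any(pts, cgis[cgis$hyper, , drop = FALSE])
  } else rep(FALSE, n)
  in_unmeth_cgi <- if (nrow(cgis)) {
    overlaps_any(pts, cgis[!cgis$hyper, , drop = FALSE])
  } else rep(FALSE, n)
  in_body <- if (nrow(bodies)) {
    overlaps_any(pts, data.frame(chrom = bodies$chrom,
                                 start = bodies$hyper_body_start,
                                 end = bodies$hyper_body_end))
  } else rep(FALSE, n)

  meth <- draw_beta(n, config$meth_background_dist)
  cls_hyper <- in_hyper_cgi | (in_body & !in_unmeth_cgi)
  cls_unmeth <- in_unmeth_cgi & !in_hyper_cgi
  meth[cls_hyper] <- draw_beta(sum(cls_hyper), config$meth_cgi_hyper_dist)
  meth[cls_unmeth] <- draw_beta(sum(cls_unmeth), config$meth_cgi_unmeth_dist)
  coverage <- stats::rpois(n, config$coverage_mean)
  cpg_table(chrom, pos, pmin(pmax(meth, 0), 1), coverage)
}

#' Generate the per-gene expression table
#'
#' RPKM values are log-normal; cluster-4 genes are resampled uniformly
#' between the 20th and 60th percentile of the initial global distribution
#' (low-to-medium expression).
#'
#' @param genome A `genome_annotation`.
#' @param config The [synthetic_config()].
#' @return Data frame gene_id / rpkm, with attribute `cluster4_bounds`
#'   holding the (P20, P60) interval used for the cluster-4 resampling.
#' @export
generate_expression <- function(genome, config) {
  set.seed(derive_seed(config$seed, "expression"))
  genes <- genome$genes
  rpkm <- stats::rlnorm(nrow(genes), config$rpkm_meanlog, config$rpkm_sdlog)
  bounds <- quantile7(rpkm, c(0.2, 0.6))
  c4 <- which(genes$cluster4)
  if (length(c4)) {
    rpkm[c4] <- stats::runif(length(c4), bounds[1], bounds[2])
  }
  out <- data.frame(gene_id = genes$gene_id, rpkm = rpkm,
                    stringsAsFactors = FALSE)
  attr(out, "cluster4_bounds") <- bounds
  out
}

# n tag positions under a triangular kernel of the given half-width,
# centred at `center` (sum of two uniforms).
rtriangle <- function(n, center, halfwidth) {
  round(center + halfwidth * (stats::runif(n) + stats::runif(n) - 1))
}

poisson_background <- function(chrom_sizes, rate) {
  chrom <- character(0); pos <- integer(0)
  for (ch in names(chrom_sizes)) {
    Lc <- chrom_sizes[[ch]]
    n <- stats::rpois(1, rate * Lc)
    p <- sample.int(Lc, min(n, Lc)) - 1L
    chrom <- c(chrom, rep(ch, length(p))); pos <- c(pos, p)
  }
  list(chrom = chrom, pos = pos)
}

kernel_tags <- function(centers_chrom, centers_pos, expected_per_kernel,
                        halfwidth, chrom_sizes) {
  chrom <- character(0); pos <- integer(0)
  for (i in seq_along(centers_pos)) {
    n <- stats::rpois(1, expected_per_kernel)
    if (n == 0) next
    p <- rtriangle(n, centers_pos[i], halfwidth)
    p <- pmin(pmax(p, 0L), chrom_sizes[[centers_chrom[i]]] - 1L)
    chrom <- c(chrom, rep(centers_chrom[i], n)); pos <- c(pos, as.integer(p))
  }
  list(chrom = chrom, pos = pos)
}

finish_track <- function(name, parts) {
  chrom <- unlist(lapply(parts, `[[`, "chrom"), use.names = FALSE)
  pos <- unlist(lapply(parts, `[[`, "pos"), use.names = FALSE)
  n <- length(pos)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tag_track(name, chrom, pos, strand)
}

#' Generate ChIP tag tracks and the planted-site truth
#'
#' Produces tracks MBD2, input, Pol2, H3K4me3, H2A.Zac, H3K27ac, H3K36me3
#' and P300. Input is homogeneous Poisson background. MBD2 adds, at each
#' planted site, Poisson(`tag_background_rate * peak_fold *
#' peak_kernel_halfwidth`) extra tags under a triangular kernel.
#' Planted site classes: `hyper_cgi_promoter` (centred on hypermethylated
#' promoter CGIs), `cgi_exon` (hypermethylated exon CGIs), `cluster4`
#' (strand-aware TSS + Normal(offset) of cluster-4 genes) and `background`
#' (random positions off CGIs and off cluster-4 bodies). Active-mark tracks
#' get TSS-centred kernels at cluster-4 genes only; H3K36me3 gets uniform
#' gene-body tags scaled by expression tier.
#'
#' @param genome A `genome_annotation`.
#' @param methylome The matching `cpg_table` (kept for interface symmetry;
#'   planting uses the hypermethylation flags recorded in the genome).
#' @param config The [synthetic_config()].
#' @param expression Optional table from [generate_expression()];
#'   regenerated deterministically from the config when missing.
#' @return List with `tracks` (named list of `tag_track`) and `truth`
#'   (list: `peaks` interval data frame with a `class` column,
#'   `cluster4_genes` with true offsets, `expression` with tier labels).
#' @export
generate_chip_tags <- function(genome, methylome, config,
                               expression = NULL) {
  if (is.null(expression)) expression <- generate_expression(genome, config)
  set.seed(derive_seed(config$seed, "chip"))
  genes <- genome$genes
  cgis <- genome$cgis
  sizes <- genome$chrom_sizes

  n_hyper <- round(config$frac_peaks_hypermeth * config$n_peaks)
  n_c4 <- min(config$n_cluster4, sum(genes$cluster4))
  abort_if(n_c4 > n_hyper,
           "n_cluster4 exceeds the hypermethylated peak budget")
  n_anchor <- n_hyper - n_c4
  hp <- which(cgis$type == "promoter" & cgis$hyper)
  he <- which(cgis$type == "exon" & cgis$hyper)
  abort_if(n_anchor > 0 && length(hp) + length(he) == 0,
           "no hypermethylated CGIs available to anchor peaks")
  n_hp <- if (n_anchor > 0) {
    round(n_anchor * length(hp) / (length(hp) + length(he)))
  } else 0L
  n_he <- n_anchor - n_hp
  abort_if(n_hp > length(hp) || n_he > length(he),
           "not enough hypermethylated CGIs to anchor ", n_anchor, " peaks")
  n_bg <- config$n_peaks - n_hyper

  centers <- data.frame(chrom = character(0), center = integer(0),
                        class = character(0), stringsAsFactors = FALSE)
  add_centers <- function(chrom, center, class) {
    rbind(centers, data.frame(chrom = chrom, center = as.integer(center),
                              class = class, stringsAsFactors = FALSE))
  }
  if (n_hp > 0) {
    pick <- sample(hp, n_hp)
    centers <- add_centers(cgis$chrom[pick],
                           (cgis$start[pick] + cgis$end[pick]) %/% 2 +
                             round(stats::rnorm(n_hp, 0, 25)),
                           "hyper_cgi_promoter")
  }
  if (n_he > 0) {
    pick <- sample(he, n_he)
    centers <- add_centers(cgis$chrom[pick],
                           (cgis$start[pick] + cgis$end[pick]) %/% 2 +
                             round(stats::rnorm(n_he, 0, 25)),
                           "cgi_exon")
  }
  c4_genes <- genes[genes$cluster4, , drop = FALSE]
  c4_offsets <- numeric(0)
  if (n_c4 > 0) {
    c4_offsets <- round(stats::rnorm(n_c4, config$cluster4_offset_mean,
                                     config$cluster4_offset_sd))
    tss <- gene_tss(c4_genes)
    ctr <- ifelse(c4_genes$strand == "+", tss + c4_offsets,
                  tss - c4_offsets)
    centers <- add_centers(c4_genes$chrom, ctr, "cluster4")
  }
  if (n_bg > 0) {
    avoid <- rbind(
      cgis[c("chrom", "start", "end")],
      data.frame(chrom = c4_genes$chrom, start = c4_genes$hyper_body_start,
                 end = c4_genes$hyper_body_end))
    got <- 0L; tries <- 0L
    bg_chrom <- character(0); bg_pos <- integer(0)
    while (got < n_bg && tries < 1000L) {
      tries <- tries + 1L
      m <- 4L * (n_bg - got)
      ch <- sample(names(sizes), m, replace = TRUE,
                   prob = sizes / sum(sizes))
      p <- floor(stats::runif(m, 1000, sizes[ch] - 1000))
      ok <- !overlaps_any(data.frame(chrom = ch, start = p - 500,
                                     end = p + 500), avoid)
      take <- which(ok)[seq_len(min(sum(ok), n_bg - got))]
      bg_chrom <- c(bg_chrom, ch[take]); bg_pos <- c(bg_pos, p[take])
      got <- got + length(take)
    }
    abort_if(got < n_bg, "could not place background peaks off CGIs")
    centers <- add_centers(bg_chrom, bg_pos, "background")
  }

  w <- pmin(pmax(round(stats::rnorm(nrow(centers), config$peak_width_mean,
                                    config$peak_width_sd)), 300), 1000)
  peaks <- genomic_intervals(
    chrom = centers$chrom,
    start = pmax(0L, centers$center - w %/% 2L),
    end = centers$center - w %/% 2L + w,
    name = sprintf("peak%04d", seq_len(nrow(centers))),
    score = config$peak_fold)
  peaks$class <- centers$class

  bg_rate <- config$tag_background_rate
  peak_area <- bg_rate * config$peak_fold * config$peak_kernel_halfwidth
  tss_area <- bg_rate * config$peak_fold * config$tss_kernel_halfwidth
  c4_tss <- gene_tss(c4_genes)

  # genome-wide methylation-coupled MBD2 component: expected
  # mbd2_meth_coupling tags per methylated-CpG equivalent, jittered
  # +/- 50 bp around the CpG
  coupled <- list(chrom = character(0), pos = integer(0))
  if (config$mbd2_meth_coupling > 0 && nrow(methylome) > 0) {
    nc <- stats::rpois(nrow(methylome),
                       config$mbd2_meth_coupling * methylome$meth)
    idx <- rep.int(seq_len(nrow(methylome)), nc)
    if (length(idx)) {
      p <- methylome$pos[idx] + round(stats::runif(length(idx), -50, 50))
      p <- pmin(pmax(p, 0L), sizes[methylome$chrom[idx]] - 1L)
      coupled <- list(chrom = methylome$chrom[idx], pos = as.integer(p))
    }
  }

  tracks <- list()
  tracks$MBD2 <- finish_track("MBD2", list(
    poisson_background(sizes, bg_rate),
    kernel_tags(centers$chrom, centers$center, peak_area,
                config$peak_kernel_halfwidth, sizes),
    coupled))
  tracks$input <- finish_track("input", list(poisson_background(sizes,
                                                                bg_rate)))
  for (mark in c("Pol2", "H3K4me3", "H2A.Zac", "H3K27ac", "P300")) {
    tracks[[mark]] <- finish_track(mark, list(
      poisson_background(sizes, bg_rate),
      kernel_tags(c4_genes$chrom, c4_tss, tss_area,
                  config$tss_kernel_halfwidth, sizes)))
  }
  tiers <- tertile_bins(expression$gene_id, expression$rpkm)
  mult <- config$h3k36_tier_mult[as.character(tiers$tier)]
  mult[is.na(mult)] <- 0
  body_chrom <- character(0); body_pos <- integer(0)
  for (i in seq_len(nrow(genes))) {
    lam <- bg_rate * mult[i] * (genes$end[i] - genes$start[i])
    nb <- stats::rpois(1, lam)
    if (nb == 0) next
    body_chrom <- c(body_chrom, rep(genes$chrom[i], nb))
    body_pos <- c(body_pos,
                  genes$start[i] + sample.int(genes$end[i] - genes$start[i],
                                              nb, replace = TRUE) - 1L)
  }
  tracks$H3K36me3 <- finish_track("H3K36me3", list(
    poisson_background(sizes, bg_rate),
    list(chrom = body_chrom, pos = body_pos)))

  truth <- list(
    peaks = peaks,
    cluster4_genes = data.frame(gene_id = c4_genes$gene_id,
                                tss = c4_tss, strand = c4_genes$strand,
                                offset = c4_offsets,
                                stringsAsFactors = FALSE),
    expression = tiers)
  list(tracks = tracks, truth = truth)
}

#' Generate the tumor/normal cohort methylation matrices
#'
#' For each site the base value is the coverage-weighted interval
#' methylation from the methylome; normal samples add Gaussian noise,
#' tumor samples add `cohort_effect_delta` plus noise, and values are
#' clipped to `[0, 1]`. A second matrix over random (length-matched) sites
#' carries no tumor effect at any site. Sites with no covered CpG are
#' dropped (count attached as attribute `n_dropped`).
#'
#' @param sites Binding-site intervals.
#' @param methylome A `cpg_table`.
#' @param config The [synthetic_config()].
#' @param genome Optional `genome_annotation`; needed to draw the random
#'   comparison sites when `random_sites` is not supplied.
#' @param random_sites Optional pre-drawn random interval set.
#' @return List with `sites` (a `cohort_matrix`), `random` (a
#'   `cohort_matrix` or `NULL`) and `truth` (base site methylation values).
#' @export
generate_cohort <- function(sites, methylome, config, genome = NULL,
                            random_sites = NULL) {
  set.seed(derive_seed(config$seed, "cohort"))
  if (is.null(random_sites) && !is.null(genome)) {
    random_sites <- sample_random_lengthmatched(
      sites, genome, seed = derive_seed(config$seed, "cohort-random"))
    set.seed(derive_seed(config$seed, "cohort"))
  }
  samples <- c(sprintf("tumor%03d", seq_len(config$cohort_n_tumor)),
               sprintf("normal%03d", seq_len(config$cohort_n_normal)))
  groups <- rep(c("tumor", "normal"),
                c(config$cohort_n_tumor, config$cohort_n_normal))

  build <- function(iv, delta) {
    b <- interval_methylation_many(iv, methylome, min_coverage = 1L)
    keep <- !is.na(b)
    n_dropped <- sum(!keep)
    if (n_dropped > 0) {
      message("generate_cohort: dropped ", n_dropped,
              " sites with no covered CpG")
    }
    abort_if(!any(keep), "no site has CpG coverage")
    iv <- iv[keep, , drop = FALSE]
    b <- b[keep]
    shift <- ifelse(groups == "tumor", delta, 0)
    vals <- outer(shift, b, `+`) +
      matrix(stats::rnorm(length(samples) * length(b), 0,
                          config$cohort_noise_sd),
             nrow = length(samples))
    vals <- pmin(pmax(vals, 0), 1)
    m <- cohort_matrix(values = vals, samples = samples, groups = groups,
                       sites = iv)
    attr(m, "n_dropped") <- n_dropped
    attr(m, "base_meth") <- b
    m
  }
  m_sites <- build(sites, config$cohort_effect_delta)
  m_random <- if (!is.null(random_sites)) build(random_sites, 0) else NULL
  list(sites = m_sites, random = m_random,
       truth = list(base = attr(m_sites, "base_meth"),
                    delta = config$cohort_effect_delta))
}

#' Generate the full synthetic dataset
#'
#' Runs every generator in order and returns all pieces plus the planted
#' truth, fully determined by `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List: `config`, `genome`, `methylome`, `expression`, `tracks`,
#'   `truth`, `cohort`.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  genome <- generate_genome(config)
  methylome <- generate_methylome(genome, config)
  expression <- generate_expression(genome, config)
  chip <- generate_chip_tags(genome, methylome, config, expression)
  cohort <- generate_cohort(chip$truth$peaks, methylome, config,
                            genome = genome)
  list(config = config, genome = genome, methylome = methylome,
       expression = expression, tracks = chip$tracks,
       truth = chip$truth, cohort = cohort)
}
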