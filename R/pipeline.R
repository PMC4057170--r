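# End-to-end orchestration: simulate (or ingest) -> annotate -> methylation
# -> cluster -> stratify -> cohort, with every figure-level numeric output
# written to stable filenames and checksummed in a manifest.

default_pipeline_config <- function() {
  list(
    simulate = synthetic_config(),
    inputs = NULL,  # alternatively: list(peaks=, genes=, cgis=, methcounts=,
                    # tags = named BED6 paths, expression=, cohort=)
    annotation = list(promoter_flank = 1000L, random = "matched"),
    methylation = list(window = 1000L, min_coverage = 1L, n_points = 100L),
    clustering = list(k = 5L, merge_threshold = 0.8, flank = 5000L,
                      bin = 20L),
    profiles = list(flank = 5000L, bin = 100L),
    metagene = list(anchor_flank = 2000L, min_gene_length = 4000L),
    outdir = "results/pipeline"
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !inherits(override[[nm]], "synthetic_config")) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

load_pipeline_inputs <- function(paths) {
  genes <- read_gene_table(paths$genes)
  cgis <- read_bed(paths$cgis)
  cgis$hyper <- NA
  sizes <- paths$chrom_sizes
  abort_if(is.null(sizes), "inputs require named chrom_sizes")
  tracks <- lapply(names(paths$tags), function(nm) {
    read_tags(paths$tags[[nm]], name = nm)
  })
  names(tracks) <- names(paths$tags)
  peaks <- read_bed(paths$peaks)
  expr <- utils::read.delim(paths$expression, stringsAsFactors = FALSE)
  list(genome = genome_annotation(sizes, genes, cgis),
       methylome = read_methcounts(paths$methcounts),
       tracks = tracks, peaks = peaks, expression = expr,
       cohort = list(sites = read_cohort_matrix(paths$cohort),
                     random = if (!is.null(paths$cohort_random)) {
                       read_cohort_matrix(paths$cohort_random)
                     }),
       truth = NULL)
}

#' Run the full analysis pipeline
#'
#' Validates the configuration, obtains the dataset (simulated from the
#' `simulate` block, or read from the `inputs` paths), and runs every
#' analysis stage, writing one file per figure-level output plus a
#' `manifest.tsv` of MD5 checksums. A re-run with the same configuration
#' and seed reproduces identical checksums.
#'
#' @param config A configuration list (see `default_pipeline_config` in the
#'   sources) or the path to a YAML file with the same structure. Exactly
#'   one of `simulate` / `inputs` must be present.
#' @param outdir Output directory (overrides `config$outdir`).
#' @return Invisibly, a list with the manifest data frame, per-stage
#'   counters, and headline numbers (fold table, rho, cluster sizes, cohort
#'   tests).
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  if (is.character(config)) {
    abort_if(!requireNamespace("yaml", quietly = TRUE),
             "reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
    if (!is.null(config$simulate)) {
      config$simulate <- do.call(synthetic_config, config$simulate)
    }
  }
  cfg <- merge_config(default_pipeline_config(), config)
  has_sim <- !is.null(cfg$simulate) && is.null(config$inputs)
  abort_if(!has_sim && is.null(cfg$inputs),
           "config must carry a simulate block or an inputs block")
  outdir <- outdir %||% cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  counters <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ds <- stage("data", {
    if (has_sim) simulate_dataset(cfg$simulate) else
      load_pipeline_inputs(cfg$inputs)
  })
  genome <- ds$genome
  peaks <- if (has_sim) ds$truth$peaks else ds$peaks
  seed <- if (has_sim) cfg$simulate$seed else (cfg$seed %||% 1L)
  files <- character(0)
  put <- function(x, name) {
    p <- file.path(outdir, name)
    write_tsv(x, p)
    files <<- c(files, p)
  }

  # -- annotation: hierarchical categories and fold over matched random
  ann <- stage("annotation", {
    obs <- annotate_sites(peaks, genome, cfg$annotation$promoter_flank)
    rnd <- if (identical(cfg$annotation$random, "matched")) {
      sample_random_distributionmatched(peaks, genome,
                                        seed = derive_seed(seed, "random"))
    } else {
      sample_random_lengthmatched(peaks, genome,
                                  seed = derive_seed(seed, "random"))
    }
    rnd_counts <- annotate_sites(rnd, genome, cfg$annotation$promoter_flank)
    folds <- fold_over_random(obs, rnd_counts)
    put(cbind(obs, total = attr(obs, "total")), "annotation_counts.tsv")
    put(folds, "annotation_folds.tsv")
    list(obs = obs, random = rnd, folds = folds)
  })

  # -- methylation at sites, density/enrichment tracks, ranked correlation
  met <- stage("methylation", {
    dist_obs <- methylation_site_distribution(peaks, ds$methylome,
                                              cfg$methylation$min_coverage)
    dist_rnd <- methylation_site_distribution(ann$random, ds$methylome,
                                              cfg$methylation$min_coverage)
    put(data.frame(set = c("sites", "random"),
                   rbind(t(dist_obs$summary), t(dist_rnd$summary)),
                   n_undefined = c(dist_obs$n_undefined,
                                   dist_rnd$n_undefined)),
        "site_methylation_summary.tsv")
    put(data.frame(level = dist_obs$levels), "site_methylation_levels.tsv")
    dens <- mcpg_density_track(ds$methylome, genome$chrom_sizes,
                               cfg$methylation$window)
    enr <- enrichment_track(ds$tracks$MBD2, ds$tracks$input,
                            genome$chrom_sizes, cfg$methylation$window)
    write_bedgraph(dens, file.path(outdir, "mcpg_density.bedgraph"),
                   "mCpG_density")
    write_bedgraph(enr, file.path(outdir, "mbd2_enrichment.bedgraph"),
                   "MBD2_enrichment")
    files <<- c(files, file.path(outdir, "mcpg_density.bedgraph"),
                file.path(outdir, "mbd2_enrichment.bedgraph"))
    rk <- ranked_density_enrichment(dens, enr, cfg$methylation$n_points)
    put(rk$curve, "ranked_density_enrichment.tsv")
    put(data.frame(statistic = "spearman_rho", value = rk$rho,
                   n_windows = rk$n_windows), "rank_correlation.tsv")
    list(dist = dist_obs, rho = rk$rho)
  })

  # -- multi-mark clustering at peak centres with mirror merging
  clu <- stage("clustering", {
    mats <- lapply(ds$tracks, tag_density_matrix, anchors = peaks,
                   flank = cfg$clustering$flank, bin = cfg$clustering$bin,
                   strand_aware = FALSE, chrom_sizes = genome$chrom_sizes)
    asg <- kmeans_cluster(mats, k = cfg$clustering$k,
                          seed = derive_seed(seed, "kmeans"))
    asg <- merge_mirrored(asg, cfg$clustering$merge_threshold)
    kept <- mats[[1]]$anchors
    out_bed <- kept
    out_bed$name <- sprintf("cluster%d", asg$cluster)
    write_bed(out_bed, file.path(outdir, "cluster_assignment.bed"))
    files <<- c(files, file.path(outdir, "cluster_assignment.bed"))
    prof_rows <- list()
    for (mk in names(asg$profiles)) {
      pr <- asg$profiles[[mk]]
      for (cid in rownames(pr)) {
        prof_rows[[length(prof_rows) + 1L]] <- data.frame(
          mark = mk, cluster = cid, bin = seq_len(ncol(pr)),
          mean = pr[cid, ], stringsAsFactors = FALSE)
      }
    }
    put(do.call(rbind, prof_rows), "cluster_profile_means.tsv")
    mc <- methylation_cpg_profile(ds$methylome, kept,
                                  flank = cfg$profiles$flank,
                                  bin = cfg$profiles$bin)
    put(mc, "peak_methylation_cpg_profile.tsv")
    list(assignment = asg, anchors = kept)
  })

  # -- TSS profile and metagene over cluster-4 genes, tier tables
  strat <- stage("stratification", {
    c4_ids <- if (has_sim) ds$truth$cluster4_genes$gene_id else
      unique(clu$anchors$name[clu$assignment$cluster == clu$assignment$k])
    c4_genes <- genome$genes[genome$genes$gene_id %in% c4_ids, ,
                             drop = FALSE]
    tp <- tss_profile(ds$tracks$MBD2, c4_genes,
                      flank = cfg$profiles$flank, bin = cfg$profiles$bin,
                      chrom_sizes = genome$chrom_sizes)
    put(tp$profile, "tss_profile_mbd2_cluster4.tsv")
    mg <- metagene_profile(ds$tracks$H3K36me3, c4_genes,
                           anchor_flank = cfg$metagene$anchor_flank,
                           min_gene_length = cfg$metagene$min_gene_length,
                           chrom_sizes = genome$chrom_sizes)
    put(cbind(anchor = "TSS", mg$tss), "metagene_h3k36me3_tss.tsv")
    put(cbind(anchor = "TES", mg$tes), "metagene_h3k36me3_tes.tsv")

    expr <- ds$expression
    tiers_expr <- tertile_bins(expr$gene_id, expr$rpkm)
    put(tiers_expr, "expression_tiers.tsv")
    h36 <- genebody_density(ds$tracks$H3K36me3, genome$genes)
    tiers_h36 <- tertile_bins(genome$genes$gene_id, h36,
                              eligible = rep(TRUE, nrow(genome$genes)))
    put(tiers_h36, "h3k36me3_density_tiers.tsv")
    mcd <- genebody_density(ds$methylome, genome$genes)
    tiers_mcd <- tertile_bins(genome$genes$gene_id, mcd,
                              eligible = rep(TRUE, nrow(genome$genes)))
    put(tiers_mcd, "mcpg_density_tiers.tsv")
    cmp_expr <- compare_subset_to_tiers(c4_ids, tiers_expr)
    cmp_h36 <- compare_subset_to_tiers(c4_ids, tiers_h36)
    cmp_mcd <- compare_subset_to_tiers(c4_ids, tiers_mcd)
    put(rbind(cbind(table = "rpkm", cmp_expr$summaries),
              cbind(table = "h3k36me3", cmp_h36$summaries),
              cbind(table = "mcpg", cmp_mcd$summaries)),
        "cluster4_vs_tiers.tsv")
    list(tss_max_offset = tp$max_offset,
         nearest = c(rpkm = cmp_expr$nearest_tier,
                     h3k36me3 = cmp_h36$nearest_tier,
                     mcpg = cmp_mcd$nearest_tier),
         c4_ids = c4_ids)
  })

  # -- tumor/normal cohort comparison at all sites, cluster 4, random
  coh <- stage("cohort", {
    cm <- if (has_sim) ds$cohort else ds$cohort
    c4_sites <- peaks[peaks$name %in% clu$anchors$name &
                        (if (has_sim) peaks$class == "cluster4" else TRUE), ,
                      drop = FALSE]
    res <- cohort_comparison(cm$sites,
                             site_sets = list(cluster4 = c4_sites),
                             random_matrix = cm$random)
    put(res$samples, "cohort_sample_means.tsv")
    put(res$summary, "cohort_summary.tsv")
    put(res$tests, "cohort_tests.tsv")
    res
  })

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  invisible(list(manifest = manifest,
                 folds = ann$folds,
                 rho = met$rho,
                 cluster_sizes = clu$assignment$sizes,
                 tss_max_offset = strat$tss_max_offset,
                 nearest_tiers = strat$nearest,
                 cohort_tests = coh$tests))
}
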