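# Hierarchical annotation of binding sites and the matched random null.
#
# Sites are assigned to exactly one of four functional features -
# promoter (TSS +/- 1 kb), exon, intron, intergenic - in that hierarchical
# order, and independently flagged CGI / non-CGI by >= 1 bp overlap with a
# CpG island, giving 8 categories in total.

FEATURE_ORDER <- c("promoter", "exon", "intron", "intergenic")

promoter_windows <- function(genes, flank = 1000L) {
  if (nrow(genes) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  tss <- gene_tss(genes)
  data.frame(chrom = genes$chrom,
             start = pmax(0L, tss - as.integer(flank)),
             end = tss + as.integer(flank),
             stringsAsFactors = FALSE)
}

#' Classify binding sites against the gene/CGI annotation
#'
#' @param sites Interval data frame.
#' @param genome A `genome_annotation`.
#' @param promoter_flank Promoter window half-width around the TSS (bp).
#' @return Data frame with columns `feature` (promoter/exon/intron/
#'   intergenic), `cgi` (logical) and `category`
#'   (`"<feature>_CGI"` / `"<feature>_nonCGI"`), one row per site.
#' @export
classify_sites <- function(sites, genome, promoter_flank = 1000L) {
  validate_intervals(sites, "site set")
  genes <- genome$genes
  in_prom <- overlaps_any(sites, promoter_windows(genes, promoter_flank))
  in_exon <- overlaps_any(sites, gene_exons(genes))
  in_span <- overlaps_any(sites, genes)
  feature <- rep("intergenic", nrow(sites))
  feature[in_span] <- "intron"
  feature[in_exon] <- "exon"
  feature[in_prom] <- "promoter"
  cgi <- overlaps_any(sites, genome$cgis)
  data.frame(feature = feature, cgi = cgi,
             category = paste0(feature, ifelse(cgi, "_CGI", "_nonCGI")),
             stringsAsFactors = FALSE)
}

#' Classify a single site
#' @param site One-row interval data frame.
#' @inheritParams classify_sites
#' @return A list with `feature` and `cgi`.
#' @export
classify_site <- function(site, genome, promoter_flank = 1000L) {
  abort_if(nrow(site) != 1L, "classify_site expects a single interval")
  cl <- classify_sites(site, genome, promoter_flank)
  list(feature = cl$feature, cgi = cl$cgi, category = cl$category)
}

all_categories <- function() {
  as.vector(t(outer(FEATURE_ORDER, c("_CGI", "_nonCGI"), paste0)))
}

#' Count sites per annotation category
#'
#' Every site is counted exactly once; all 8 categories are reported, with
#' zero counts where empty.
#'
#' @inheritParams classify_sites
#' @return A `category_counts` data frame: feature, cgi, category, count,
#'   percent; total count in attribute `total`.
#' @export
annotate_sites <- function(sites, genome, promoter_flank = 1000L) {
  cats <- all_categories()
  if (nrow(sites) == 0L) {
    counts <- stats::setNames(rep(0L, length(cats)), cats)
  } else {
    cl <- classify_sites(sites, genome, promoter_flank)
    counts <- table(factor(cl$category, levels = cats))
    counts <- stats::setNames(as.integer(counts), cats)
  }
  total <- sum(counts)
  out <- data.frame(
    category = cats,
    feature = rep(FEATURE_ORDER, each = 2),
    cgi = rep(c(TRUE, FALSE), times = length(FEATURE_ORDER)),
    count = unname(counts),
    percent = if (total > 0) 100 * unname(counts) / total else
      rep(NA_real_, length(cats)),
    stringsAsFactors = FALSE)
  attr(out, "total") <- total
  class(out) <- c("category_counts", "data.frame")
  out
}

#' Draw a random region set matched for site-length distribution
#'
#' Produces exactly as many intervals as there are sites. Each length is
#' drawn with replacement from the empirical site-length distribution, the
#' chromosome is drawn weighted by its length, and the start is uniform so
#' the interval fits without clipping.
#'
#' @param sites Observed site intervals (>= 1 row).
#' @param genome A `genome_annotation` (chromosome sizes are used).
#' @param seed Integer seed; the same seed reproduces the same set.
#' @param n Number of intervals (defaults to `nrow(sites)`).
#' @return Interval data frame of random regions.
#' @export
sample_random_lengthmatched <- function(sites, genome, seed,
                                        n = nrow(sites)) {
  abort_if(nrow(sites) < 1L, "need at least one site")
  set.seed(as.integer(seed %% 2147483647))
  sizes <- genome$chrom_sizes
  lens <- sample(interval_width(sites), n, replace = TRUE)
  abort_if(max(lens) > max(sizes), "site longer than every chromosome")
  chrom <- sample(names(sizes), n, replace = TRUE, prob = sizes / sum(sizes))
  redo <- which(lens > sizes[chrom])
  while (length(redo)) {  # re-draw chromosomes too short for the length
    chrom[redo] <- sample(names(sizes), length(redo), replace = TRUE,
                          prob = sizes / sum(sizes))
    redo <- redo[lens[redo] > sizes[chrom[redo]]]
  }
  start <- floor(stats::runif(n) * (sizes[chrom] - lens))
  genomic_intervals(chrom, start, start + lens,
                    name = sprintf("random%05d", seq_len(n)))
}

#' Draw a random set matched for the sites' genomic category distribution
#'
#' First annotates the sites, then rejection-samples length-matched random
#' intervals per category until the random per-category counts equal the
#' observed ones.
#'
#' @inheritParams sample_random_lengthmatched
#' @param promoter_flank Promoter window half-width used for annotation.
#' @param max_attempts Cap on candidate draws per category before giving up.
#' @return Interval data frame with the same `category_counts` as the sites.
#' @export
sample_random_distributionmatched <- function(sites, genome, seed,
                                              promoter_flank = 1000L,
                                              max_attempts = 1e6) {
  target <- annotate_sites(sites, genome, promoter_flank)
  need <- stats::setNames(target$count, target$category)
  need <- need[need > 0]
  if (any(grepl("_CGI$", names(need))) && nrow(genome$cgis) == 0L) {
    stop("category quota unreachable (no CGIs in genome): ",
         paste(grep("_CGI$", names(need), value = TRUE), collapse = ", "),
         call. = FALSE)
  }
  set.seed(as.integer(seed %% 2147483647))
  lens_pool <- interval_width(sites)
  sizes <- genome$chrom_sizes
  acc <- list()
  attempts <- stats::setNames(rep(0, length(need)), names(need))
  while (any(need > 0)) {
    m <- max(2000L, 4L * sum(need))
    lens <- sample(lens_pool, m, replace = TRUE)
    chrom <- sample(names(sizes), m, replace = TRUE,
                    prob = sizes / sum(sizes))
    ok <- lens <= sizes[chrom]
    lens <- lens[ok]; chrom <- chrom[ok]
    start <- floor(stats::runif(length(lens)) * (sizes[chrom] - lens))
    cand <- genomic_intervals(chrom, start, start + lens)
    cat_c <- classify_sites(cand, genome, promoter_flank)$category
    drawn <- table(factor(cat_c, levels = names(need)))
    attempts <- attempts + as.numeric(drawn) +
      (length(lens) - sum(drawn)) / length(need)
    for (cc in names(need)[need > 0]) {
      idx <- which(cat_c == cc)
      take <- idx[seq_len(min(length(idx), need[[cc]]))]
      if (length(take)) {
        acc[[length(acc) + 1L]] <- cand[take, , drop = FALSE]
        need[[cc]] <- need[[cc]] - length(take)
      }
    }
    unfilled <- names(need)[need > 0]
    over <- unfilled[attempts[unfilled] > max_attempts]
    abort_if(length(over) > 0,
             "category quota unreachable after ", max_attempts,
             " attempts: ", paste(over, collapse = ", "))
  }
  out <- do.call(rbind, acc)
  out$name <- sprintf("random%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Fold enrichment of observed over random category shares
#'
#' `fold(c) = (obs(c) / obs_total) / (rand(c) / rand_total)`. Categories
#' with a zero random share but observed sites get `Inf`; 0/0 is `NaN`
#' (undefined), never an error.
#'
#' @param obs,rand `category_counts` from [annotate_sites()].
#' @return Data frame: category, obs_count, rand_count, obs_share,
#'   rand_share, fold.
#' @export
fold_over_random <- function(obs, rand) {
  abort_if(attr(obs, "total") == 0, "observed set is empty")
  abort_if(attr(rand, "total") == 0, "random set is empty")
  stopifnot(identical(obs$category, rand$category))
  obs_share <- obs$count / attr(obs, "total")
  rand_share <- rand$count / attr(rand, "total")
  fold <- ifelse(obs_share == 0 & rand_share == 0, NaN,
                 obs_share / rand_share)
  data.frame(category = obs$category,
             obs_count = obs$count, rand_count = rand$count,
             obs_share = obs_share, rand_share = rand_share,
             fold = fold, stringsAsFactors = FALSE)
}
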