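# Interval methylation, methyl-CpG density and enrichment window tracks,
# and the ranked density-vs-enrichment correlation.

#' Coverage-weighted methylation level of one interval
#'
#' Mean of per-CpG methylation fractions weighted by read coverage, over
#' CpGs with `coverage >= min_coverage` inside the interval. `NA`
#' (undefined) when no CpG qualifies - a value, not an error.
#'
#' @param site One-row interval data frame.
#' @param cpgs A `cpg_table`.
#' @param min_coverage Minimum per-CpG read coverage (>= 1).
#' @return A methylation level in `[0, 1]`, or `NA`.
#' @export
interval_methylation <- function(site, cpgs, min_coverage = 1L) {
  abort_if(nrow(site) != 1L, "interval_methylation expects a single site")
  interval_methylation_many(site, cpgs, min_coverage)
}

#' Coverage-weighted methylation level of many intervals
#'
#' Vectorised form of [interval_methylation()].
#'
#' @param sites Interval data frame.
#' @inheritParams interval_methylation
#' @return Numeric vector, one level (or `NA`) per site.
#' @export
interval_methylation_many <- function(sites, cpgs, min_coverage = 1L) {
  abort_if(min_coverage < 1, "min_coverage must be >= 1")
  validate_intervals(sites, "site set")
  keep <- cpgs$coverage >= min_coverage
  cp <- cpgs[keep, , drop = FALSE]
  out <- rep(NA_real_, nrow(sites))
  if (nrow(cp) == 0L || nrow(sites) == 0L) return(out)
  hits <- point_overlap_pairs(cp$chrom, cp$pos, sites)
  if (nrow(hits) == 0L) return(out)
  w <- cp$coverage[hits$query]
  mw <- cp$meth[hits$query] * w
  num <- tapply(mw, hits$subject, sum)
  den <- tapply(w, hits$subject, sum)
  idx <- as.integer(names(num))
  out[idx] <- as.numeric(num) / as.numeric(den)
  out
}

#' Per-site methylation levels with a five-number summary
#'
#' Applies [interval_methylation_many()]; undefined sites are excluded and
#' counted. Errors if every site is undefined.
#'
#' @inheritParams interval_methylation_many
#' @return List: `levels` (defined values), `n_undefined`, `summary`
#'   (min, Q1, median, Q3, max).
#' @export
methylation_site_distribution <- function(sites, cpgs, min_coverage = 1L) {
  v <- interval_methylation_many(sites, cpgs, min_coverage)
  ok <- !is.na(v)
  abort_if(!any(ok), "no site has a defined methylation level")
  list(levels = v[ok], n_undefined = sum(!ok),
       summary = five_number(v[ok]))
}

#' Tile chromosomes into fixed windows
#'
#' Windows of `window` bp every `step` bp; the last partial window is
#' dropped, so each chromosome contributes
#' `floor((len - window) / step) + 1` windows.
#'
#' @param chrom_sizes Named chromosome lengths.
#' @param window,step Window size and step (bp).
#' @return A `window_track` data frame (chrom/start/end/value = NA) with
#'   attributes `window` and `step`.
#' @export
make_windows <- function(chrom_sizes, window, step = window) {
  rows <- lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    if (L < window) return(NULL)
    n <- (L - window) %/% step + 1
    s <- as.integer(seq(0, by = step, length.out = n))
    data.frame(chrom = ch, start = s, end = s + as.integer(window),
               value = NA_real_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "window") <- window
  attr(out, "step") <- step
  class(out) <- c("window_track", "data.frame")
  out
}

#' Methyl-CpG density per genomic window
#'
#' `value(w) = sum of meth_fraction over CpGs in w / window length`, i.e.
#' methylated-CpG equivalents per bp. Windows without CpGs get 0.
#'
#' @param cpgs A `cpg_table`.
#' @param chrom_sizes Named chromosome lengths.
#' @param window Window size (bp).
#' @param step Step (bp); must not exceed `window` (gaps would bias the
#'   ranked correlation).
#' @return A `window_track`.
#' @export
mcpg_density_track <- function(cpgs, chrom_sizes, window, step = window) {
  abort_if(step > window, "step must not exceed window (tiling required)")
  wt <- make_windows(chrom_sizes, window, step)
  wt$value <- 0
  hits <- point_overlap_pairs(cpgs$chrom, cpgs$pos, wt)
  if (nrow(hits)) {
    s <- tapply(cpgs$meth[hits$query], hits$subject, sum)
    wt$value[as.integer(names(s))] <- as.numeric(s) / window
  }
  wt
}

window_tag_counts <- function(track, wt) {
  counts <- numeric(nrow(wt))
  hits <- point_overlap_pairs(track$tags$chrom, track$tags$pos, wt)
  if (nrow(hits)) {
    s <- table(hits$subject)
    counts[as.integer(names(s))] <- as.numeric(s)
  }
  counts
}

#' ChIP enrichment over input per genomic window
#'
#' `value(w) = log2((chip_w / chip_total + p) / (input_w / input_total + p))`
#' with pseudo-frequency `p = 0.5 / min(totals)` so empty windows stay
#' finite. Tags are assigned to the window containing their 5' position.
#'
#' @param chip,input `tag_track` objects with positive totals.
#' @param chrom_sizes Named chromosome lengths.
#' @param window Window size (bp); windows tile (step = window).
#' @return A `window_track` of log2 enrichment values.
#' @export
enrichment_track <- function(chip, input, chrom_sizes, window) {
  abort_if(chip$total_mapped <= 0 || input$total_mapped <= 0,
           "tracks must have positive total_mapped")
  wt <- make_windows(chrom_sizes, window, window)
  p <- 0.5 / min(chip$total_mapped, input$total_mapped)
  cw <- window_tag_counts(chip, wt)
  iw <- window_tag_counts(input, wt)
  wt$value <- log2((cw / chip$total_mapped + p) /
                     (iw / input$total_mapped + p))
  wt
}

# Spearman rank correlation with a fixed convention for degenerate input:
# a constant vector has no ranking signal, so rho is reported as 0.
spearman_rho <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y, method = "spearman")
}

#' Enrichment as a function of methylation-density rank
#'
#' Windows are sorted by ascending density (ties broken by genomic order,
#' deterministically), the enrichment values are smoothed by averaging
#' consecutive runs of `ceil(N / n_points)` sorted windows, and the
#' Spearman correlation between density and enrichment is computed over all
#' windows.
#'
#' @param density,enrichment `window_track`s on identical window grids.
#' @param n_points Number of curve samples.
#' @return List: `curve` (data frame rank_quantile / density / enrichment),
#'   `rho` (Spearman), `n_windows`.
#' @export
ranked_density_enrichment <- function(density, enrichment, n_points = 100L) {
  same_grid <- identical(attr(density, "window"), attr(enrichment, "window")) &&
    identical(attr(density, "step"), attr(enrichment, "step")) &&
    nrow(density) == nrow(enrichment) &&
    all(density$chrom == enrichment$chrom) &&
    all(density$start == enrichment$start)
  abort_if(!same_grid, "density and enrichment tracks use different grids")
  n <- nrow(density)
  ord <- order(density$value, seq_len(n))  # stable: genomic order on ties
  d <- density$value[ord]
  e <- enrichment$value[ord]
  k <- ceiling(n / n_points)
  grp <- ceiling(seq_len(n) / k)
  curve <- data.frame(
    rank_quantile = as.numeric(tapply(seq_len(n) / n, grp, mean)),
    density = as.numeric(tapply(d, grp, mean)),
    enrichment = as.numeric(tapply(e, grp, mean)))
  list(curve = curve, rho = spearman_rho(density$value, enrichment$value),
       n_windows = n)
}
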