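# Interval methylation, window tracks and the ranked correlation.

test_that("interval methylation is the coverage-weighted mean", {
  cp <- cpg_table(rep("chr1", 3), c(10L, 20L, 500L),
                  c(1.0, 0.0, 0.7), c(10L, 10L, 5L))
  site <- genomic_intervals("chr1", 0L, 100L)
  expect_equal(interval_methylation(site, cp), 0.5)
  cp2 <- cpg_table(rep("chr1", 2), c(10L, 20L), c(1.0, 0.5), c(30L, 10L))
  expect_equal(interval_methylation(site, cp2), 35 / 40)  # (30 + 5) / 40
  # coverage floor excludes low-coverage calls
  expect_equal(interval_methylation(site, cp2, min_coverage = 20L), 1.0)
  # no CpG in the site -> undefined, not an error
  expect_true(is.na(interval_methylation(genomic_intervals("chr1", 900L,
                                                           950L), cp)))
})

test_that("interval methylation recombines across a split site", {
  set.seed(5)
  cp <- cpg_table(rep("chr1", 200), sort(sample(1e4, 200)),
                  runif(200), rpois(200, 20) + 1L)
  for (i in 1:20) {
    s <- sample(8000L, 1); e <- s + sample(500:1500, 1); mid <- (s + e) %/% 2
    full <- interval_methylation(genomic_intervals("chr1", s, e), cp)
    left <- genomic_intervals("chr1", s, mid)
    right <- genomic_intervals("chr1", mid, e)
    wsum <- function(iv) {
      hit <- cp$pos >= iv$start & cp$pos < iv$end
      c(num = sum(cp$meth[hit] * cp$coverage[hit]),
        den = sum(cp$coverage[hit]))
    }
    parts <- wsum(left) + wsum(right)
    if (parts[["den"]] > 0) {
      expect_equal(full, parts[["num"]] / parts[["den"]])
    }
  }
})

test_that("site distribution summary matches an independent quantile", {
  ds <- default_dataset()
  d <- methylation_site_distribution(ds$truth$peaks, ds$methylome)
  expect_equal(unname(d$summary),
               unname(quantile(d$levels, c(0, .25, .5, .75, 1), type = 7)))
  expect_equal(length(d$levels) + d$n_undefined, nrow(ds$truth$peaks))

  # uniform methylome: every site level 0.3, zero IQR
  cp <- cpg_table(rep("chr1", 100), seq(0L, 9900L, by = 100L), 0.3, 30L)
  sites <- genomic_intervals("chr1", c(0L, 2000L), c(1000L, 3000L))
  du <- methylation_site_distribution(sites, cp)
  expect_true(all(du$levels == 0.3))
  expect_equal(unname(du$summary["q3"] - du$summary["q1"]), 0)
  expect_error(methylation_site_distribution(
    genomic_intervals("chrZ", 0L, 10L), cp), "no site")
})

test_that("mCpG density implements sum(meth)/length per window", {
  cp <- cpg_table(rep("chr1", 3), c(100L, 200L, 300L), c(1.0, 0.5, 0.5),
                  rep(10L, 3))
  tr <- mcpg_density_track(cp, c(chr1 = 3000L), window = 1000L)
  expect_equal(tr$value, c(0.002, 0, 0))
  expect_true(all(tr$value >= 0))
  # step > window is rejected (gaps would bias the ranking)
  expect_error(mcpg_density_track(cp, c(chr1 = 3000L), 100L, step = 200L),
               "step")
  # scale invariance on a homogeneous CpG field
  set.seed(3)
  n <- 5000L
  cph <- cpg_table(rep("chr1", n), sort(sample(5e5, n)), runif(n), 30L)
  t1 <- mcpg_density_track(cph, c(chr1 = 5e5), 1000L)
  t2 <- mcpg_density_track(cph, c(chr1 = 5e5), 2000L)
  expect_lt(abs(mean(t1$value) - mean(t2$value)), 0.0002)
})

test_that("window grids drop the last partial window", {
  w <- make_windows(c(chr1 = 1050L, chr2 = 90L), window = 100L, step = 50L)
  expect_equal(sum(w$chrom == "chr1"), (1050 - 100) %/% 50 + 1)
  expect_false(any(w$chrom == "chr2"))  # shorter than one window
  expect_true(all(w$end <= 1050))
})

test_that("enrichment is a depth-normalised log2 ratio over input", {
  mk <- function(n, total) {
    tag_track("t", rep("chr1", n), sort(sample.int(900L, n)), "+",
              total_mapped = total)
  }
  set.seed(8)
  chip <- mk(40L, 1e6)
  input <- tag_track("i", rep("chr1", 10L), sample.int(900L, 10L), "+",
                     total_mapped = 1e6)
  tr <- enrichment_track(chip, input, c(chr1 = 1000L), 1000L)
  p <- 0.5 / 1e6
  expect_equal(tr$value, log2((40 / 1e6 + p) / (10 / 1e6 + p)))
  expect_lt(abs(tr$value - 2), 0.1)

  # identical tag lists -> exactly zero
  same <- enrichment_track(chip, chip, c(chr1 = 1000L), 500L)
  expect_true(all(same$value == 0))

  # duplicating chip tags and doubling its total changes nothing
  chip2 <- tag_track("t", rep(chip$tags$chrom, 2), rep(chip$tags$pos, 2),
                     rep(chip$tags$strand, 2), total_mapped = 2e6)
  tr2 <- enrichment_track(chip2, input, c(chr1 = 1000L), 1000L)
  expect_equal(tr2$value, tr$value)
  expect_error(enrichment_track(chip, tag_track("z", character(0),
                                                integer(0), character(0),
                                                total_mapped = NULL),
                                c(chr1 = 1000L), 1000L), "total")
})

test_that("ranked density-enrichment handles degenerate and exact cases", {
  w <- make_windows(c(chr1 = 100000L), 1000L)
  d <- w; set.seed(2); d$value <- runif(nrow(w))
  e_const <- w; e_const$value <- rep(1.5, nrow(w))
  rk0 <- ranked_density_enrichment(d, e_const, n_points = 10L)
  expect_equal(rk0$rho, 0)
  expect_true(all(abs(rk0$curve$enrichment - 1.5) < 1e-12))
  e_id <- d
  expect_equal(ranked_density_enrichment(d, e_id, 10L)$rho, 1)
  bad <- make_windows(c(chr1 = 100000L), 2000L)
  bad$value <- runif(nrow(bad))
  expect_error(ranked_density_enrichment(d, bad), "grid")
})

test_that("Spearman rho matches the independent implementation to 1e-12", {
  set.seed(77)
  w <- make_windows(c(chr1 = 1000000L), 1000L)
  d <- w; d$value <- round(runif(nrow(w)), 2)  # ties on purpose
  e <- w; e$value <- d$value + rnorm(nrow(w), 0, 0.5)
  rk <- ranked_density_enrichment(d, e, 100L)
  expect_equal(rk$rho, oracle_spearman(d$value, e$value), tolerance = 1e-12)
  expect_equal(rk$n_windows, 1000L)
})

test_that("planted methylation-enrichment coupling is recovered", {
  ds <- default_dataset()
  dens <- mcpg_density_track(ds$methylome, ds$genome$chrom_sizes, 1000L)
  enr <- enrichment_track(ds$tracks$MBD2, ds$tracks$input,
                          ds$genome$chrom_sizes, 1000L)
  rk <- ranked_density_enrichment(dens, enr)
  expect_gt(rk$rho, 0.3)
  # the smoothed curve rises from the low-density to the high-density end
  ends <- c(mean(head(rk$curve$enrichment, 10)),
            mean(tail(rk$curve$enrichment, 10)))
  expect_gt(ends[2], ends[1])
})

test_that("methylomes with different Beta means order correctly in windows", {
  cfg_lo <- small_config(seed = 14L, meth_background_dist = c(2, 8),
                         cgi_promoter_fraction = 0, cgi_exon_fraction = 0,
                         n_cluster4 = 0L)
  cfg_hi <- small_config(seed = 14L, meth_background_dist = c(8, 2),
                         cgi_promoter_fraction = 0, cgi_exon_fraction = 0,
                         n_cluster4 = 0L)
  g <- generate_genome(cfg_lo)
  m_lo <- generate_methylome(g, cfg_lo)
  m_hi <- generate_methylome(g, cfg_hi)
  t_lo <- mcpg_density_track(m_lo, g$chrom_sizes, 50L)
  t_hi <- mcpg_density_track(m_hi, g$chrom_sizes, 50L)
  expect_gt(mean(t_hi$value), mean(t_lo$value))
})
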