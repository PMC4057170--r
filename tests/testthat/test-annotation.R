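# Hierarchical site annotation, matched random nulls, fold over random.

tiny_genome <- function() {
  genes <- gene_table(
    gene_id = c("gA", "gB"),
    chrom = c("chr1", "chr1"),
    start = c(1000L, 20000L), end = c(9000L, 30000L),
    strand = c("+", "-"),
    exon_starts = c("0,4000", "0,8000"),
    exon_sizes = c("500,1000", "1000,2000"))
  cgis <- genomic_intervals("chr1", 500L, 1500L, "cgi1")
  genome_annotation(c(chr1 = 50000L, chr2 = 50000L), genes, cgis)
}

test_that("classification follows the promoter>exon>intron hierarchy", {
  g <- tiny_genome()
  # overlaps gA's promoter window [0, 2000) AND its first exon
  expect_equal(classify_site(genomic_intervals("chr1", 900L, 1100L),
                             g)$feature, "promoter")
  # inside gA span, over exon 2 [5000, 6000), outside the promoter window
  expect_equal(classify_site(genomic_intervals("chr1", 5100L, 5200L),
                             g)$feature, "exon")
  # inside gA span between exons
  expect_equal(classify_site(genomic_intervals("chr1", 3000L, 3100L),
                             g)$feature, "intron")
  # open genome, no gene, no CGI
  cl <- classify_site(genomic_intervals("chr2", 100L, 200L), g)
  expect_equal(cl$feature, "intergenic")
  expect_false(cl$cgi)
  # CGI flag is independent of the hierarchy
  expect_true(classify_site(genomic_intervals("chr1", 600L, 700L), g)$cgi)
  # minus-strand promoter: gB TSS = 29999, window [28999, 30999)
  expect_equal(classify_site(genomic_intervals("chr1", 30500L, 30600L),
                             g)$feature, "promoter")
})

test_that("adding an exon under a promoter-classified site changes nothing", {
  g <- tiny_genome()
  site <- genomic_intervals("chr1", 900L, 1100L)
  expect_equal(classify_site(site, g)$feature, "promoter")
  # a new gene whose middle exon [850, 1250) covers the site
  g3 <- g
  g3$genes <- rbind(g$genes, gene_table("gD", "chr1", 500L, 40000L, "+",
                                        "0,350,30000", "100,400,500"))
  expect_equal(classify_site(site, g3)$feature, "promoter")
})

test_that("classification agrees with the per-rule oracle on fuzzed sites", {
  cfg <- small_config(seed = 13L)
  g <- generate_genome(cfg)
  set.seed(99)
  n <- 1000L
  sites <- genomic_intervals(
    sample(names(g$chrom_sizes), n, TRUE),
    s <- sample(1.4e6, n), s + sample(2000L, n))
  got <- classify_sites(sites, g)
  for (i in seq_len(n)) {
    want <- oracle_classify(sites[i, ], g)
    expect_identical(got$feature[i], want$feature)
    expect_identical(got$cgi[i], want$cgi)
  }
  # partition: exactly one of 8 categories each, counts sum to total
  counts <- annotate_sites(sites, g)
  expect_equal(sum(counts$count), n)
  expect_true(all(got$category %in% counts$category))
})

test_that("annotate_sites handles the empty set and preserves totals", {
  g <- tiny_genome()
  z <- annotate_sites(genomic_intervals(character(0), integer(0),
                                        integer(0)), g)
  expect_equal(sum(z$count), 0L)
  expect_equal(attr(z, "total"), 0L)
  expect_equal(nrow(z), 8L)
})

test_that("planted CGI-promoter peaks are recovered by annotation", {
  # all hypermethylated peaks anchored at promoter CGIs (90% of the total)
  cfg <- synthetic_config(seed = 8L, cgi_exon_fraction = 0,
                          cgi_hyper_fraction = 0.8, n_cluster4 = 0L)
  g <- generate_genome(cfg)
  m <- generate_methylome(g, cfg)
  ch <- generate_chip_tags(g, m, cfg)
  counts <- annotate_sites(ch$truth$peaks, g)
  share <- counts$count[counts$category == "promoter_CGI"] /
    attr(counts, "total")
  expect_gte(share, 0.8)
})

test_that("length-matched random sets match count and length", {
  ds <- default_dataset()
  sites <- ds$truth$peaks
  r1 <- sample_random_lengthmatched(sites, ds$genome, seed = 4L)
  expect_equal(nrow(r1), nrow(sites))
  expect_identical(r1, sample_random_lengthmatched(sites, ds$genome,
                                                   seed = 4L))
  means <- vapply(1:10, function(s) {
    mean(interval_width(sample_random_lengthmatched(sites, ds$genome, s)))
  }, numeric(1))
  expect_lt(abs(mean(means) / mean(interval_width(sites)) - 1), 0.05)
})

test_that("distribution-matched random reproduces the category counts", {
  ds <- default_dataset()
  sites <- ds$truth$peaks
  rnd <- sample_random_distributionmatched(sites, ds$genome, seed = 6L)
  expect_equal(annotate_sites(rnd, ds$genome)$count,
               annotate_sites(sites, ds$genome)$count)
  # unreachable quota errors name the category instead of spinning
  expect_error(
    sample_random_distributionmatched(sites, ds$genome, seed = 6L,
                                      max_attempts = 2),
    "quota unreachable")
  # matched random has a different methylation distribution than naive
  naive <- sample_random_lengthmatched(sites, ds$genome, seed = 6L)
  v_m <- interval_methylation_many(rnd, ds$methylome)
  v_n <- interval_methylation_many(naive, ds$methylome)
  ks <- suppressWarnings(stats::ks.test(v_m[!is.na(v_m)],
                                        v_n[!is.na(v_n)]))
  expect_gt(unname(ks$statistic), 0)
})

test_that("fold_over_random arithmetic, identity and boundary flags", {
  obs <- make_counts(c(promoter_CGI = 50L, intergenic_nonCGI = 50L))
  rnd <- make_counts(c(promoter_CGI = 10L, intergenic_nonCGI = 90L))
  f <- fold_over_random(obs, rnd)
  expect_equal(f$fold[f$category == "promoter_CGI"], 5.0)
  # identity: identical counts give fold 1 wherever defined
  fi <- fold_over_random(obs, obs)
  expect_true(all(fi$fold[obs$count > 0] == 1))
  expect_true(all(is.nan(fi$fold[obs$count == 0])))
  # rand 0 with obs > 0 flags infinity, not an error
  rnd0 <- make_counts(c(promoter_CGI = 0L, intergenic_nonCGI = 100L))
  obs3 <- make_counts(c(promoter_CGI = 3L, intergenic_nonCGI = 97L))
  expect_equal(fold_over_random(obs3, rnd0)$fold[1], Inf)
  empty <- make_counts(integer(0))
  expect_error(fold_over_random(empty, rnd), "empty")
})

test_that("fold over an identically distributed set converges to 1", {
  ds <- default_dataset()
  seed_sites <- ds$truth$peaks
  a <- sample_random_lengthmatched(seed_sites, ds$genome, seed = 101L,
                                   n = 10000L)
  b <- sample_random_lengthmatched(seed_sites, ds$genome, seed = 202L,
                                   n = 10000L)
  f <- fold_over_random(annotate_sites(a, ds$genome),
                        annotate_sites(b, ds$genome))
  # only categories large enough to have power at n = 1e4
  big <- f$rand_count >= 500
  expect_true(any(big))
  expect_true(all(abs(f$fold[big] - 1) <= 0.1))
})
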