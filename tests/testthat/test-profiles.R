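# Profile matrices, k-means clustering with mirror merging, TSS/metagene
# profiles and methylation/CpG profiles.

# handmade profile_matrix for clustering fixtures
pm_fixture <- function(mat, name = "m") {
  structure(list(mat = mat, anchors = NULL, flank = ncol(mat) * 10L,
                 bin = 20L, n_dropped = 0L, track = name,
                 strand_aware = FALSE),
            class = "profile_matrix")
}

test_that("tag matrix bins, normalises and drops edge anchors", {
  anchors <- genomic_intervals("chr1", c(20000L, 2000L), c(20000L, 2000L) + 1L)
  empty <- tag_track("e", character(0), integer(0), character(0),
                     total_mapped = 1)
  pm0 <- tag_density_matrix(empty, anchors, flank = 5000L, bin = 20L)
  expect_true(all(pm0$mat == 0))
  expect_equal(pm0$n_dropped, 1L)   # anchor at 2000 is within flank of edge

  # a tag exactly at the anchor centre lands in the first downstream bin
  tr <- tag_track("t", "chr1", 20000L, "+", total_mapped = 1e7)
  pm <- tag_density_matrix(tr, anchors[1, ], flank = 5000L, bin = 20L)
  expect_equal(which(pm$mat[1, ] != 0), 251L)  # 0-indexed bin 250
  expect_equal(pm$mat[1, 251], 1)              # reads-per-10-million units
  expect_error(tag_density_matrix(tr, anchors, flank = 5000L, bin = 300L),
               "divide")
})

test_that("tag matrix equals a per-anchor brute-force count", {
  set.seed(31)
  tr <- tag_track("t", sample(c("chr1", "chr2"), 400, TRUE),
                  sample(20000L, 400), sample(c("+", "-"), 400, TRUE),
                  total_mapped = 1000L)
  anchors <- genomic_intervals(sample(c("chr1", "chr2"), 12, TRUE),
                               a <- sample(3000:17000, 12), a + 50L,
                               strand = sample(c("+", "-"), 12, TRUE))
  pm <- tag_density_matrix(tr, anchors, flank = 2000L, bin = 100L,
                           strand_aware = TRUE)
  nb <- 40L
  for (i in seq_len(nrow(pm$anchors))) {
    ctr <- (pm$anchors$start[i] + pm$anchors$end[i]) %/% 2L
    cnt <- numeric(nb)
    for (j in seq_len(nrow(tr$tags))) {
      if (tr$tags$chrom[j] != pm$anchors$chrom[i]) next
      d <- tr$tags$pos[j] - (ctr - 2000L)
      if (d >= 0 && d < 4000L) {
        b <- d %/% 100L + 1L
        cnt[b] <- cnt[b] + 1
      }
    }
    if (pm$anchors$strand[i] == "-") cnt <- rev(cnt)
    expect_equal(pm$mat[i, ], cnt * 1e7 / 1000, ignore_attr = TRUE)
  }
})

test_that("duplicating tags and total leaves profiles unchanged", {
  ds <- default_dataset()
  tr <- ds$tracks$Pol2
  tr2 <- tag_track("Pol2x2", rep(tr$tags$chrom, 2), rep(tr$tags$pos, 2),
                   rep(tr$tags$strand, 2), total_mapped = 2 * tr$total_mapped)
  anchors <- ds$truth$peaks[1:30, ]
  p1 <- tag_density_matrix(tr, anchors, chrom_sizes = ds$genome$chrom_sizes)
  p2 <- tag_density_matrix(tr2, anchors, chrom_sizes = ds$genome$chrom_sizes)
  expect_equal(p1$mat, p2$mat)
})

test_that("matrix totals equal in-window tag counts times normalisation", {
  ds <- default_dataset()
  tr <- ds$tracks$MBD2
  anchors <- ds$truth$peaks
  pm <- tag_density_matrix(tr, anchors, flank = 5000L, bin = 20L,
                           chrom_sizes = ds$genome$chrom_sizes)
  ctr <- (pm$anchors$start + pm$anchors$end) %/% 2L
  win <- data.frame(chrom = pm$anchors$chrom, start = ctr - 5000L,
                    end = ctr + 5000L)
  n_in <- nrow(mbdscape:::point_overlap_pairs(tr$tags$chrom, tr$tags$pos,
                                              win))
  expect_equal(sum(pm$mat), n_in * 1e7 / tr$total_mapped)
})

test_that("k-means recovers planted archetypes and is deterministic", {
  set.seed(17)
  n <- 60L; nb <- 50L
  truth <- rep(1:2, each = n / 2)
  bump <- function(center) dnorm(seq_len(nb), center, 3) * 60
  mat <- t(vapply(truth, function(g) {
    bump(if (g == 1) 15 else 35) + rnorm(nb, 0, 0.3)
  }, numeric(nb)))
  asg <- kmeans_cluster(list(m = pm_fixture(mat)), k = 2L, seed = 1L)
  expect_gte(mclust::adjustedRandIndex(asg$cluster, truth), 0.95)
  asg2 <- kmeans_cluster(list(m = pm_fixture(mat)), k = 2L, seed = 1L)
  expect_identical(asg$cluster, asg2$cluster)

  one <- kmeans_cluster(list(m = pm_fixture(mat)), k = 1L, seed = 1L)
  expect_true(all(one$cluster == 1L))
  expect_equal(as.vector(one$profiles$m), colMeans(mat))
  expect_error(kmeans_cluster(list(m = pm_fixture(mat)), k = 100L,
                              seed = 1L), "k exceeds")
})

test_that("display-only marks never change the assignment", {
  set.seed(18)
  mat <- matrix(rnorm(60 * 30), 60)
  mat[1:30, 1:10] <- mat[1:30, 1:10] + 5
  noise <- matrix(rnorm(60 * 30), 60)
  a1 <- kmeans_cluster(list(sig = pm_fixture(mat)), k = 2L, seed = 2L)
  a2 <- kmeans_cluster(list(sig = pm_fixture(mat),
                            extra = pm_fixture(noise)),
                       k = 2L, seed = 2L, display_only = "extra")
  expect_identical(a1$cluster, a2$cluster)
  expect_true("extra" %in% names(a2$profiles))
})

test_that("mirror merging joins reversed pairs and only those", {
  set.seed(19)
  nb <- 40L
  bump <- function(center, h = 8) dnorm(seq_len(nb), center, 2.5) * h * 10
  rows <- list(
    left = t(replicate(20, bump(10) + rnorm(nb, 0, 0.2))),
    right = t(replicate(20, rev(bump(10)) + rnorm(nb, 0, 0.2))),
    tall = t(replicate(20, bump(20.5, 30) + rnorm(nb, 0, 0.2))),
    twin = t(replicate(20, bump(13) + bump(28) + rnorm(nb, 0, 0.2))))
  mat <- do.call(rbind, rows)
  truth <- rep(names(rows), each = 20)
  asg <- kmeans_cluster(list(m = pm_fixture(mat)), k = 4L, seed = 3L)
  merged <- merge_mirrored(asg, threshold = 0.8)
  expect_equal(merged$k, 3L)
  expect_equal(length(merged$merge_history), 1L)
  # the merged cluster holds exactly the mirror pair, flagged reversed on
  # one side
  pair_id <- merged$cluster[truth == "left"][1]
  expect_true(all(merged$cluster[truth %in% c("left", "right")] == pair_id))
  expect_equal(sum(merged$reversed[merged$cluster == pair_id]), 20L)
  # symmetric but different profiles never merge (tall vs twin)
  expect_false(any(merged$cluster[truth == "tall"] %in%
                     merged$cluster[truth == "twin"]))
})

test_that("average profile reports mean and percentile bands", {
  pm <- pm_fixture(rbind(rep(0, 10), rep(2, 10)))
  ap <- average_profile(pm)
  expect_true(all(ap$mean == 1))
  single <- average_profile(pm, members = 2L)
  expect_true(all(single$mean == 2 & single$p50 == 2 & single$p90 == 2))
  expect_error(average_profile(pm, members = integer(0)), "empty")
  set.seed(20)
  pmr <- pm_fixture(matrix(rnorm(200), 20))
  apr <- average_profile(pmr)
  expect_equal(apr$p90,
               apply(pmr$mat, 2, quantile, probs = 0.9, type = 7,
                     names = FALSE))
})

test_that("TSS profile is strand-aware and flat on uniform background", {
  # minus-strand gene: a tag 500 bp 5' of the TSS (genomically downstream)
  g <- gene_table("gm", "chr1", 10000L, 20000L, "-", "0", "10000")
  tss <- gene_tss(g)  # 19999
  tr <- tag_track("t", "chr1", tss + 500L, "-", total_mapped = 100L)
  tp <- tss_profile(tr, g, flank = 2000L, bin = 100L)
  expect_equal(tp$max_offset, -550)  # upstream bin midpoint
  ds <- default_dataset()
  flat <- tag_density_matrix(ds$tracks$input, ds$truth$peaks,
                             flank = 5000L, bin = 250L,
                             chrom_sizes = ds$genome$chrom_sizes)
  prof <- colMeans(flat$mat)
  expect_lt(max(prof) / min(prof), 1.5)
})

test_that("cluster-4 MBD2 profile peaks ~1 kb downstream of the TSS", {
  ds <- default_dataset()
  c4 <- ds$genome$genes[ds$genome$genes$cluster4, ]
  tp <- tss_profile(ds$tracks$MBD2, c4, flank = 5000L, bin = 100L,
                    chrom_sizes = ds$genome$chrom_sizes)
  expect_lt(abs(tp$max_offset - 1000), 200)
})

test_that("metagene profile filters short genes and steps down after TES", {
  ds <- default_dataset()
  genes <- ds$genome$genes
  mg <- metagene_profile(ds$tracks$H3K36me3, genes,
                         anchor_flank = 2000L, min_gene_length = 4000L,
                         chrom_sizes = ds$genome$chrom_sizes)
  expect_equal(mg$n_excluded, sum(genes$end - genes$start < 4000))
  inside <- mg$tes$mean[mg$tes$offset < 0]
  outside <- mg$tes$mean[mg$tes$offset > 0]
  expect_gt(mean(inside), 1.5 * mean(outside))
  short <- genes[genes$end - genes$start < 4000, ]
  expect_error(metagene_profile(ds$tracks$H3K36me3, short,
                                min_gene_length = 4000L), "length filter")
  expect_error(metagene_profile(ds$tracks$H3K36me3, genes,
                                anchor_flank = 3000L,
                                min_gene_length = 4000L), "2 \\* anchor")
})

test_that("methylation/CpG profile matches brute-force recomputation", {
  cp <- cpg_table(rep("chr1", 4), c(9950L, 10050L, 10500L, 30000L),
                  c(0.8, 0.8, 0.8, 0.8), rep(10L, 4))
  anchors <- genomic_intervals("chr1", 10000L, 10001L)
  mp <- methylation_cpg_profile(cp, anchors, flank = 1000L, bin = 100L)
  expect_true(all(mp$meth[!is.na(mp$meth)] == 0.8))
  expect_equal(sum(mp$n_cpg), 3)           # CpG at 30000 is out of range
  expect_equal(mp$cpg_density[mp$offset == -50], 1 / 100)
  expect_true(all(mp$cpg_density[abs(mp$offset) > 600] == 0))

  set.seed(23)
  cpr <- cpg_table(rep("chr1", 300), sort(sample(40000L, 300)),
                   runif(300), rep(10L, 300))
  anch <- genomic_intervals("chr1", c(15000L, 22000L), c(15400L, 22400L))
  mpr <- methylation_cpg_profile(cpr, anch, flank = 2000L, bin = 200L)
  for (b in seq_len(20)) {
    lo <- -2000 + (b - 1) * 200
    vals <- c()
    for (i in 1:2) {
      ctr <- (anch$start[i] + anch$end[i]) %/% 2
      hit <- cpr$pos >= ctr + lo & cpr$pos < ctr + lo + 200
      vals <- c(vals, cpr$meth[hit])
    }
    if (length(vals)) expect_equal(mpr$meth[b], mean(vals))
    expect_equal(mpr$n_cpg[b], length(vals))
  }
})
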