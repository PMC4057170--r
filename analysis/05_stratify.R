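#!/usr/bin/env Rscript
# Stage 5: where do the cluster-4 genes sit among all genes? TSS-anchored
# MBD2/Pol2 profiles at cluster-4 promoters, expression tertiles,
# H3K36me3 and methyl-CpG gene-body density tertiles, and the metagene
# profile over genes longer than 4 kb.

suppressMessages(library(mbdscape))

indir <- "results/data"
outdir <- "results/stratification"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

sizes <- read.table(file.path(indir, "chrom.sizes"),
                    col.names = c("chrom", "size"))
genes <- read_gene_table(file.path(indir, "genes.bed12"))
chrom_sizes <- setNames(sizes$size, sizes$chrom)
cpgs <- read_methcounts(file.path(indir, "methylome.methcounts.tsv"))
expr <- read.delim(file.path(indir, "expression_rpkm.tsv"))
c4_ids <- read.delim(file.path(indir, "cluster4_genes.tsv"))$gene_id
c4_genes <- genes[genes$gene_id %in% c4_ids, ]
mbd2 <- read_tags(file.path(indir, "tags_MBD2.bed"), "MBD2")
pol2 <- read_tags(file.path(indir, "tags_Pol2.bed"), "Pol2")
h36 <- read_tags(file.path(indir, "tags_H3K36me3.bed"), "H3K36me3")

tp_mbd2 <- tss_profile(mbd2, c4_genes, flank = 5000L, bin = 100L,
                       chrom_sizes = chrom_sizes)
tp_pol2 <- tss_profile(pol2, c4_genes, flank = 5000L, bin = 100L,
                       chrom_sizes = chrom_sizes)
write.table(cbind(mark = "MBD2", tp_mbd2$profile),
            file.path(outdir, "tss_profile_mbd2.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cbind(mark = "Pol2", tp_pol2$profile),
            file.path(outdir, "tss_profile_pol2.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

tiers_expr <- tertile_bins(expr$gene_id, expr$rpkm)
cmp_expr <- compare_subset_to_tiers(c4_ids, tiers_expr)
d_h36 <- genebody_density(h36, genes)
tiers_h36 <- tertile_bins(genes$gene_id, d_h36,
                          eligible = rep(TRUE, nrow(genes)))
cmp_h36 <- compare_subset_to_tiers(c4_ids, tiers_h36)
d_mcpg <- genebody_density(cpgs, genes)
tiers_mcpg <- tertile_bins(genes$gene_id, d_mcpg,
                           eligible = rep(TRUE, nrow(genes)))
cmp_mcpg <- compare_subset_to_tiers(c4_ids, tiers_mcpg)

write.table(tiers_expr, file.path(outdir, "expression_tiers.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(rbind(cbind(table = "rpkm", cmp_expr$summaries),
                  cbind(table = "h3k36me3", cmp_h36$summaries),
                  cbind(table = "mcpg_density", cmp_mcpg$summaries)),
            file.path(outdir, "cluster4_vs_tiers.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

mg <- metagene_profile(h36, c4_genes, anchor_flank = 2000L,
                       min_gene_length = 4000L,
                       chrom_sizes = chrom_sizes)
write.table(rbind(cbind(anchor = "TSS", mg$tss),
                  cbind(anchor = "TES", mg$tes)),
            file.path(outdir, "metagene_h3k36me3_cluster4.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("MBD2 TSS profile over %d cluster-4 promoters peaks %+d bp from the TSS\n",
            tp_mbd2$n_anchors, tp_mbd2$max_offset))
cat(sprintf("Pol2 peaks %+d bp (at the TSS itself)\n", tp_pol2$max_offset))
cat("Cluster-4 genes vs tertiles (nearest tier by median):\n")
cat(sprintf("  expression (RPKM):        %s\n", cmp_expr$nearest_tier))
cat(sprintf("  H3K36me3 gene-body tags:  %s\n", cmp_h36$nearest_tier))
cat(sprintf("  gene-body mCpG density:   %s\n", cmp_mcpg$nearest_tier))
cat(sprintf("Metagene used %d genes (>= 4 kb), excluded %d shorter ones\n",
            mg$n_used, mg$n_excluded))
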