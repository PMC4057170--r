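#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data at the default configuration
# (seed 42) and write every input in its on-disk dialect, so the later
# stages consume files exactly as a real analysis would.

suppressMessages(library(mbdscape))

outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config()  # 2 x 5 Mb genome, 300 genes, 150 binding sites
ds <- simulate_dataset(cfg)

write_bed(ds$truth$peaks, file.path(outdir, "peaks.bed"))
write.table(ds$truth$peaks[c("name", "class")],
            file.path(outdir, "peak_classes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_gene_table(ds$genome$genes, file.path(outdir, "genes.bed12"))
write_bed(ds$genome$cgis[c("chrom", "start", "end", "name", "score",
                           "strand")],
          file.path(outdir, "cgis.bed"))
write.table(data.frame(chrom = names(ds$genome$chrom_sizes),
                       size = unname(ds$genome$chrom_sizes)),
            file.path(outdir, "chrom.sizes"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
write_methcounts(ds$methylome, file.path(outdir, "methylome.methcounts.tsv"))
for (nm in names(ds$tracks)) {
  write_tags(ds$tracks[[nm]], file.path(outdir, paste0("tags_", nm, ".bed")))
}
write.table(ds$expression, file.path(outdir, "expression_rpkm.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ds$truth$cluster4_genes,
            file.path(outdir, "cluster4_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_cohort_matrix(ds$cohort$sites, file.path(outdir, "cohort_sites.tsv"))
write_cohort_matrix(ds$cohort$random, file.path(outdir, "cohort_random.tsv"))

cat("Simulated dataset at seed", cfg$seed, "\n")
cat(" genes:", nrow(ds$genome$genes),
    "| CGIs:", nrow(ds$genome$cgis),
    "| CpGs:", nrow(ds$methylome), "\n")
cat(" binding sites by class:\n")
print(table(ds$truth$peaks$class))
cat(" tag tracks:", paste(names(ds$tracks), collapse = ", "), "\n")
cat(" cohort:", sum(ds$cohort$sites$groups == "tumor"), "tumor /",
    sum(ds$cohort$sites$groups == "normal"), "normal samples\n")
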