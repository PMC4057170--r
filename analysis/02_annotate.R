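#!/usr/bin/env Rscript
# Stage 2: hierarchical genomic annotation of the binding sites
# (promoter > exon > intron > intergenic, each split CGI / non-CGI) and
# fold enrichment over a random set matched for length and for genomic
# distribution.

suppressMessages(library(mbdscape))

indir <- "results/data"
outdir <- "results/annotation"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

sizes <- read.table(file.path(indir, "chrom.sizes"),
                    col.names = c("chrom", "size"))
genome <- genome_annotation(setNames(sizes$size, sizes$chrom),
                            read_gene_table(file.path(indir, "genes.bed12")),
                            read_bed(file.path(indir, "cgis.bed")))
peaks <- read_bed(file.path(indir, "peaks.bed"))

obs <- annotate_sites(peaks, genome)
rnd_len <- sample_random_lengthmatched(peaks, genome, seed = 1L)
rnd_match <- sample_random_distributionmatched(peaks, genome, seed = 1L)
folds <- fold_over_random(obs, annotate_sites(rnd_len, genome))

write.table(obs, file.path(outdir, "category_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(folds, file.path(outdir, "fold_over_random.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_bed(rnd_match, file.path(outdir, "random_matched.bed"))

cat("Binding-site annotation (", attr(obs, "total"), "sites ):\n")
print(obs[c("category", "count", "percent")], row.names = FALSE)
cat("\nFold over length-matched random (binding is CGI-promoter biased):\n")
print(folds[c("category", "fold")], row.names = FALSE)
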