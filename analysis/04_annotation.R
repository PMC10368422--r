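#!/usr/bin/env Rscript
# Peak-to-gene annotation: nearest-TSS target assignment (strictly < 10 kb
# from the peak midpoint) and genomic-context classification, summarised
# per OCR cluster.

library(clonatlas)

out <- "results/annotation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- read_genome("results/simulate/genome.chrom.sizes",
                      "results/simulate/genes.gff3")
atlas <- read_narrowpeak("results/atlas/atlas.bed")
pk_cl <- read.delim("results/clustering/peak_clusters.tsv")
labels <- stats::setNames(pk_cl$cluster, pk_cl$peak_id)

ann <- assign_targets(atlas, genome)
ctx <- classify_context(atlas, genome)
merged <- merge(ann, ctx, by = "peak_id")
write.table(merged, file.path(out, "annotation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

prof <- cluster_context_profile(ctx, labels)
write_matrix_tsv(prof, file.path(out, "cluster_context.tsv"), "cluster")

cat(sprintf("Targets: %d/%d atlas peaks assigned a gene (median TSS distance %d bp)\n",
            sum(!is.na(ann$target_gene)), nrow(ann),
            as.integer(median(ann$tss_distance, na.rm = TRUE))),
    sprintf("Context mix over all peaks: %s\n",
            paste(sprintf("%s %.0f%%", colnames(prof),
                          100 * colMeans(prof)), collapse = ", ")))
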