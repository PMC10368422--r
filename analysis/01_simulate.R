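#!/usr/bin/env Rscript
# Simulate the study-shaped synthetic cohort all later steps analyse:
# a random genome; 4 brain-region groups of micro-dissected samples over 6
# planted open-chromatin clusters, the "Dd2" region carrying 2 private
# clusters closed everywhere else; planted QC failures; a 3-condition
# RNA-seq design whose planted DE genes are coupled (c = 0.7) to the
# private clusters; one PWM planted into cluster 1.
#
# Everything is written as plain text (BED / narrowPeak / GFF3 / FASTA /
# TSV / JSON) under results/simulate so each later script can reload it.

library(clonatlas)

seed <- 1
out <- "results/simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- generate_genome(n_chrom = 2, chrom_length = 4e5, n_genes = 240,
                          seed = seed, gene_length = 800)
regions <- data.frame(name = c("Dd2", "Dm", "Dl", "Vv"),
                      n_samples = c(3, 3, 3, 3))
cmap <- design_cluster_map(regions$name, n_clusters = 6,
                           distinct_region = "Dd2", n_private = 2)
sim <- generate_cohort(genome, regions, n_clusters = 6, cmap,
                       distinct_region = "Dd2",
                       depth_range = c(2e4, 4e4), n_fail = 2,
                       frip_target = 0.4, peaks_per_cluster = 25,
                       qc_min_fragments = 2e4, seed = seed)

pwms <- stats::setNames(
  lapply(c("TGACGTCATG", "CACGTGACTT", "GGGATTACAG", "TTGCCCAAGG"),
         function(s) consensus_pwm(s, p = 0.97)),
  c("TGACGTCATG", "CACGTGACTT", "GGGATTACAG", "TTGCCCAAGG"))
pl <- plant_motifs(genome, sim$truth$peak_clusters, pwms[[1]],
                   clusters = 1, prob = 0.8, offset_sd = 0, seed = seed)
genome <- pl$genome
sim$truth$motif <- list(motif = names(pwms)[1], cluster = 1)

planted <- couple_de_to_clusters(genome, sim$truth$peak_clusters,
                                 clusters = 1:2, n = 60, coupling = 0.7,
                                 seed = seed)
expr <- generate_expression(genome, conditions = c("Dd2", "D", "V"),
                            lfc = 2, dispersion = 0.05, n_reps = 2,
                            planted = planted, seed = seed)
sim$truth$de <- expr$truth

write_genome(genome, out)
write_cohort(sim$cohort, out)
write_counts(expr$counts, file.path(out, "counts.tsv"))
write.table(expr$samples, file.path(out, "rna_samples.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_truth(sim$truth, file.path(out, "truth.json"))

cat(sprintf("Simulated %d samples over %d regions (%d planted QC failures),\n",
            sum(regions$n_samples), nrow(regions),
            nrow(sim$truth$fail_samples)),
    sprintf("%d truth peaks in 6 clusters, %d planted DE genes, motif %s\n",
            nrow(sim$truth$peak_clusters), nrow(expr$truth), names(pwms)[1]),
    sprintf("planted in cluster 1 at prob 0.8. Outputs under %s/\n", out))
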