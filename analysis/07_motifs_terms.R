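#!/usr/bin/env Rscript
# Regulatory sequence analysis: per-cluster known-motif enrichment against
# the rest of the atlas, the planted motif's positional density profile,
# and term over-representation of the Dd2-preferential genes.

library(clonatlas)

out <- "results/motifs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- read_genome("results/simulate/genome.chrom.sizes",
                      "results/simulate/genes.gff3",
                      "results/simulate/genome.fa")
truth <- read_truth("results/simulate/truth.json")
tp <- truth$peak_clusters

pwms <- stats::setNames(
  lapply(c("TGACGTCATG", "CACGTGACTT", "GGGATTACAG", "TTGCCCAAGG"),
         function(s) consensus_pwm(s, p = 0.97)),
  c("TGACGTCATG", "CACGTGACTT", "GGGATTACAG", "TTGCCCAAGG"))

labels <- stats::setNames(tp$cluster, tp$peak_id)
tab <- cluster_motif_enrichment(genome, tp, labels, pwms)
write.table(tab, file.path(out, "motif_enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

c_planted <- tab[tab$cluster == truth$motif$cluster, ]
cat(sprintf("Cluster %d top motif: %s (p = %.2e, %.0f%% of targets)%s\n",
            truth$motif$cluster, c_planted$motif[which.min(c_planted$p)],
            min(c_planted$p), c_planted$percent_target[which.min(c_planted$p)],
            if (c_planted$motif[which.min(c_planted$p)] == truth$motif$motif)
              " - the planted motif" else ""))

prof <- density_profile(genome, tp[tp$cluster == truth$motif$cluster, ],
                        pwms[[truth$motif$motif]])
write.table(prof, file.path(out, "motif_density.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Density profile argmax at offset %d bp (planted at the centre)\n",
            prof$offset[which.max(prof$density)]))

# term over-representation of the preferential set
de <- read.delim("results/de/de_Dd2_vs_D.tsv")
universe <- de$gene_id[!is.na(de$padj)]
study <- intersect(readLines("results/de/preferential_up.txt"), universe)
tm <- generate_terms(universe, n_terms = 15, term_size = 25,
                     planted_study = study, seed = 7)
write_gmt(tm$terms, file.path(out, "terms.gmt"))
res <- ora(study, universe, tm$terms)
write.table(res, file.path(out, "ora.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("ORA: top term %s (fold enrichment %.1f, FDR %.1e)%s\n",
            res$term[1], res$fold_enrichment[1], res$fdr[1],
            if (res$term[1] == "planted_term") " - the planted term" else ""))
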