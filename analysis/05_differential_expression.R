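#!/usr/bin/env Rscript
# Region-level differential expression: the Dd2-versus-rest-of-pallium
# contrast with the negative binomial Wald test, gated at padj < 0.05,
# scored against the planted truth.

library(clonatlas)

out <- "results/de"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read_counts("results/simulate/counts.tsv")
samples <- read.delim("results/simulate/rna_samples.tsv")
truth <- read_truth("results/simulate/truth.json")

de <- run_contrast(counts, samples, c("Dd2", "D"))
write.table(de, file.path(out, "de_Dd2_vs_D.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

pref <- preferential_sets(de)
writeLines(pref$up, file.path(out, "preferential_up.txt"))
writeLines(pref$down, file.path(out, "preferential_down.txt"))

planted_up <- truth$de$gene_id[truth$de$sign == 1]
cat(sprintf("Dd2 vs D: %d genes significant (padj < 0.05) of %d tested\n",
            sum(de$significant), sum(!is.na(de$padj))),
    sprintf("%d preferentially up in Dd2; %d/%d planted up-genes recovered\n",
            length(pref$up), length(intersect(pref$up, planted_up)),
            length(planted_up)),
    sprintf("median |log2FC error| on planted genes: %.2f\n",
            median(abs(abs(de$log2fc[match(truth$de$gene_id, de$gene_id)]) -
                         truth$de$lfc), na.rm = TRUE)))
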