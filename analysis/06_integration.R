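#!/usr/bin/env Rscript
# "Actively regulated" genes: intersect the Dd2-preferential expression
# sets with the target genes of the Dd2-private OCR clusters. The planted
# coupling between DE genes and private-cluster targets is 0.7, so the
# recovered up-fraction should land near it.

library(clonatlas)

out <- "results/integration"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ann <- read.delim("results/annotation/annotation.tsv")
pk_cl <- read.delim("results/clustering/peak_clusters.tsv")
up <- readLines("results/de/preferential_up.txt")
down <- readLines("results/de/preferential_down.txt")

# the fitted k-means labels carrying the truth private clusters (1, 2)
tab <- table(pk_cl$truth_cluster, pk_cl$cluster)
fitted_private <- unique(apply(tab[c("1", "2"), , drop = FALSE], 1,
                               function(r) as.integer(colnames(tab)[which.max(r)])))
labels <- stats::setNames(pk_cl$cluster, pk_cl$peak_id)

targets <- cluster_targets(ann, labels, fitted_private)
rep_up <- active_regulation(up, targets, direction = "up")
rep_down <- active_regulation(down, targets, direction = "down")
jsonlite::write_json(list(up = rep_up, down = rep_down),
                     file.path(out, "active_regulation.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("Private-cluster target set: %d genes (fitted clusters %s)\n",
            length(targets), paste(fitted_private, collapse = ",")),
    sprintf("Actively upregulated: %d/%d Dd2-preferential genes (%.0f%%; planted coupling 70%%)\n",
            rep_up$n_targeted, rep_up$n_universe, 100 * rep_up$fraction),
    sprintf("Actively downregulated: %d/%d (%.0f%%)\n",
            rep_down$n_targeted, rep_down$n_universe,
            100 * ifelse(is.na(rep_down$fraction), 0, rep_down$fraction)))
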