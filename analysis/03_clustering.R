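#!/usr/bin/env Rscript
# Chromatin-landscape structure: Ward dendrogram over samples, k-means
# clustering of atlas peaks (OCR clusters), and 2-D embeddings; each
# compared against the generator's ground truth.

library(clonatlas)

out <- "results/clustering"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

norm <- read_counts("results/atlas/normalized.tsv")
truth <- read_truth("results/simulate/truth.json")
region_of <- unlist(truth$sample_region)

tree <- cluster_samples(norm)
cut <- cut_samples(tree, length(unique(region_of)))
ari_samples <- mclust::adjustedRandIndex(cut, region_of[names(cut)])

pc <- cluster_peaks(norm, k = 6, seed = 3, n_restarts = 10)
atlas <- read_narrowpeak("results/atlas/atlas.bed")  # BED4 reads fine
# match atlas peaks to truth peaks by overlap to score the clustering
tp <- truth$peak_clusters
tgr <- GenomicRanges::GRanges(tp$chrom, IRanges::IRanges(tp$start, tp$end))
ov <- GenomicRanges::findOverlaps(atlas, tgr)
tlab <- rep(NA_integer_, length(atlas))
tlab[S4Vectors::queryHits(ov)] <- tp$cluster[S4Vectors::subjectHits(ov)]
names(tlab) <- names(atlas)
ari_peaks <- mclust::adjustedRandIndex(pc$labels[names(tlab)], tlab)

emb <- embed_samples(norm, "pca")
sep <- region_separation(emb, region_of)

write.table(data.frame(sample_id = names(cut), branch = unname(cut),
                       region = region_of[names(cut)]),
            file.path(out, "sample_clusters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(peak_id = names(pc$labels),
                       cluster = unname(pc$labels),
                       truth_cluster = tlab[names(pc$labels)]),
            file.path(out, "peak_clusters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_matrix_tsv(emb, file.path(out, "embedding_pca.tsv"), "sample_id")

cat(sprintf("Sample dendrogram cut at %d regions: ARI %.3f vs truth\n",
            length(unique(region_of)), ari_samples),
    sprintf("Peak k-means (k = 6, best of 10 restarts, WCSS %.1f): ARI %.3f\n",
            pc$wcss, ari_peaks),
    sprintf("PCA separation by region: %s; most distinct: %s\n",
            paste(sprintf("%s=%.1f", names(sep), sep), collapse = " "),
            names(which.max(sep))))
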