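#!/usr/bin/env Rscript
# Sample quality gate and consensus peak atlas.
#
# Applies the two-part QC rule (minimum mapped fragments AND minimum
# fraction of reads in peaks, both inclusive) at the thresholds the cohort
# was simulated against, merges the passing samples' peak calls into the
# non-overlapping atlas, counts fragments per atlas peak per sample, and
# normalizes each peak row to a cross-sample mean of 1.

library(clonatlas)

sim_dir <- "results/simulate"
out <- "results/atlas"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- read_cohort(sim_dir)
genome <- read_genome(file.path(sim_dir, "genome.chrom.sizes"),
                      file.path(sim_dir, "genes.gff3"))
truth <- read_truth(file.path(sim_dir, "truth.json"))

qc <- qc_filter(sample_qc(cohort), min_fragments = 2e4, min_frip = 0.2)
write.table(qc, file.path(out, "qc.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

planted_fail <- truth$fail_samples$sample_id
cat(sprintf("QC: %d/%d samples pass; failing set {%s} %s the planted set\n",
            sum(qc$pass), nrow(qc),
            paste(qc$sample_id[!qc$pass], collapse = ","),
            if (setequal(qc$sample_id[!qc$pass], planted_fail))
              "exactly matches" else "DIFFERS FROM"))

at <- build_atlas(cohort, qc, chromosomes = genome$chromosomes)
write_atlas_bed(at$atlas, file.path(out, "atlas.bed"))
write_matrix_tsv(at$raw, file.path(out, "raw_counts.tsv"), "peak_id")
write_matrix_tsv(at$normalized, file.path(out, "normalized.tsv"), "peak_id")

cat(sprintf("Atlas: %d merged peaks from %d samples (truth: %d peaks);\n",
            length(at$atlas), sum(qc$pass), nrow(truth$peak_clusters)),
    sprintf("max |row mean - 1| of the normalized matrix: %.2e\n",
            max(abs(rowMeans(at$normalized) - 1))))
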