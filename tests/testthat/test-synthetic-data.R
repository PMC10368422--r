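test_that("generate_genome honours its contract on edge and random cases", {
  # empty gene set
  g0 <- generate_genome(1, 10000, 0, seed = 1, with_sequence = FALSE)
  expect_equal(nrow(g0$genes), 0)
  expect_equal(unname(g0$chromosomes), 10000L)

  # determinism: same seed, byte-identical (genes and sequence)
  g1 <- generate_genome(2, 5e4, 20, seed = 9)
  g2 <- generate_genome(2, 5e4, 20, seed = 9)
  expect_identical(g1$genes, g2$genes)
  expect_identical(as.character(g1$sequence), as.character(g2$sequence))

  # exhaustive bound / invariant check on a larger draw
  g <- generate_genome(2, 1e6, 200, seed = 7, with_sequence = FALSE)
  expect_equal(nrow(g$genes), 200)
  for (i in seq_len(nrow(g$genes))) {
    row <- g$genes[i, ]
    expect_gte(row$start, 1)
    expect_lte(row$end, g$chromosomes[[row$chrom]])
    expect_identical(row$tss,
                     if (row$strand == "+") row$start else row$end)
  }
  expect_false(anyDuplicated(g$genes$gene_id) > 0)
  # genes on a shared chromosome never overlap
  for (chr in names(g$chromosomes)) {
    gg <- g$genes[g$genes$chrom == chr, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1)
      expect_true(all(gg$start[-1] > gg$end[-nrow(gg)]))
  }

  # infeasible density is an explicit error
  expect_error(generate_genome(1, 1000, 50, seed = 1),
               "density infeasible")
})

test_that("cohort generator plants recoverable structure deterministically", {
  sim <- small_cohort_fixture(seed = 11, n_fail = 0)
  sim2 <- small_cohort_fixture(seed = 11, n_fail = 0)
  expect_identical(sim$truth, sim2$truth)
  expect_identical(
    lapply(sim$cohort$samples, function(s) as.data.frame(s$fragments)),
    lapply(sim2$cohort$samples, function(s) as.data.frame(s$fragments)))

  # n_fail = 0: every sample passes at the generator's own thresholds
  qc <- qc_filter(sample_qc(sim$cohort),
                  min_fragments = sim$truth$qc_min_fragments,
                  min_frip = sim$truth$qc_min_frip)
  expect_true(all(qc$pass))

  # error paths
  regions <- data.frame(name = c("A", "B"), n_samples = c(2, 2))
  cmap <- list(A = 1, B = 1)
  expect_error(
    generate_cohort(sim$genome, regions, 1, cmap, n_fail = 4,
                    depth_range = c(2e4, 3e4), qc_min_fragments = 2e4),
    "n_fail")
  expect_error(
    generate_cohort(sim$genome, regions, 2, cmap,
                    depth_range = c(2e4, 3e4), qc_min_fragments = 2e4),
    "cover clusters")
})

test_that("realized FRiP of passing samples concentrates near the target", {
  # large genome so background fragments rarely land inside peaks
  genome <- generate_genome(1, 5e6, 50, seed = 3, with_sequence = FALSE)
  regions <- data.frame(name = c("A", "B"), n_samples = c(2, 2))
  cmap <- list(A = c(1, 3), B = c(2, 3))
  sim <- generate_cohort(genome, regions, 3, cmap,
                         depth_range = c(5e4, 6e4), frip_target = 0.4,
                         peaks_per_cluster = 20,
                         qc_min_fragments = 5e4, seed = 5)
  qc <- sample_qc(sim$cohort)
  expect_true(all(abs(qc$frip - 0.4) <= 0.05))
})

test_that("identical cluster maps leave no between-region structure", {
  genome <- generate_genome(1, 1e6, 50, seed = 2, with_sequence = FALSE)
  regions <- data.frame(name = c("A", "B", "C"), n_samples = c(4, 4, 4))
  cmap <- list(A = 1:4, B = 1:4, C = 1:4)   # same clusters everywhere
  sim <- generate_cohort(genome, regions, 4, cmap,
                         depth_range = c(2e4, 3e4),
                         qc_min_fragments = 2e4, seed = 8)
  at <- build_atlas(sim$cohort,
                    qc_filter(sample_qc(sim$cohort), 2e4, 0.2),
                    chromosomes = genome$chromosomes)
  d <- dist(t(at$normalized))
  sil <- cluster::silhouette(
    as.integer(factor(sim$truth$sample_region[colnames(at$normalized)])), d)
  expect_lt(abs(mean(sil[, "sil_width"])), 0.1)
})

test_that("the distinct region's private peaks appear only in its samples", {
  sim <- small_cohort_fixture(seed = 21, n_fail = 0)
  truth <- sim$truth
  private <- setdiff(truth$cluster_region_map[[truth$distinct_region]],
                     unlist(truth$cluster_region_map[
                       setdiff(names(truth$cluster_region_map),
                               truth$distinct_region)]))
  expect_length(private, 2)
  pp <- truth$peak_clusters[truth$peak_clusters$cluster %in% private, ]
  for (sid in names(sim$cohort$samples)) {
    pk <- sim$cohort$samples[[sid]]$peaks
    # exhaustive scan: any sample peak overlapping any private truth peak?
    hit <- FALSE
    for (i in seq_len(nrow(pp))) {
      same <- as.character(GenomicRanges::seqnames(pk)) == pp$chrom[i]
      if (any(same &
              GenomicRanges::start(pk) <= pp$end[i] &
              GenomicRanges::end(pk) >= pp$start[i])) { hit <- TRUE; break }
    }
    in_distinct <- truth$sample_region[[sid]] == truth$distinct_region
    expect_identical(hit, in_distinct)
  }
})

test_that("expression generator matches its NB parameterisation", {
  genome <- generate_genome(1, 3e5, 60, seed = 4, with_sequence = FALSE)

  # lfc = 0 plants nothing
  ex0 <- generate_expression(genome, conditions = c("A", "B"), n_de = 10,
                             lfc = 0, dispersion = 0.1, seed = 1)
  expect_equal(nrow(ex0$truth), 0)

  # determinism
  ex1 <- generate_expression(genome, seed = 6)
  ex2 <- generate_expression(genome, seed = 6)
  expect_identical(ex1$counts, ex2$counts)

  # near-zero dispersion, high depth: planted mean ratio approaches 2^lfc
  exl <- generate_expression(genome, conditions = c("A", "B"), n_de = 10,
                             lfc = 2, dispersion = 1e-3, n_reps = 30,
                             base_mean_meanlog = log(3000),
                             base_mean_sdlog = 0, seed = 12)
  isA <- exl$samples$condition == "A"
  up <- exl$truth$gene_id[exl$truth$sign == 1]
  ratios <- rowMeans(exl$counts[up, isA, drop = FALSE]) /
    rowMeans(exl$counts[up, !isA, drop = FALSE])
  expect_true(all(abs(ratios / 4 - 1) < 0.05))

  # argument validation
  expect_error(generate_expression(genome, dispersion = 0), "dispersion")
  expect_error(generate_expression(genome, depth = -1), "depth")
  expect_error(generate_expression(genome, n_reps = 1), "n_reps")
})

test_that("motif planting writes the consensus exactly where it claims", {
  genome <- generate_genome(1, 2e5, 20, seed = 5)
  regions <- data.frame(name = "A", n_samples = 2)
  sim <- generate_cohort(genome, regions, 2, list(A = 1:2),
                         depth_range = c(2e4, 3e4), peaks_per_cluster = 10,
                         qc_min_fragments = 2e4, seed = 5)
  pwm <- consensus_pwm("TGACGTCATG")

  # prob = 0: byte-identical genome
  pl0 <- plant_motifs(genome, sim$truth$peak_clusters, pwm, clusters = 1,
                      prob = 0, seed = 1)
  expect_identical(as.character(pl0$genome$sequence),
                   as.character(genome$sequence))

  # prob = 1, offset_sd = 0: every target peak's centre carries the
  # consensus; non-target peaks untouched (exhaustive string scan)
  pl1 <- plant_motifs(genome, sim$truth$peak_clusters, pwm, clusters = 1,
                      prob = 1, offset_sd = 0, seed = 1)
  seqs <- peak_sequences(pl1$genome, sim$truth$peak_clusters)
  for (i in seq_len(nrow(sim$truth$peak_clusters))) {
    row <- sim$truth$peak_clusters[i, ]
    has <- grepl("TGACGTCATG", seqs[[row$peak_id]], fixed = TRUE)
    expect_identical(has, row$cluster == 1)
    if (row$cluster == 1) {
      centre_win <- substr(seqs[[row$peak_id]],
                           (row$end - row$start + 1) %/% 2 - 10,
                           (row$end - row$start + 1) %/% 2 + 11)
      expect_true(grepl("TGACGTCATG", centre_win, fixed = TRUE))
    }
  }
  expect_true(all(pl1$truth$planted[pl1$truth$cluster == 1]))
})

test_that("truth records and cohorts round-trip through their file formats", {
  sim <- small_cohort_fixture(seed = 31)
  tmp <- withr::local_tempdir()

  write_truth(sim$truth, file.path(tmp, "truth.json"))
  back <- read_truth(file.path(tmp, "truth.json"))
  expect_equal(unlist(back$sample_region), unlist(sim$truth$sample_region))
  expect_equal(back$peak_clusters$cluster, sim$truth$peak_clusters$cluster)
  expect_equal(back$fail_samples$sample_id, sim$truth$fail_samples$sample_id)

  write_cohort(sim$cohort, tmp)
  back_c <- read_cohort(tmp)
  s1 <- names(sim$cohort$samples)[1]
  expect_equal(
    GenomicRanges::start(back_c$samples[[s1]]$fragments),
    GenomicRanges::start(sim$cohort$samples[[s1]]$fragments))
  expect_equal(
    names(back_c$samples[[s1]]$peaks),
    names(sim$cohort$samples[[s1]]$peaks))

  g <- sim$genome
  write_genome(g, tmp)
  gb <- read_genome(file.path(tmp, "genome.chrom.sizes"),
                    file.path(tmp, "genes.gff3"))
  expect_equal(gb$chromosomes, g$chromosomes)
  expect_equal(gb$genes[order(gb$genes$gene_id), c("gene_id", "tss")],
               g$genes[order(g$genes$gene_id), c("gene_id", "tss")],
               ignore_attr = TRUE)
})
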