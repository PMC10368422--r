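make_genome <- function(genes, L = 1e6, exons = NULL) {
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genome_model(c(chr1 = L), genes, exons = exons)
}

test_that("nearest-TSS assignment is strict at the 10 kb boundary", {
  g <- make_genome(data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1", strand = "+",
    start = c(50000, 500000), end = c(51000, 501000)))
  # midpoints 40001 / 40000 / 50000: distances to gA's TSS 9999 / 10000 / 0
  pk <- gr("chr1", c(39801, 39800, 49800), c(40201, 40200, 50200),
           names = c("at9999", "at10000", "at0"))
  ann <- assign_targets(pk, g)
  expect_equal(ann$target_gene, c("gA", NA, "gA"))
  expect_equal(ann$tss_distance, c(9999L, NA, 0L))
})

test_that("equidistant ties break to the lexicographically smaller gene", {
  g <- make_genome(data.frame(
    gene_id = c("gB", "gA"), chrom = "chr1", strand = c("+", "-"),
    start = c(60000, 39000), end = c(61000, 40000)))
  # midpoint 50000: both TSS 10,000 away -> outside; move closer
  pk <- gr("chr1", 49800, 50199, names = "mid")   # midpoint 49999
  # distances: gB 10001 (no), gA 9999 -> gA; now a true tie:
  g2 <- make_genome(data.frame(
    gene_id = c("gB", "gA"), chrom = "chr1", strand = c("+", "-"),
    start = c(50999, 48000), end = c(52000, 48999)))
  ann <- assign_targets(gr("chr1", 49800, 50199, names = "m"), g2)
  expect_equal(ann$target_gene, "gA")   # both at distance 1000
  expect_equal(ann$tss_distance, 1000L)
})

test_that("assignment equals the exhaustive all-TSS minimum on random genomes", {
  set.seed(301)
  for (rep in 1:20) {
    genome <- generate_genome(2, 1e5, 30, seed = 300 + rep,
                              with_sequence = FALSE)
    ps <- sample.int(99000, 25)
    pk <- gr(sample(names(genome$chromosomes), 25, TRUE), ps, ps + 400,
             names = sprintf("pk%02d", 1:25))
    ann <- assign_targets(pk, genome)
    for (i in seq_len(25)) {
      mid <- floor((ps[i] + ps[i] + 400) / 2)
      o <- oracle_nearest_tss(mid,
                              as.character(GenomicRanges::seqnames(pk))[i],
                              genome$genes)
      expect_identical(ann$target_gene[i], o$gene)
      expect_identical(ann$tss_distance[i], o$dist)
    }
  }
})

test_that("assignment is invariant under coordinate translation", {
  genome <- generate_genome(1, 1e5, 20, seed = 33, with_sequence = FALSE)
  ps <- sample.int(8e4, 10)
  pk <- gr("chr1", ps, ps + 300, names = sprintf("p%d", 1:10))
  ann1 <- assign_targets(pk, genome)

  shift <- 5000L
  g2 <- genome
  g2$chromosomes["chr1"] <- g2$chromosomes["chr1"] + shift
  g2$genes$start <- g2$genes$start + shift
  g2$genes$end <- g2$genes$end + shift
  g2$genes$tss <- g2$genes$tss + shift
  pk2 <- gr("chr1", ps + shift, ps + 300 + shift,
            names = sprintf("p%d", 1:10))
  ann2 <- assign_targets(pk2, g2)
  expect_identical(ann1$target_gene, ann2$target_gene)
  expect_identical(ann1$tss_distance, ann2$tss_distance)
})

test_that("edge-anchored distance is zero for TSS inside the peak", {
  g <- make_genome(data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                              start = 5000, end = 6000))
  pk <- gr("chr1", 4500, 5500, names = "spanning")
  expect_equal(assign_targets(pk, g, anchor = "edge")$tss_distance, 0L)
  expect_equal(assign_targets(pk, g, anchor = "midpoint")$tss_distance, 0L)
})

test_that("context classification follows promoter > exon > intron > intergenic", {
  exons <- data.frame(gene_id = "g1", chrom = "chr1",
                      start = c(10000, 14000), end = c(11000, 15000))
  g <- make_genome(data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                              start = 10000, end = 15000), exons = exons)
  pk <- gr("chr1",
           c(9400, 10300, 12300, 50000, 9950),
           c(9600, 10500, 12500, 50400, 10050),
           names = c("prom", "exon", "intron", "inter", "tss_window"))
  ctx <- classify_context(pk, g)
  expect_equal(as.character(ctx$context),
               c("promoter", "exon", "intron", "intergenic", "promoter"))

  # without exon models a gene body is one exon: intron cannot occur
  g_noex <- make_genome(data.frame(gene_id = "g1", chrom = "chr1",
                                   strand = "+", start = 10000, end = 15000))
  ctx2 <- classify_context(gr("chr1", 12300, 12500), g_noex)
  expect_equal(as.character(ctx2$context), "exon")
})

test_that("context labels match a brute-force classifier on random genomes", {
  set.seed(302)
  for (rep in 1:8) {
    genome <- generate_genome(1, 5e4, 12, seed = 310 + rep,
                              gene_length = 2000, exons_per_gene = 3,
                              with_sequence = FALSE)
    ps <- sample.int(49000, 40)
    pk <- gr("chr1", ps, pmin(ps + 200, 5e4), names = sprintf("q%02d", 1:40))
    ctx <- classify_context(pk, genome, promoter_window = 500)

    gg <- genome$genes; ex <- genome$exons
    for (i in seq_len(40)) {
      mid <- floor((GenomicRanges::start(pk)[i] +
                      GenomicRanges::end(pk)[i]) / 2)
      in_prom <- any(ifelse(gg$strand == "+",
                            mid >= gg$tss - 500 & mid <= gg$tss,
                            mid >= gg$tss & mid <= gg$tss + 500))
      in_exon <- any(mid >= ex$start & mid <= ex$end)
      in_body <- any(mid >= gg$start & mid <= gg$end)
      want <- if (in_prom) "promoter" else if (in_exon) "exon"
      else if (in_body) "intron" else "intergenic"
      expect_identical(as.character(ctx$context)[i], want)
    }
  }
})

test_that("cluster context profiles are proper distributions", {
  ctx <- data.frame(
    peak_id = sprintf("p%d", 1:6),
    context = factor(c("intron", "intron", "intergenic", "intergenic",
                       "promoter", "promoter"),
                     levels = c("promoter", "exon", "intron", "intergenic")))
  labels <- stats::setNames(c(1, 1, 1, 1, 2, 2), ctx$peak_id)
  prof <- cluster_context_profile(ctx, labels)
  expect_equal(unname(prof["1", ]), c(0, 0, 0.5, 0.5))
  expect_equal(unname(prof["2", ]), c(1, 0, 0, 0))
  expect_equal(unname(rowSums(prof)), c(1, 1), tolerance = 1e-12)

  # empty cluster: zero row with a warning
  labels2 <- stats::setNames(c(1, 1, 1, 1, 2, 2),
                             c(ctx$peak_id[1:4], "x5", "x6"))
  expect_warning(prof2 <- cluster_context_profile(ctx, labels2),
                 "cluster 2 has no annotated peaks")
  expect_equal(unname(rowSums(prof2)), c(1, 0))
})
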