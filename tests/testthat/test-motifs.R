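test_that("log-odds scoring and strand handling are exact", {
  pwm <- consensus_pwm("ACGTAC")   # deterministic columns, uniform bg

  # consensus scores 2 bits per position
  hits <- scan_pwm("ACGTAC", pwm)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$score, 12)
  expect_equal(max_score(pwm), 12)

  # reverse complement of a hit-bearing sequence has the same hit count
  s <- "TTTACGTACTTTTTT"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(nrow(scan_pwm(s, pwm)), nrow(scan_pwm(rc, pwm)))

  # motif longer than the sequence: zero hits, no error
  expect_equal(nrow(scan_pwm("ACG", pwm)), 0)

  # N scores as background: a single N drops the score by 2 bits
  h <- scan_pwm("ACGNAC", pwm, threshold = 9)
  expect_equal(h$score, 10)
})

test_that("vectorised scanning equals a position-by-position oracle", {
  set.seed(601)
  pwm <- consensus_pwm("TGACGTCA", p = 0.9)
  for (rep in 1:6) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    # plant one instance so the hit set is non-trivial
    pos <- sample(50:150, 1)
    substr(s, pos, pos + 7) <- "TGACGTCA"
    got <- scan_pwm(s, pwm)
    want <- oracle_scan(s, pwm)
    expect_equal(got[, c("start", "strand")], want, ignore_attr = TRUE)
  }
})

test_that("PWM text formats parse to proper probability matrices", {
  tmp <- withr::local_tempdir()
  jaspar <- file.path(tmp, "m.jaspar")
  writeLines(c(
    ">MA0001.1 FooTF",
    "A [ 10  0  0 20 ]",
    "C [  0 20  0  0 ]",
    "G [  0  0 20  0 ]",
    "T [ 10  0  0  0 ]"), jaspar)
  pj <- read_jaspar(jaspar)
  expect_named(pj, "FooTF")
  expect_equal(unname(pj$FooTF$matrix[1, ]), c(0.5, 0, 0, 0.5))
  expect_equal(consensus(pj$FooTF), "ACGA")
  expect_lt(max(abs(rowSums(pj$FooTF$matrix) - 1)), 1e-9)

  meme <- file.path(tmp, "m.meme")
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "MOTIF BarTF", "",
    "letter-probability matrix: alength= 4 w= 3 nsites= 20",
    " 0.25 0.25 0.25 0.25",
    " 1.0 0.0 0.0 0.0",
    " 0.0 0.0 0.0 1.0"), meme)
  pm <- read_meme(meme)
  expect_named(pm, "BarTF")
  expect_equal(nrow(pm$BarTF$matrix), 3)
  expect_equal(unname(pm$BarTF$matrix[2, 1]), 1)

  # invariant enforcement
  expect_error(motif_pwm(matrix(c(0.5, 0.2, 0.1, 0.1), 1), "bad"),
               "sum to 1")
})

test_that("enrichment p-values are the exact hypergeometric tail", {
  # 10/10 target vs 0/90 background, all carrying vs none
  pwm <- consensus_pwm("TGACGTCATG")
  set.seed(602)
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
  tgt <- vapply(1:10, function(i) {
    s <- rand_seq(100); substr(s, 40, 49) <- "TGACGTCATG"; s
  }, character(1))
  bg <- vapply(1:90, function(i) rand_seq(100), character(1))
  names(tgt) <- paste0("t", 1:10); names(bg) <- paste0("b", 1:90)
  tab <- motif_enrichment(tgt, bg, list(pwm))
  k <- tab$target_hits; K <- tab$target_hits + tab$bg_hits
  expect_equal(tab$target_hits, 10)
  expect_equal(tab$p, oracle_hyper(k, K, 10, 100), tolerance = 1e-12)
  expect_equal(tab$percent_target, 100)
  expect_error(motif_enrichment(character(0), bg, list(pwm)),
               "empty target")
})

test_that("identical target and background composition is a null", {
  set.seed(603)
  pwms <- lapply(c("TGACGTCA", "CACGTGAC", "GGGATTAC"), consensus_pwm)
  names(pwms) <- vapply(pwms, function(p) p$name, character(1))
  flagged <- vapply(1:10, function(rep) {
    seqs <- vapply(1:60, function(i)
      paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = ""),
      character(1))
    names(seqs) <- paste0("s", 1:60)
    tab <- motif_enrichment(seqs[1:20], seqs[21:60], pwms)
    any(tab$padj < 0.05)
  }, logical(1))
  expect_lte(mean(flagged), 0.05)
})

test_that("share matrices are exact set intersections", {
  A <- list(c1 = c("A", "B", "C"), c2 = c("D"))
  B <- list(r1 = c("B", "C", "D"), r2 = c("X"))
  m <- share_matrix(A, B)
  expect_equal(m["c1", "r1"], 2L)
  expect_equal(m["c2", "r1"], 1L)
  expect_equal(m["c2", "r2"], 0L)

  # transpose symmetry
  expect_identical(t(share_matrix(A, B)), share_matrix(B, A))

  # random sets vs exhaustive double loop
  set.seed(604)
  uni <- sprintf("m%02d", 1:30)
  A2 <- lapply(1:4, function(i) sample(uni, sample(3:12, 1)))
  names(A2) <- paste0("a", 1:4)
  B2 <- lapply(1:3, function(i) sample(uni, sample(3:12, 1)))
  names(B2) <- paste0("b", 1:3)
  m2 <- share_matrix(A2, B2)
  for (i in 1:4) for (j in 1:3) {
    cnt <- 0L
    for (x in A2[[i]]) if (x %in% B2[[j]]) cnt <- cnt + 1L
    expect_equal(m2[i, j], cnt)
  }
})

test_that("density profiles locate planted motifs and conserve mass", {
  genome <- generate_genome(1, 3e5, 10, seed = 61)
  regions <- data.frame(name = "A", n_samples = 2)
  sim <- generate_cohort(genome, regions, 2, list(A = 1:2),
                         depth_range = c(2e4, 3e4), peaks_per_cluster = 15,
                         qc_min_fragments = 2e4, seed = 62)
  pwm <- consensus_pwm("TGACGTCATG")
  pl <- plant_motifs(genome, sim$truth$peak_clusters, pwm, clusters = 1,
                     prob = 1, offset_sd = 0, seed = 63)
  pk1 <- sim$truth$peak_clusters[sim$truth$peak_clusters$cluster == 1, ]
  # keep peaks whose full window fits the chromosome so no bin is truncated
  ctr <- floor((pk1$start + pk1$end) / 2)
  pk1 <- pk1[ctr > 1000 & ctr < genome$chromosomes[[1]] - 1000, ]
  prof <- density_profile(pl$genome, pk1, pwm, window = 2000, bin = 20)

  # hits concentrate in the central bin (offset_sd = 0)
  centre_bin <- which(prof$offset == -20 | prof$offset == 0)
  expect_true(which.max(prof$density) %in% centre_bin)

  # summed density equals total hits per peak
  expect_true(all(prof$n_peaks == nrow(pk1)))
  expect_equal(sum(prof$density), sum(prof$hits) / nrow(pk1))

  # no planted motif, high threshold: all-zero profile
  pwm_absent <- consensus_pwm("AAAAACCCCCGGGGG")
  prof0 <- density_profile(genome, pk1, pwm_absent)
  expect_true(all(prof0$density == 0))

  # window must be an even multiple of bin
  expect_error(density_profile(genome, pk1, pwm, window = 1990, bin = 20),
               "even multiple")
})

test_that("a planted motif is the top-ranked enrichment for its cluster", {
  genome <- generate_genome(1, 4e5, 10, seed = 64)
  regions <- data.frame(name = c("A", "B"), n_samples = c(2, 2))
  cmap <- list(A = c(1, 3), B = c(2, 3))
  sim <- generate_cohort(genome, regions, 3, cmap,
                         depth_range = c(2e4, 3e4), peaks_per_cluster = 12,
                         qc_min_fragments = 2e4, seed = 65)
  pwms <- lapply(c("TGACGTCATG", "CACGTGACTT", "GGGATTACAG"), consensus_pwm)
  names(pwms) <- vapply(pwms, function(p) p$name, character(1))
  pl <- plant_motifs(genome, sim$truth$peak_clusters, pwms[[1]],
                     clusters = 1, prob = 0.8, seed = 66)
  labels <- stats::setNames(sim$truth$peak_clusters$cluster,
                            sim$truth$peak_clusters$peak_id)
  tab <- cluster_motif_enrichment(pl$genome, sim$truth$peak_clusters,
                                  labels, pwms)
  c1 <- tab[tab$cluster == 1, ]
  expect_equal(c1$motif[which.min(c1$p)], pwms[[1]]$name)
  other <- tab[tab$cluster != 1, ]
  expect_true(all(other$padj[other$motif == pwms[[1]]$name] >= 0.05))
})
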