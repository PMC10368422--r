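test_that("merge_peaks is the transitive overlap closure", {
  # pairwise union
  m <- merge_peaks(list(gr("chr1", 10, 19), gr("chr1", 15, 29)))
  expect_equal(GenomicRanges::start(m), 10)
  expect_equal(GenomicRanges::end(m), 29)

  # disjoint peaks unchanged
  m2 <- merge_peaks(gr("chr1", c(10, 30), c(19, 39)))
  expect_length(m2, 2)

  # overlap chain collapses end to end
  m3 <- merge_peaks(gr("chr1", c(1, 10, 20), c(10, 20, 30)))
  expect_length(m3, 1)
  expect_equal(GenomicRanges::width(m3), 30)

  # empty input: empty atlas with a warning
  expect_warning(m0 <- merge_peaks(list()), "no input peaks")
  expect_length(m0, 0)

  # idempotence: merging the atlas with itself returns the atlas
  sets <- list(gr("chr1", c(5, 50, 200), c(30, 90, 260)),
               gr("chr1", c(25, 85), c(60, 120)))
  atlas <- merge_peaks(sets)
  again <- merge_peaks(list(atlas, atlas))
  expect_equal(as.data.frame(again)[1:3], as.data.frame(atlas)[1:3])
})

test_that("merged atlas equals the per-base boolean union on random input", {
  set.seed(201)
  for (rep in 1:25) {
    L <- 10000
    np <- sample(2:12, 1)
    s <- sample.int(L - 400, np); e <- pmin(s + sample(20:400, np, TRUE), L)
    m <- merge_peaks(gr("chr1", s, e))
    o <- oracle_union(s, e, L)
    expect_equal(GenomicRanges::start(m), o$start)
    expect_equal(GenomicRanges::end(m), o$end)
  }
})

test_that("count_matrix matches an exhaustive fragment x peak double loop", {
  set.seed(202)
  atlas <- merge_peaks(gr("chr1", c(100, 500, 900), c(200, 640, 1000),
                          seqlengths = c(chr1 = 10000)))
  # empty sample gives a zero column; totals count all fragments
  frs <- list(
    s1 = gr("chr1", c(90, 150, 630, 5000), c(120, 160, 660, 5100)),
    s2 = GenomicRanges::GRanges())
  cm <- count_matrix(atlas, frs, chromosomes = c(chr1 = 10000))
  expect_equal(unname(cm$raw[, "s2"]), c(0L, 0L, 0L))
  expect_equal(unname(cm$totals), c(4L, 0L))

  for (rep in 1:15) {
    L <- 10000
    s <- sort(sample.int(L - 500, 4)); e <- s + 60
    at <- merge_peaks(gr("chr1", s, e))
    fs <- sample.int(L - 150, 40); fe <- fs + sample(20:150, 40, TRUE)
    cm <- count_matrix(at, list(x = gr("chr1", fs, fe)))
    manual <- integer(length(at))
    for (i in seq_along(at)) {
      for (j in seq_along(fs)) {
        if (fs[j] <= GenomicRanges::end(at)[i] &&
            fe[j] >= GenomicRanges::start(at)[i])
          manual[i] <- manual[i] + 1L
      }
    }
    expect_equal(unname(cm$raw[, 1]), manual)
  }
})

test_that("a gap-spanning fragment is counted in both flanking peaks", {
  atlas <- merge_peaks(gr("chr1", c(100, 300), c(200, 400)))
  cm <- count_matrix(atlas, list(s = gr("chr1", 150, 350)))
  expect_equal(unname(cm$raw[, 1]), c(1L, 1L))
})

test_that("fragments on unknown chromosomes are a named error", {
  atlas <- merge_peaks(gr("chr1", 100, 200))
  expect_error(
    count_matrix(atlas, list(s = gr("chrMystery", 1, 50)),
                 chromosomes = c(chr1 = 1000)),
    "chrMystery")
})

test_that("normalization follows the sample-relative / peak-mean formula", {
  # hand computation: raw [[2,4]], totals [100,100]:
  # rel = [0.02, 0.04], mean 0.03 -> normalized [2/3, 4/3]
  norm <- normalize_accessibility(matrix(c(2, 4), 1,
                                         dimnames = list("p1", c("a", "b"))),
                                  c(100, 100))
  expect_equal(unname(norm[1, ]), c(2 / 3, 4 / 3))

  # identical columns: all ones
  raw <- matrix(c(5, 9, 5, 9), 2, dimnames = list(c("p1", "p2"), c("a", "b")))
  expect_true(all(normalize_accessibility(raw, c(50, 50)) == 1))

  # all-zero rows are dropped under the default policy
  raw0 <- rbind(raw, p3 = c(0, 0))
  expect_message(n0 <- normalize_accessibility(raw0, c(50, 50)), "dropping")
  expect_false("p3" %in% rownames(n0))
  expect_error(normalize_accessibility(raw0, c(50, 50), "error"),
               "zero counts")

  # zero totals are an error, not a division
  expect_error(normalize_accessibility(raw, c(50, 0)), "zero")
})

test_that("every retained normalized row has mean 1 and depth cancels", {
  set.seed(203)
  raw <- matrix(rpois(300, 8), 50,
                dimnames = list(sprintf("p%02d", 1:50), sprintf("s%d", 1:6)))
  totals <- sample(5e4:9e4, 6)
  norm <- normalize_accessibility(raw, totals)
  expect_lt(max(abs(rowMeans(norm) - 1)), 1e-12)

  # scaling one sample's fragments (counts and total) x10 changes nothing
  raw10 <- raw; raw10[, 3] <- raw10[, 3] * 10L
  t10 <- totals; t10[3] <- t10[3] * 10
  expect_equal(normalize_accessibility(raw10, t10), norm)
})

test_that("atlas coverage is bounded by sample coverages", {
  sim <- small_cohort_fixture(seed = 17, n_fail = 0)
  qc <- qc_filter(sample_qc(sim$cohort), 2e4, 0.2)
  at <- build_atlas(sim$cohort, qc, chromosomes = sim$genome$chromosomes)
  cov_atlas <- sum(GenomicRanges::width(at$atlas))
  cov_samples <- vapply(sim$cohort$samples,
                        function(s) sum(GenomicRanges::width(s$peaks)),
                        numeric(1))
  expect_gte(cov_atlas, max(cov_samples))
  expect_lte(cov_atlas, sum(cov_samples))
})
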