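# Brute-force oracles and tiny fixtures shared across the suite.
# The oracles deliberately use per-base / per-element enumeration, never the
# interval or combinatorial machinery they are checking.

gr <- function(chrom, start, end, names = NULL, seqlengths = NULL) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                              seqlengths = seqlengths)
  if (!is.null(names)) names(g) <- names
  g
}

# Per-base boolean union of intervals on a single chromosome of length L,
# returned as a sorted data.frame of maximal runs.
oracle_union <- function(starts, ends, L) {
  covered <- logical(L)
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  r <- rle(covered)
  stop_at <- cumsum(r$lengths)
  start_at <- stop_at - r$lengths + 1L
  data.frame(start = start_at[r$values], end = stop_at[r$values])
}

# Per-base overlap test: does interval [s1, e1] share >= 1 base with any
# [s2, e2]?
oracle_overlaps_any <- function(s1, e1, s2, e2, L) {
  inpeak <- logical(L)
  for (i in seq_along(s2)) inpeak[s2[i]:e2[i]] <- TRUE
  vapply(seq_along(s1), function(i) any(inpeak[s1[i]:e1[i]]), logical(1))
}

# Exhaustive nearest-TSS assignment: min over every gene on the peak's
# chromosome, strict < max_dist, lexicographic tie-break.
oracle_nearest_tss <- function(mid, chrom, genes, max_dist = 10000) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) return(list(gene = NA_character_, dist = NA_integer_))
  d <- abs(g$tss - mid)
  dmin <- min(d)
  if (dmin >= max_dist) return(list(gene = NA_character_, dist = NA_integer_))
  list(gene = min(g$gene_id[d == dmin]), dist = as.integer(dmin))
}

# Hypergeometric upper tail by direct summation of exact binomial
# coefficients (exact in doubles for N <= 50).
oracle_hyper <- function(k, K, n, N) {
  i <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Position-by-position PWM scorer, both strands, no vectorisation.
oracle_scan <- function(seq_str, pwm, threshold = pwm$threshold) {
  chars <- strsplit(toupper(seq_str), "")[[1]]
  m <- nrow(pwm$matrix)
  lom <- log2(pmax(pwm$matrix, 1e-4) /
                rep(pwm$background, each = m))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- data.frame(start = integer(0), strand = character(0))
  for (i in seq_len(max(length(chars) - m + 1L, 0))) {
    win <- chars[i:(i + m - 1L)]
    sc_f <- 0; sc_r <- 0
    for (j in seq_len(m)) {
      b <- win[j]
      if (b %in% c("A", "C", "G", "T")) {
        sc_f <- sc_f + lom[j, b]
        rb <- comp[[win[m - j + 1L]]]
        if (!is.null(rb) && rb %in% c("A", "C", "G", "T"))
          sc_r <- sc_r + lom[j, rb]
      }
    }
    if (sc_f >= threshold)
      hits <- rbind(hits, data.frame(start = i, strand = "+"))
    if (sc_r >= threshold)
      hits <- rbind(hits, data.frame(start = i, strand = "-"))
  }
  hits
}

# Benjamini-Hochberg step-up from its definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# A small cohort used by several files; built once per test run.
small_cohort_fixture <- function(seed = 42, n_fail = 2) {
  genome <- generate_genome(2, 4e5, 150, seed = seed, with_sequence = FALSE)
  regions <- data.frame(name = c("Dd2", "Dm", "Vv"), n_samples = c(3, 3, 3))
  cmap <- design_cluster_map(regions$name, 5, "Dd2", n_private = 2)
  sim <- generate_cohort(genome, regions, 5, cmap, distinct_region = "Dd2",
                         depth_range = c(2e4, 4e4), n_fail = n_fail,
                         peaks_per_cluster = 15,
                         qc_min_fragments = 2e4, seed = seed)
  c(sim, list(genome = genome))
}
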