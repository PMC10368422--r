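#' Known-motif enrichment of a peak set against a background
#'
#' For each PWM in the library, counts the peaks carrying at least one
#' log-odds hit (either strand) in the target set and in the background
#' set, and tests over-representation of hit-bearing peaks in the target
#' with a one-sided hypergeometric tail over the pooled universe
#' (target plus background). By default the background is "all other
#' atlas peaks". The `-log10 p > 100` gate mirrors the usual dot-plot
#' display rule and is a plotting flag, not a test: both raw and gated
#' columns are emitted.
#'
#' @param target_seqs named character vector of target peak sequences.
#' @param background_seqs named character vector of background peak
#'   sequences (no overlap with the target assumed).
#' @param pwms named list of [motif_pwm()].
#' @param display_gate `-log10(p)` display threshold (default 100).
#' @return data.frame per motif: `motif`, `target_hits`, `target_n`,
#'   `bg_hits`, `bg_n`, `percent_target`, `p`, `neg_log10_p`, `padj`
#'   (BH across the library), `enriched` (display gate).
#' @export
motif_enrichment <- function(target_seqs, background_seqs, pwms,
                             display_gate = 100) {
  if (length(target_seqs) == 0) stop("empty target peak set")
  rows <- lapply(pwms, function(pwm) {
    th <- sum(vapply(target_seqs,
                     function(s) nrow(scan_pwm(s, pwm)) > 0, logical(1)))
    bh <- sum(vapply(background_seqs,
                     function(s) nrow(scan_pwm(s, pwm)) > 0, logical(1)))
    n <- length(target_seqs); N <- n + length(background_seqs)
    K <- th + bh
    p <- hyper_test(th, K, n, N)
    data.frame(motif = pwm$name, target_hits = th, target_n = n,
               bg_hits = bh, bg_n = length(background_seqs),
               percent_target = 100 * th / n, p = p,
               neg_log10_p = -log10(p))
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$neg_log10_p > display_gate
  rownames(out) <- NULL
  out[order(out$p), ]
}

#' Per-cluster motif enrichment over a clustered atlas
#'
#' Runs [motif_enrichment()] once per OCR cluster with all other atlas
#' peaks as background.
#'
#' @param genome a [genome_model()] with sequence.
#' @param peaks truth-peak data.frame or named GRanges covering all
#'   clustered peaks.
#' @param clusters `ocr_clusters` object or named peak -> label vector.
#' @param pwms named list of [motif_pwm()].
#' @param ... passed to [motif_enrichment()].
#' @return data.frame with a `cluster` column prepended.
#' @export
cluster_motif_enrichment <- function(genome, peaks, clusters, pwms, ...) {
  labels <- if (inherits(clusters, "ocr_clusters")) clusters$labels
  else clusters
  seqs <- peak_sequences(genome, peaks)
  seqs <- seqs[names(labels)]
  out <- lapply(sort(unique(labels)), function(cl) {
    tgt <- seqs[labels == cl]
    bg <- seqs[labels != cl]
    cbind(cluster = cl, motif_enrichment(tgt, bg, pwms, ...))
  })
  do.call(rbind, out)
}

#' Shared-motif count matrix between two collections of motif sets
#'
#' Entry (a, b) is the number of motif names present in both collection
#' A's set a and collection B's set b — the cross-dataset comparison of
#' which regulatory motifs two region-specific OCR collections share.
#'
#' @param collection_a,collection_b named lists of character vectors of
#'   motif names (a shared namespace).
#' @return integer matrix, rows = A's sets, columns = B's sets.
#' @export
share_matrix <- function(collection_a, collection_b) {
  out <- vapply(collection_b, function(b) {
    vapply(collection_a, function(a) length(intersect(a, b)), integer(1))
  }, integer(length(collection_a)))
  matrix(out, nrow = length(collection_a),
         dimnames = list(names(collection_a), names(collection_b)))
}

#' Motif hit density around peak centres
#'
#' Counts PWM hits by the offset of the hit start from the peak centre,
#' folded into fixed-width bins spanning `[-window/2, +window/2)`
#' (defaults 2000 bp window, 20 bp bins — the conventional histogram for
#' motif positional profiles). Peaks closer than `window/2` to a
#' chromosome edge are truncated, and each bin is normalised by the
#' number of peaks that actually cover it, giving hits per peak per bin.
#'
#' @param genome a [genome_model()] with sequence.
#' @param peaks named GRanges or truth-peak data.frame.
#' @param pwm a [motif_pwm()].
#' @param window total window in bp (even multiple of `bin`).
#' @param bin bin width in bp.
#' @return data.frame: `offset` (bin left edge relative to centre),
#'   `hits`, `n_peaks` (peaks covering the bin), `density`.
#' @export
density_profile <- function(genome, peaks, pwm, window = 2000, bin = 20) {
  if (window %% bin != 0 || (window / bin) %% 2 != 0)
    stop("window must be an even multiple of bin")
  if (is.data.frame(peaks)) {
    chrom <- peaks$chrom
    centre <- floor((peaks$start + peaks$end) / 2)
  } else {
    chrom <- as.character(GenomicRanges::seqnames(peaks))
    centre <- floor((GenomicRanges::start(peaks) +
                       GenomicRanges::end(peaks)) / 2)
  }
  half <- window %/% 2
  edges <- seq(-half, half, by = bin)
  n_bins <- length(edges) - 1L
  hits <- integer(n_bins)
  covered <- integer(n_bins)
  for (i in seq_along(centre)) {
    L <- genome$chromosomes[chrom[i]]
    from <- max(centre[i] - half, 1L)
    to <- min(centre[i] + half - 1L, L)
    s <- as.character(Biostrings::subseq(genome$sequence[[chrom[i]]],
                                         from, to))
    h <- scan_pwm(s, pwm)
    off <- (from - centre[i]) + h$start - 1L        # offset of hit start
    b <- findInterval(off, edges, rightmost.closed = FALSE)
    b <- b[b >= 1 & b <= n_bins]
    if (length(b) > 0) hits <- hits + tabulate(b, n_bins)
    cov_bins <- which(edges[-length(edges)] >= (from - centre[i]) &
                        edges[-1] - 1 <= (to - centre[i]))
    covered[cov_bins] <- covered[cov_bins] + 1L
  }
  data.frame(offset = edges[-length(edges)], hits = hits,
             n_peaks = covered,
             density = ifelse(covered > 0, hits / covered, 0))
}
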