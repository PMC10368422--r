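#' Nearest-TSS target-gene assignment for atlas peaks
#'
#' Each peak is assigned the gene whose TSS is nearest to the peak's
#' anchor point, provided that distance is strictly less than `max_dist`
#' (default 10 kb). The anchor is the peak midpoint by default (merged
#' atlas peaks carry no summit); `anchor = "edge"` measures from the
#' nearest peak edge instead (distance 0 when the TSS lies inside the
#' peak). TSS on other chromosomes are never considered. Equidistant ties
#' are broken by the lexicographically smaller gene id, for determinism.
#'
#' @param peaks named GRanges of (atlas) peaks.
#' @param genome a [genome_model()].
#' @param max_dist assignment radius in bp; strict `<` comparison.
#' @param anchor `"midpoint"` (default) or `"edge"`.
#' @return data.frame: `peak_id`, `target_gene` (NA when no TSS in range),
#'   `tss_distance` (unsigned bp; NA when unassigned).
#' @export
assign_targets <- function(peaks, genome, max_dist = 10000,
                           anchor = c("midpoint", "edge")) {
  anchor <- match.arg(anchor)
  pid <- names(peaks)
  if (is.null(pid)) pid <- sprintf("peak_%d", seq_along(peaks))
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  ps <- GenomicRanges::start(peaks)
  pe <- GenomicRanges::end(peaks)
  mid <- floor((ps + pe) / 2)
  genes <- genome$genes
  target <- rep(NA_character_, length(peaks))
  dist <- rep(NA_integer_, length(peaks))
  for (chr in unique(chrom)) {
    g <- genes[genes$chrom == chr, , drop = FALSE]
    idx <- which(chrom == chr)
    if (nrow(g) == 0) next
    for (i in idx) {
      d <- if (anchor == "midpoint") abs(g$tss - mid[i])
      else ifelse(g$tss < ps[i], ps[i] - g$tss,
                  ifelse(g$tss > pe[i], g$tss - pe[i], 0L))
      dmin <- min(d)
      if (dmin < max_dist) {
        cand <- g$gene_id[d == dmin]
        target[i] <- min(cand)          # lexicographic tie-break
        dist[i] <- as.integer(dmin)
      }
    }
  }
  data.frame(peak_id = pid, target_gene = target, tss_distance = dist)
}

#' Genomic-context classification of peaks
#'
#' Classifies each peak, at its midpoint, into exactly one of
#' `promoter > exon > intron > intergenic` (that precedence). The promoter
#' is the strand-aware window of `promoter_window` bp upstream of the TSS
#' plus the TSS base itself. When the genome carries no exon models every
#' gene body counts as a single exon (so `intron` cannot occur).
#'
#' @param peaks named GRanges of peaks.
#' @param genome a [genome_model()].
#' @param promoter_window upstream window in bp (default 1000).
#' @return data.frame: `peak_id`, `context` (factor with the four levels).
#' @export
classify_context <- function(peaks, genome, promoter_window = 1000) {
  pid <- names(peaks)
  if (is.null(pid)) pid <- sprintf("peak_%d", seq_along(peaks))
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  mid <- floor((GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2)
  pts <- GenomicRanges::GRanges(chrom, IRanges::IRanges(mid, width = 1))

  g <- genome$genes
  ctx <- rep("intergenic", length(peaks))
  if (nrow(g) > 0) {
    prom_start <- ifelse(g$strand == "+", g$tss - promoter_window, g$tss)
    prom_end <- ifelse(g$strand == "+", g$tss, g$tss + promoter_window)
    prom <- GenomicRanges::GRanges(g$chrom,
      IRanges::IRanges(pmax(prom_start, 1L), prom_end))
    body <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end))
    ex <- if (!is.null(genome$exons))
      GenomicRanges::GRanges(genome$exons$chrom,
        IRanges::IRanges(genome$exons$start, genome$exons$end))
    else body
    in_body <- IRanges::overlapsAny(pts, body)
    in_exon <- IRanges::overlapsAny(pts, ex)
    in_prom <- IRanges::overlapsAny(pts, prom)
    ctx[in_body & !in_exon] <- "intron"
    ctx[in_exon] <- "exon"
    ctx[in_prom] <- "promoter"
  }
  data.frame(peak_id = pid,
             context = factor(ctx, levels = c("promoter", "exon",
                                              "intron", "intergenic")))
}

#' Per-cluster genomic-context fractions
#'
#' @param contexts data.frame from [classify_context()].
#' @param clusters an `ocr_clusters` object or a named vector
#'   peak id -> cluster label.
#' @return matrix clusters x contexts of fractions; each non-empty row sums
#'   to 1, empty clusters give a zero row with a warning.
#' @export
cluster_context_profile <- function(contexts, clusters) {
  labels <- if (inherits(clusters, "ocr_clusters")) clusters$labels
  else clusters
  lv <- levels(contexts$context)
  cl_ids <- sort(unique(labels))
  out <- matrix(0, length(cl_ids), length(lv),
                dimnames = list(as.character(cl_ids), lv))
  for (ci in seq_along(cl_ids)) {
    ids <- names(labels)[labels == cl_ids[ci]]
    sub <- contexts$context[contexts$peak_id %in% ids]
    if (length(sub) == 0) {
      warning("cluster ", cl_ids[ci], " has no annotated peaks")
      next
    }
    out[ci, ] <- as.numeric(table(sub)) / length(sub)
  }
  out
}
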