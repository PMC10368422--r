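#' Plant PWM consensus instances into selected peak clusters
#'
#' Writes the motif's consensus string into each truth peak of the target
#' clusters with probability `prob`, at a Gaussian offset around the peak
#' centre, leaving all other clusters (and, at `prob = 0`, the whole genome)
#' untouched. Peaks shorter than the motif are skipped with a warning and
#' recorded in the returned truth.
#'
#' @param genome a [genome_model()] with sequence.
#' @param truth_peaks truth-peak data.frame (`peak_id`, `chrom`, `start`,
#'   `end`, `cluster`) as produced by [generate_cohort()].
#' @param pwm a [motif_pwm()]; its consensus is the planted instance.
#' @param clusters integer ids of the clusters to plant into.
#' @param prob per-peak planting probability.
#' @param offset_sd SD in bp of the Gaussian offset of the motif centre
#'   around the peak centre (clamped so the instance stays inside the peak).
#' @param seed integer seed.
#' @return list with `genome` (mutated copy) and `truth` (data.frame:
#'   `peak_id`, `cluster`, `planted`, `start` of the instance or NA,
#'   `skipped`).
#' @export
plant_motifs <- function(genome, truth_peaks, pwm, clusters, prob = 1,
                         offset_sd = 0, seed = 1) {
  if (is.null(genome$sequence))
    stop("genome has no sequence; generate it with with_sequence = TRUE")
  stopifnot(prob >= 0, prob <= 1)
  set.seed(seed)
  cons <- consensus(pwm)
  m <- nchar(cons)
  tp <- truth_peaks[truth_peaks$cluster %in% clusters, , drop = FALSE]
  truth <- data.frame(peak_id = tp$peak_id, cluster = tp$cluster,
                      planted = FALSE, start = NA_integer_, skipped = FALSE)
  if (prob == 0 || nrow(tp) == 0)
    return(list(genome = genome, truth = truth))

  width <- tp$end - tp$start + 1L
  too_short <- width < m
  if (any(too_short)) {
    warning(sum(too_short), " peak(s) shorter than the motif; skipped")
    truth$skipped[too_short] <- TRUE
  }
  plant <- !too_short & stats::runif(nrow(tp)) < prob
  centre <- floor((tp$start + tp$end) / 2)
  off <- round(stats::rnorm(nrow(tp), 0, offset_sd))
  ins <- centre + off - floor(m / 2)
  ins <- pmax(pmin(ins, tp$end - m + 1L), tp$start)  # keep inside the peak
  truth$planted <- plant
  truth$start[plant] <- as.integer(ins[plant])

  seqs <- genome$sequence
  for (chr in unique(tp$chrom[plant])) {
    sel <- plant & tp$chrom == chr
    at <- IRanges::IRanges(ins[sel], width = m)
    seqs[[chr]] <- Biostrings::replaceAt(
      seqs[[chr]], at, as(rep(cons, sum(sel)), "DNAStringSet"))
  }
  genome$sequence <- seqs
  list(genome = genome, truth = truth)
}

#' Extract peak sequences from a genome model
#' @param genome a [genome_model()] with sequence.
#' @param peaks GRanges (names are kept) or a truth-peak data.frame.
#' @return named character vector of peak sequences.
#' @export
peak_sequences <- function(genome, peaks) {
  if (is.null(genome$sequence)) stop("genome has no sequence")
  if (is.data.frame(peaks)) {
    ids <- peaks$peak_id
    chrom <- peaks$chrom; start <- peaks$start; end <- peaks$end
  } else {
    ids <- names(peaks)
    chrom <- as.character(GenomicRanges::seqnames(peaks))
    start <- GenomicRanges::start(peaks)
    end <- GenomicRanges::end(peaks)
  }
  out <- vapply(seq_along(ids), function(i) {
    as.character(Biostrings::subseq(genome$sequence[[chrom[i]]],
                                    start[i], end[i]))
  }, character(1))
  stats::setNames(out, ids)
}
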