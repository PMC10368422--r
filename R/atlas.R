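#' Merge per-sample peak calls into a consensus atlas
#'
#' Peaks are merged whenever they overlap, transitively: the atlas is the
#' connected-overlap closure (interval union) of all input peaks, so a
#' chain of pairwise-overlapping peaks collapses into one atlas peak. The
#' result is non-overlapping and sorted by (chromosome, start), with stable
#' ids `atlas_00001...`.
#'
#' @param peak_sets list of GRanges, one per passing sample (a single
#'   GRanges is also accepted).
#' @return GRanges of atlas peaks, named by atlas id.
#' @export
merge_peaks <- function(peak_sets) {
  if (inherits(peak_sets, "GRanges")) peak_sets <- list(peak_sets)
  if (length(peak_sets) == 0 || sum(lengths(peak_sets)) == 0) {
    warning("no input peaks; returning an empty atlas")
    return(GenomicRanges::GRanges())
  }
  all_peaks <- suppressWarnings(
    unlist(methods::as(peak_sets, "GRangesList"), use.names = FALSE))
  GenomicRanges::strand(all_peaks) <- "*"
  atlas <- GenomicRanges::reduce(GenomicRanges::sort(all_peaks))
  names(atlas) <- sprintf("atlas_%05d", seq_along(atlas))
  atlas
}

#' Fragment counts per atlas peak per sample
#'
#' `raw[i, j]` is the number of sample-j fragments overlapping atlas peak i
#' by at least 1 bp. Because atlas peaks are non-overlapping, a fragment can
#' only be counted in two rows when it spans the gap between two peaks; it
#' is then counted in both. Sample totals are ALL mapped fragments of the
#' sample, not just in-atlas ones.
#'
#' @param atlas GRanges of non-overlapping atlas peaks (named).
#' @param fragment_sets named list of GRanges, one per sample.
#' @param chromosomes optional named vector of chromosome lengths; any
#'   fragment on a chromosome absent from it raises an error naming the
#'   chromosome.
#' @return list with `raw` (peaks x samples integer matrix) and `totals`
#'   (named per-sample fragment counts).
#' @export
count_matrix <- function(atlas, fragment_sets, chromosomes = NULL) {
  if (is.null(chromosomes)) {
    sl <- GenomeInfoDb::seqlengths(atlas)
    chromosomes <- if (all(is.na(sl))) NULL else sl
  }
  raw <- vapply(fragment_sets, function(fr) {
    if (!is.null(chromosomes)) {
      unknown <- setdiff(unique(as.character(GenomicRanges::seqnames(fr))),
                         names(chromosomes))
      if (length(unknown) > 0)
        stop("fragment(s) on unknown chromosome: ",
             paste(unknown, collapse = ", "))
    }
    suppressWarnings(GenomicRanges::countOverlaps(atlas, fr))
  }, integer(length(atlas)))
  raw <- matrix(raw, nrow = length(atlas),
                dimnames = list(names(atlas), names(fragment_sets)))
  list(raw = raw, totals = vapply(fragment_sets, length, integer(1)))
}

#' Depth- and peak-relative accessibility normalization
#'
#' For each peak, the per-sample fragment count is divided by the sample's
#' total fragments, then by the average of that ratio over all samples:
#' `normalized[i, j] = (raw[i, j] / total[j]) / mean_j(raw[i, ] / total)`.
#' Every retained row therefore has mean exactly 1 across samples. Rows
#' whose cross-sample mean is 0 carry no information and are dropped (with
#' a message) under the default policy.
#'
#' @param raw peaks x samples count matrix.
#' @param totals per-sample total fragment counts (all > 0).
#' @param zero_row_policy `"drop"` (default) or `"error"`.
#' @return normalized matrix (possibly fewer rows than `raw`).
#' @export
normalize_accessibility <- function(raw, totals, zero_row_policy = "drop") {
  stopifnot(ncol(raw) == length(totals))
  if (any(totals <= 0))
    stop("sample total(s) of zero: ",
         paste(colnames(raw)[totals <= 0], collapse = ", "),
         " (should have failed QC)")
  rel <- sweep(raw, 2, totals, "/")
  m <- rowMeans(rel)
  zero <- m == 0
  if (any(zero)) {
    if (zero_row_policy == "error")
      stop(sum(zero), " atlas peak(s) with zero counts in every sample")
    message("dropping ", sum(zero), " atlas peak(s) with all-zero counts")
    rel <- rel[!zero, , drop = FALSE]
    m <- m[!zero]
  }
  rel / m
}

#' Build the peak atlas end-to-end from a QC-passing cohort
#'
#' Convenience wrapper: merge the passing samples' peaks, count fragments,
#' and normalize.
#'
#' @param cohort cohort list.
#' @param qc QC table from [qc_filter()]; only passing samples are used.
#' @param chromosomes optional chromosome lengths for fragment validation.
#' @return list `atlas` (GRanges), `raw`, `totals`, `normalized`.
#' @export
build_atlas <- function(cohort, qc, chromosomes = NULL) {
  keep <- qc$sample_id[qc$pass]
  if (length(keep) == 0) stop("no passing samples")
  peaks <- lapply(cohort$samples[keep], `[[`, "peaks")
  frags <- lapply(cohort$samples[keep], `[[`, "fragments")
  atlas <- merge_peaks(peaks)
  cm <- count_matrix(atlas, frags, chromosomes = chromosomes)
  norm <- normalize_accessibility(cm$raw, cm$totals)
  list(atlas = atlas, raw = cm$raw, totals = cm$totals, normalized = norm)
}

#' Write an atlas as BED4 with peak ids
#' @param atlas named GRanges of atlas peaks.
#' @param path BED path.
#' @export
write_atlas_bed <- function(atlas, path) {
  df <- data.frame(as.character(GenomicRanges::seqnames(atlas)),
                   GenomicRanges::start(atlas) - 1L,
                   GenomicRanges::end(atlas), names(atlas))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Write a numeric matrix as TSV with an id column
#' @param mat matrix with rownames.
#' @param path TSV path.
#' @param id_col name of the id column (default `"id"`).
#' @export
write_matrix_tsv <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
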