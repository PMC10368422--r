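#' Synthetic clonal-unit ATAC-seq cohort with ground truth
#'
#' Emulates the structure of a micro-dissected brain-region ATAC-seq study:
#' a fixed set of "atlas-truth" peaks partitioned into accessibility clusters,
#' regions whose samples expose only the clusters active in that region, one
#' optional "distinct" region whose private clusters are closed everywhere
#' else, variable sequencing depth including planted sub-threshold samples,
#' and fragments placed inside active peaks with a target in-peak fraction
#' (FRiP) against a uniform genomic background.
#'
#' Per-sample peak calls are jittered re-centrings of the truth peaks with
#' random drop-out, so consensus-atlas merging is non-trivial downstream.
#'
#' @param genome a [genome_model()].
#' @param regions data.frame with columns `name` and `n_samples`.
#' @param n_clusters number of planted peak clusters.
#' @param cluster_region_map named list: region name -> integer vector of the
#'   clusters active in that region; the union must cover `1..n_clusters`.
#' @param distinct_region optional region name whose map entry holds its
#'   private clusters (recorded in the truth; the map itself encodes the
#'   open/closed pattern).
#' @param depth_range fragment-count range for passing samples.
#' @param n_fail number of planted QC failures (low depth or low FRiP).
#' @param frip_target in-peak placement probability for passing samples.
#' @param peaks_per_cluster,peak_width truth-peak geometry.
#' @param fragment_length fixed fragment length in bp (default 200 bp, the
#'   usual Tn5 peak-calling extension size).
#' @param jitter_sd per-sample peak re-centring SD in bp (truncated at 4 SD).
#' @param drop_prob per-sample probability of dropping each active peak.
#' @param qc_min_fragments,qc_min_frip the QC thresholds the planted
#'   failures are constructed to violate.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return list with elements `cohort` (see Details) and `truth`.
#'
#' @details The cohort is a list with `samples` (named list, each holding
#' `fragments` and `peaks` as [GenomicRanges::GRanges]) and `metadata`
#' (data.frame: `sample_id`, `region`, `n_fragments`). The truth records the
#' sample-to-region map, the planted failure set with failure mode, and the
#' truth peaks with their cluster labels.
#' @export
generate_cohort <- function(genome, regions, n_clusters, cluster_region_map,
                            distinct_region = NULL,
                            depth_range = c(5e4, 1e5),
                            n_fail = 0, frip_target = 0.45,
                            peaks_per_cluster = 40, peak_width = 400,
                            fragment_length = 200, jitter_sd = 20,
                            drop_prob = 0.05,
                            qc_min_fragments = 5e4, qc_min_frip = 0.2,
                            seed = 1) {
  regions <- as.data.frame(regions)
  stopifnot(all(c("name", "n_samples") %in% names(regions)),
            peak_width >= fragment_length,
            frip_target > 0, frip_target < 1)
  if (!is.null(distinct_region) && !distinct_region %in% regions$name)
    stop("distinct_region '", distinct_region, "' is not a listed region")
  if (!setequal(names(cluster_region_map), regions$name))
    stop("cluster_region_map must have one entry per region")
  covered <- sort(unique(as.integer(unlist(cluster_region_map))))
  if (!identical(covered, seq_len(n_clusters)))
    stop("cluster_region_map must cover clusters 1..", n_clusters)
  n_total <- sum(regions$n_samples)
  if (n_fail >= n_total)
    stop("n_fail (", n_fail, ") must be below the total sample count (",
         n_total, ")")
  if (min(depth_range) < qc_min_fragments)
    stop("depth_range must sit at or above qc_min_fragments so that only ",
         "planted failures fall below the depth gate")
  set.seed(seed)

  ## --- truth peaks, separated widely enough that per-sample jitter can
  ## never fuse neighbouring truth peaks in the merged atlas
  n_peaks <- n_clusters * peaks_per_cluster
  gap <- as.integer(2L * ceiling(4 * jitter_sd) + fragment_length)
  chrom_names <- names(genome$chromosomes)
  per_chrom <- tabulate(sample.int(length(chrom_names), n_peaks,
                                   replace = TRUE), length(chrom_names))
  truth_peaks <- do.call(rbind, lapply(seq_along(chrom_names), function(i) {
    np <- per_chrom[i]
    if (np == 0) return(NULL)
    starts <- place_nonoverlapping(np, genome$chromosomes[i], peak_width,
                                   min_gap = gap)
    data.frame(chrom = chrom_names[i], start = starts,
               end = starts + peak_width - 1L)
  }))
  truth_peaks$peak_id <- sprintf("tpeak_%04d", seq_len(nrow(truth_peaks)))
  truth_peaks$cluster <- sample(rep(seq_len(n_clusters),
                                    length.out = n_peaks))

  ## --- sample sheet with planted failures
  meta <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n_total)),
    region = rep(regions$name, regions$n_samples))
  fail_idx <- sort(sample.int(n_total, n_fail))
  fail_mode <- sample(c("depth", "frip"), n_fail, replace = TRUE)

  chrom_w <- genome$chromosomes / sum(genome$chromosomes)
  samples <- vector("list", n_total)
  names(samples) <- meta$sample_id
  depths <- integer(n_total)
  for (i in seq_len(n_total)) {
    active <- cluster_region_map[[meta$region[i]]]
    tp <- truth_peaks[truth_peaks$cluster %in% active, ]
    keep <- stats::runif(nrow(tp)) >= drop_prob
    if (!any(keep)) keep[1] <- TRUE
    tp <- tp[keep, ]
    jit <- as.integer(round(pmax(pmin(stats::rnorm(nrow(tp), 0, jitter_sd),
                                      4 * jitter_sd), -4 * jitter_sd)))
    ps <- pmax(tp$start + jit, 1L)
    pe <- pmin(ps + peak_width - 1L, genome$chromosomes[tp$chrom])
    peaks <- GenomicRanges::GRanges(tp$chrom, IRanges::IRanges(ps, pe),
                                    seqlengths = genome$chromosomes)
    names(peaks) <- tp$peak_id

    fpos <- match(i, fail_idx)
    depth <- if (!is.na(fpos) && fail_mode[fpos] == "depth")
      as.integer(round(stats::runif(1, 0.3, 0.8) * qc_min_fragments))
    else as.integer(round(stats::runif(1, depth_range[1], depth_range[2])))
    p_in <- if (!is.na(fpos) && fail_mode[fpos] == "frip")
      0.5 * qc_min_frip else frip_target

    n_in <- stats::rbinom(1, depth, p_in)
    pick <- sample.int(length(peaks), n_in, replace = TRUE)
    in_start <- GenomicRanges::start(peaks)[pick] +
      floor(stats::runif(n_in) *
              (GenomicRanges::width(peaks)[pick] - fragment_length + 1L))
    in_chrom <- as.character(GenomicRanges::seqnames(peaks))[pick]
    n_bg <- depth - n_in
    bg_chrom_i <- sample.int(length(chrom_names), n_bg, replace = TRUE,
                             prob = chrom_w)
    bg_start <- 1L + floor(stats::runif(n_bg) *
      (genome$chromosomes[bg_chrom_i] - fragment_length + 1L))
    fr <- GenomicRanges::GRanges(
      c(in_chrom, chrom_names[bg_chrom_i]),
      IRanges::IRanges(as.integer(c(in_start, bg_start)),
                       width = fragment_length),
      seqlengths = genome$chromosomes)
    samples[[i]] <- list(fragments = fr, peaks = peaks)
    depths[i] <- depth
  }
  meta$n_fragments <- depths

  truth <- list(
    sample_region = stats::setNames(meta$region, meta$sample_id),
    fail_samples = data.frame(sample_id = meta$sample_id[fail_idx],
                              mode = fail_mode),
    peak_clusters = truth_peaks,
    cluster_region_map = cluster_region_map,
    distinct_region = distinct_region,
    frip_target = frip_target,
    qc_min_fragments = qc_min_fragments, qc_min_frip = qc_min_frip,
    seed = seed)
  list(cohort = list(samples = samples, metadata = meta), truth = truth)
}

#' Cluster-to-region design with one distinct region
#'
#' Builds a `cluster_region_map` of the shape the cohort generator expects:
#' `n_private` clusters private to the distinct region, one cluster per
#' remaining region specific to it, and the remaining clusters active in
#' every region (including, by default, the distinct one), mirroring a study
#' design where one compartment's specific open-chromatin clusters are
#' closed elsewhere and vice versa.
#'
#' @param region_names character vector of region names.
#' @param n_clusters total clusters; must be at least
#'   `n_private + length(region_names) - 1`.
#' @param distinct_region name of the distinct region.
#' @param n_private number of clusters private to the distinct region.
#' @return named list region -> active cluster ids.
#' @export
design_cluster_map <- function(region_names, n_clusters, distinct_region,
                               n_private = 2) {
  stopifnot(distinct_region %in% region_names)
  others <- setdiff(region_names, distinct_region)
  n_specific <- length(others)
  if (n_clusters < n_private + n_specific)
    stop("need at least ", n_private + n_specific, " clusters for ",
         "this design (", n_private, " private + ", n_specific, " specific)")
  private <- seq_len(n_private)
  specific <- n_private + seq_len(n_specific)
  common <- setdiff(seq_len(n_clusters), c(private, specific))
  map <- stats::setNames(
    lapply(seq_along(others), function(i) c(specific[i], common)), others)
  map[[distinct_region]] <- c(private, common)
  map[region_names]
}

#' Write a cohort to disk as BED6 fragments and narrowPeak peak calls
#' @param cohort cohort list from [generate_cohort()].
#' @param dir output directory; `fragments/` and `peaks/` subdirectories are
#'   created, plus `samples.tsv`.
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  fdir <- file.path(dir, "fragments")
  pdir <- file.path(dir, "peaks")
  dir.create(fdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(cohort$samples)) {
    s <- cohort$samples[[sid]]
    rtracklayer::export(s$fragments, file.path(fdir, paste0(sid, ".bed")),
                        format = "bed")
    write_narrowpeak(s$peaks, file.path(pdir, paste0(sid, ".narrowPeak")))
  }
  utils::write.table(cohort$metadata, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir cohort directory.
#' @return a cohort list (`samples`, `metadata`).
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.delim(file.path(dir, "samples.tsv"))
  samples <- lapply(meta$sample_id, function(sid) {
    fr <- rtracklayer::import(file.path(dir, "fragments",
                                        paste0(sid, ".bed")), format = "bed")
    pk <- read_narrowpeak(file.path(dir, "peaks",
                                    paste0(sid, ".narrowPeak")))
    list(fragments = fr, peaks = pk)
  })
  names(samples) <- meta$sample_id
  list(samples = samples, metadata = meta)
}

#' @rdname write_cohort
#' @param peaks GRanges of peak calls (names become the narrowPeak name
#'   column).
#' @param path output file.
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,   # BED half-open
    end = GenomicRanges::end(peaks),
    name = if (is.null(names(peaks)))
      sprintf("peak_%d", seq_along(peaks)) else names(peaks),
    score = 0L, strand = ".",
    signalValue = 0, pValue = -1, qValue = -1,
    peak = as.integer(floor(GenomicRanges::width(peaks) / 2)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' @rdname read_cohort
#' @param path narrowPeak file.
#' @export
read_narrowpeak <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df[[1]],
                               IRanges::IRanges(df[[2]] + 1L, df[[3]]))
  names(gr) <- df[[4]]
  gr
}
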