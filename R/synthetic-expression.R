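#' Synthetic region-level RNA-seq counts with planted differential expression
#'
#' Draws gene-level counts from a negative binomial with gene-wise baseline
#' means and a fixed dispersion, for a small multi-condition design (the
#' study shape is three conditions, two replicates each). Planted
#' differentially expressed genes have their mean multiplied by
#' `2^(sign * lfc)` in the first condition, so the first-vs-others contrasts
#' carry known signal.
#'
#' The NB is parameterised by mean and dispersion with
#' `Var = mu + dispersion * mu^2`, the model family of the downstream Wald
#' test.
#'
#' @param genome a [genome_model()]; its gene ids index the count matrix.
#' @param conditions character vector of condition labels; the first is the
#'   condition carrying planted effects.
#' @param n_de number of planted DE genes (half up, half down in
#'   `conditions[1]`); ignored when `planted` is supplied; forced to 0 when
#'   `lfc == 0`.
#' @param lfc absolute log2 fold change of planted genes.
#' @param dispersion NB dispersion (must be > 0).
#' @param depth per-sample relative library depth (recycled; must be > 0).
#' @param n_reps replicates per condition (>= 2).
#' @param base_mean_meanlog,base_mean_sdlog log-normal parameters of the
#'   baseline mean distribution.
#' @param planted optional data.frame (`gene_id`, `sign` in `{-1,1}`)
#'   overriding random planted-gene selection.
#' @param seed integer seed.
#' @return list with `counts` (genes x samples integer matrix),
#'   `samples` (data.frame: `sample_id`, `condition`) and `truth`
#'   (data.frame of planted genes: `gene_id`, `sign`, `lfc`).
#' @export
generate_expression <- function(genome, conditions = c("Dd2", "D", "V"),
                                n_de = 100, lfc = 2, dispersion = 0.05,
                                depth = 1, n_reps = 2,
                                base_mean_meanlog = log(100),
                                base_mean_sdlog = 1,
                                planted = NULL, seed = 1) {
  if (dispersion <= 0) stop("dispersion must be positive")
  if (any(depth <= 0)) stop("depth must be positive")
  if (n_reps < 2) stop("n_reps must be at least 2")
  genes <- genome$genes$gene_id
  if (length(genes) == 0) stop("genome has no genes")
  set.seed(seed)
  n_samples <- length(conditions) * n_reps
  depth <- rep_len(depth, n_samples)
  cond <- rep(conditions, each = n_reps)
  sample_id <- paste0(cond, "_r", rep(seq_len(n_reps), length(conditions)))

  base <- stats::rlnorm(length(genes), base_mean_meanlog, base_mean_sdlog)
  if (is.null(planted)) {
    if (lfc == 0 || n_de == 0) {
      planted <- data.frame(gene_id = character(0), sign = integer(0))
    } else {
      ids <- sample(genes, min(n_de, length(genes)))
      planted <- data.frame(
        gene_id = ids,
        sign = rep(c(1L, -1L), length.out = length(ids)))
    }
  } else {
    planted <- as.data.frame(planted)
    stopifnot(all(planted$gene_id %in% genes),
              all(planted$sign %in% c(-1L, 1L)))
  }
  shift <- rep(1, length(genes))
  shift[match(planted$gene_id, genes)] <- 2^(planted$sign * lfc)

  mu <- outer(base, depth)
  mu[, cond == conditions[1]] <- mu[, cond == conditions[1]] * shift
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = length(genes),
                   dimnames = list(genes, sample_id))
  truth <- if (nrow(planted) > 0)
    data.frame(gene_id = planted$gene_id, sign = planted$sign, lfc = lfc)
  else data.frame(gene_id = character(0), sign = integer(0), lfc = numeric(0))
  list(counts = counts,
       samples = data.frame(sample_id = sample_id, condition = cond),
       truth = truth)
}

#' Choose planted DE genes coupled to a set of peak-cluster target genes
#'
#' Selects `n` genes of which a fraction `coupling` are nearest-TSS targets
#' of the given clusters' truth peaks and the rest are non-targets, so that
#' downstream "actively regulated" fractions have a known expectation.
#'
#' @param genome a [genome_model()].
#' @param truth_peaks truth-peak data.frame from [generate_cohort()]
#'   (`chrom`, `start`, `end`, `peak_id`, `cluster`).
#' @param clusters cluster ids whose targets to couple to.
#' @param n number of planted genes.
#' @param coupling fraction of planted genes drawn from the target set.
#' @param sign planted sign (default +1, i.e. upregulated).
#' @param max_dist nearest-TSS assignment radius in bp.
#' @param seed integer seed.
#' @return data.frame (`gene_id`, `sign`) usable as the `planted` argument
#'   of [generate_expression()].
#' @export
couple_de_to_clusters <- function(genome, truth_peaks, clusters, n,
                                  coupling, sign = 1L, max_dist = 10000,
                                  seed = 1) {
  set.seed(seed)
  tp <- truth_peaks[truth_peaks$cluster %in% clusters, ]
  gr <- GenomicRanges::GRanges(tp$chrom, IRanges::IRanges(tp$start, tp$end))
  names(gr) <- tp$peak_id
  ann <- assign_targets(gr, genome, max_dist = max_dist)
  target_genes <- unique(stats::na.omit(ann$target_gene))
  other_genes <- setdiff(genome$genes$gene_id, target_genes)
  n_t <- round(coupling * n)
  n_o <- n - n_t
  if (length(target_genes) < n_t || length(other_genes) < n_o)
    stop(sprintf(
      "cannot draw %d target and %d non-target genes (available: %d / %d)",
      n_t, n_o, length(target_genes), length(other_genes)))
  data.frame(
    gene_id = c(sample(target_genes, n_t), sample(other_genes, n_o)),
    sign = as.integer(sign))
}

#' Write / read a counts matrix as TSV (genes x samples)
#' @param counts integer matrix with gene rownames and sample colnames.
#' @param path TSV path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
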