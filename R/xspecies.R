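#' Normalize a region x gene expression atlas to the all-gene mean
#'
#' Divides each region's column by the mean expression of ALL genes in
#' that region, so that after normalization every region's all-gene mean
#' is exactly 1. This corrects per-region intensity bias before asking
#' whether a gene set is preferentially expressed anywhere.
#'
#' @param expr genes x regions non-negative matrix with dimnames.
#' @return matrix of the same shape, each column divided by its mean.
#' @export
normalize_atlas <- function(expr) {
  if (any(expr < 0)) stop("expression values must be non-negative")
  if (anyDuplicated(colnames(expr))) stop("region labels must be unique")
  m <- colMeans(expr)
  if (any(m == 0))
    stop("region(s) with all-zero expression: ",
         paste(colnames(expr)[m == 0], collapse = ", "))
  sweep(expr, 2, m, "/")
}

#' Regional expression bias of a gene set
#'
#' Per-region mean of the normalized expression over a gene set, plus a
#' descriptive bias score (max region mean over median region mean). A
#' set with no regional preference gives means near 1 everywhere and a
#' bias score near 1; no statistical test is attached — the score is
#' descriptive.
#'
#' @param genes gene ids; ids absent from the atlas are dropped with a
#'   message, an empty intersection is an error.
#' @param normalized genes x regions matrix from [normalize_atlas()].
#' @return list: `region_means` (named vector), `bias_score`, `argmax`
#'   (region with the largest mean), `n_genes` used.
#' @export
region_bias <- function(genes, normalized) {
  found <- intersect(genes, rownames(normalized))
  if (length(found) == 0)
    stop("none of the gene ids are present in the atlas")
  dropped <- length(genes) - length(found)
  if (dropped > 0)
    message(dropped, " gene(s) absent from the atlas were dropped")
  rm_ <- colMeans(normalized[found, , drop = FALSE])
  list(region_means = rm_,
       bias_score = max(rm_) / stats::median(rm_),
       argmax = names(rm_)[which.max(rm_)],
       n_genes = length(found))
}

#' Generate a synthetic region x gene expression atlas
#'
#' Log-normal baseline expression with independent per-region noise;
#' optionally a planted gene set elevated by a fixed factor in one
#' region, for truth-recovery tests of [region_bias()].
#'
#' @param genes gene ids.
#' @param regions region labels.
#' @param planted_genes optional gene subset to elevate.
#' @param planted_region region in which to elevate them.
#' @param fold elevation factor (default 3).
#' @param noise_sd log-scale noise SD.
#' @param seed integer seed.
#' @return genes x regions matrix.
#' @export
generate_atlas_expression <- function(genes, regions, planted_genes = NULL,
                                      planted_region = NULL, fold = 3,
                                      noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  base <- stats::rlnorm(length(genes), log(5), 1)
  m <- base * matrix(stats::rlnorm(length(genes) * length(regions),
                                   0, noise_sd),
                     length(genes), length(regions))
  dimnames(m) <- list(genes, regions)
  if (!is.null(planted_genes)) {
    stopifnot(planted_region %in% regions)
    m[planted_genes, planted_region] <- m[planted_genes, planted_region] * fold
  }
  m
}

#' Apply a 1:1 orthology mapping to a gene set
#'
#' Maps gene ids through a two-column table (own id, foreign id),
#' dropping rows where several own genes map to one foreign gene — the
#' standard exclusion for ambiguous orthology.
#'
#' @param genes own gene ids.
#' @param mapping data.frame with columns `own` and `foreign`.
#' @return character vector of foreign ids (unique).
#' @export
map_orthologs <- function(genes, mapping) {
  stopifnot(all(c("own", "foreign") %in% names(mapping)))
  dup <- mapping$foreign[duplicated(mapping$foreign)]
  mapping <- mapping[!mapping$foreign %in% dup, ]
  unique(mapping$foreign[mapping$own %in% genes])
}

#' Cross-dataset comparison of regulatory motif landscapes
#'
#' Two views of how a clustered OCR atlas relates to a foreign collection
#' of region-specific OCR sets: (1) the shared-motif count matrix between
#' the two collections' enriched-motif sets; (2) positional density
#' profiles of selected own motifs around the foreign regions' peak
#' centres.
#'
#' @param own_motif_sets named list: own cluster -> enriched motif names.
#' @param foreign_motif_sets named list: foreign region -> enriched motif
#'   names (shared namespace with `own_motif_sets`).
#' @param top_motifs named list of [motif_pwm()] to profile.
#' @param foreign_peaks named list: foreign region -> GRanges (or
#'   truth-peak data.frame) of that region's peaks.
#' @param foreign_genome [genome_model()] with sequence for the foreign
#'   peaks; an empty foreign peak set is an error naming the region.
#' @param window,bin passed to [density_profile()].
#' @return list: `share` (matrix), `profiles` (data.frame with `motif`,
#'   `region` and the [density_profile()] columns).
#' @export
compare_motif_landscapes <- function(own_motif_sets, foreign_motif_sets,
                                     top_motifs, foreign_peaks,
                                     foreign_genome,
                                     window = 2000, bin = 20) {
  share <- share_matrix(own_motif_sets, foreign_motif_sets)
  empty <- names(foreign_peaks)[vapply(foreign_peaks, function(p) {
    if (is.data.frame(p)) nrow(p) == 0 else length(p) == 0
  }, logical(1))]
  if (length(empty) > 0)
    stop("empty foreign peak set for region(s): ",
         paste(empty, collapse = ", "))
  profiles <- do.call(rbind, lapply(names(top_motifs), function(mn) {
    do.call(rbind, lapply(names(foreign_peaks), function(rg) {
      cbind(motif = mn, region = rg,
            density_profile(foreign_genome, foreign_peaks[[rg]],
                            top_motifs[[mn]], window = window, bin = bin))
    }))
  }))
  list(share = share, profiles = profiles)
}
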