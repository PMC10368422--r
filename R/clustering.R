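#' Hierarchical clustering of samples on accessibility profiles
#'
#' Samples are clustered on the Euclidean distance between their normalized
#' accessibility columns with Ward linkage. The Ward variant is the
#' squared-Euclidean objective ("ward.D2"), the textbook Ward criterion.
#'
#' @param normalized peaks x samples normalized matrix.
#' @return an [stats::hclust] tree over samples.
#' @export
cluster_samples <- function(normalized) {
  if (ncol(normalized) < 2) stop("need at least 2 samples to cluster")
  bad <- which(!is.finite(normalized), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-finite values in normalized matrix at: ",
         paste(sprintf("(%s, %s)",
                       rownames(normalized)[bad[, 1]],
                       colnames(normalized)[bad[, 2]])[seq_len(min(5, nrow(bad)))],
               collapse = ", "))
  stats::hclust(stats::dist(t(normalized)), method = "ward.D2")
}

#' @rdname cluster_samples
#' @param tree hclust tree from [cluster_samples()].
#' @param k number of flat clusters to cut into.
#' @export
cut_samples <- function(tree, k) stats::cutree(tree, k = k)

## k-means++ seeding: first centre uniform, then D^2-weighted draws
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 == 0)) idx <- sample.int(n, 1)
    else idx <- sample.int(n, 1, prob = d2)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' k-means clustering of atlas peaks (open chromatin regions)
#'
#' Peaks are clustered on their normalized accessibility rows with Lloyd's
#' algorithm from k-means++ starts; the best of `n_restarts` runs by total
#' within-cluster sum of squares is kept. The default `k = 15` follows the
#' standard choice for regional OCR classes in this assay. Cluster labels
#' are relabelled by descending cluster size so label 1 is always the
#' largest cluster. A restart that converges with an empty cluster is
#' re-seeded (and counted).
#'
#' @param normalized peaks x samples normalized matrix.
#' @param k number of clusters (default 15).
#' @param seed integer seed.
#' @param n_restarts number of k-means++ restarts (default 10).
#' @return object of class `ocr_clusters`: list with `labels` (named by
#'   peak id), `k`, `seed`, `wcss`, `sizes`, `centers`.
#' @export
cluster_peaks <- function(normalized, k = 15, seed = 0, n_restarts = 10) {
  if (k > nrow(normalized))
    stop("k (", k, ") exceeds the number of peaks (", nrow(normalized), ")")
  set.seed(seed)
  best <- NULL
  attempts <- 0
  r <- 0
  while (r < n_restarts && attempts < 5 * n_restarts) {
    attempts <- attempts + 1
    km <- suppressWarnings(
      stats::kmeans(normalized, centers = kmeanspp_init(normalized, k),
                    iter.max = 100, algorithm = "Lloyd"))
    if (length(unique(km$cluster)) < k) {
      message("k-means restart produced an empty cluster; re-seeding")
      next
    }
    r <- r + 1
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed to produce ", k,
                          " non-empty clusters")
  ## stable labels: 1 = largest cluster, ties by first appearance
  sizes <- table(best$cluster)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relab <- integer(k)
  relab[as.integer(names(sizes))[ord]] <- seq_len(k)
  labels <- relab[best$cluster]
  names(labels) <- rownames(normalized)
  structure(
    list(labels = labels, k = k, seed = seed, wcss = best$tot.withinss,
         sizes = as.integer(table(labels)),
         centers = best$centers[as.integer(names(sizes))[ord], ,
                                drop = FALSE]),
    class = "ocr_clusters")
}

#' @export
print.ocr_clusters <- function(x, ...) {
  cat(sprintf("ocr_clusters: %d peaks in %d clusters (WCSS %.4g)\n",
              length(x$labels), x$k, x$wcss))
  cat("sizes:", paste(x$sizes, collapse = " "), "\n")
  invisible(x)
}

#' Two-dimensional embedding of sample accessibility profiles
#'
#' @param normalized peaks x samples normalized matrix.
#' @param method `"pca"` (deterministic), `"tsne"` or `"umap"` (seeded).
#' @param perplexity t-SNE perplexity (default 5); must satisfy
#'   `perplexity < (n_samples - 1) / 3`.
#' @param n_neighbors UMAP neighbourhood size (default 7).
#' @param n_components embedding dimension (default 2).
#' @param seed integer seed for the stochastic methods.
#' @return samples x `n_components` coordinate matrix with sample rownames.
#' @export
embed_samples <- function(normalized, method = c("pca", "tsne", "umap"),
                          perplexity = 5, n_neighbors = 7,
                          n_components = 2, seed = 0) {
  method <- match.arg(method)
  x <- t(normalized)
  n <- nrow(x)
  coords <- switch(method,
    pca = {
      p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
      sc <- p$x
      if (ncol(sc) < n_components)   # rank-deficient: pad with zero variance
        sc <- cbind(sc, matrix(0, n, n_components - ncol(sc)))
      sc[, seq_len(n_components), drop = FALSE]
    },
    tsne = {
      if (perplexity >= (n - 1) / 3)
        stop("t-SNE requires perplexity < (n_samples - 1) / 3; got ",
             perplexity, " with ", n, " samples")
      set.seed(seed)
      Rtsne::Rtsne(x, dims = n_components, perplexity = perplexity,
                   check_duplicates = FALSE, pca = FALSE)$Y
    },
    umap = {
      if (n_neighbors >= n)
        stop("UMAP requires n_neighbors < n_samples; got ", n_neighbors,
             " with ", n, " samples")
      set.seed(seed)
      uwot::umap(x, n_neighbors = n_neighbors, n_components = n_components,
                 n_threads = 1)
    })
  rownames(coords) <- colnames(normalized)
  colnames(coords) <- paste0(toupper(method), seq_len(ncol(coords)))
  coords
}

#' Mean pairwise embedded distance from each region to all other regions
#'
#' Diagnostic behind the "distinct region" claim: for each region, the mean
#' Euclidean distance between its samples' embedded coordinates and those
#' of samples from every other region.
#'
#' @param coords samples x 2 embedding from [embed_samples()].
#' @param regions named character vector sample -> region.
#' @return named numeric vector, one mean inter-region distance per region.
#' @export
region_separation <- function(coords, regions) {
  regions <- regions[rownames(coords)]
  d <- as.matrix(stats::dist(coords))
  vapply(unique(regions), function(r) {
    mean(d[regions == r, regions != r])
  }, numeric(1))
}
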