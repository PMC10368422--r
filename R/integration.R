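#' Target genes of a set of OCR clusters
#'
#' The union, over the selected clusters, of the nearest-TSS target genes
#' of their peaks. Peaks without an assigned target contribute nothing.
#'
#' @param annotations data.frame from [assign_targets()].
#' @param clusters an `ocr_clusters` object (or named peak -> label
#'   vector) over the same atlas.
#' @param cluster_ids cluster ids to pool; unknown ids raise an error.
#' @return character vector of unique gene ids.
#' @export
cluster_targets <- function(annotations, clusters, cluster_ids) {
  labels <- if (inherits(clusters, "ocr_clusters")) clusters$labels
  else clusters
  unknown <- setdiff(cluster_ids, unique(labels))
  if (length(unknown) > 0)
    stop("unknown cluster id(s): ", paste(unknown, collapse = ", "))
  peaks <- names(labels)[labels %in% cluster_ids]
  hits <- annotations$target_gene[annotations$peak_id %in% peaks]
  sort(unique(hits[!is.na(hits)]))
}

#' Actively regulated gene fraction
#'
#' The fraction of a preferentially expressed gene set (optionally
#' restricted to a category list such as synaptic genes) that is targeted
#' by the selected OCR clusters: genes both differentially expressed in a
#' region and assigned as nearest-TSS targets of that region's specific
#' open-chromatin clusters are called "actively regulated".
#'
#' @param preferential character vector of preferentially up- or
#'   down-regulated genes (one direction).
#' @param targets gene set from [cluster_targets()].
#' @param category optional category gene list; the universe is then
#'   `preferential` intersected with it.
#' @param direction `"up"` or `"down"` (recorded in the report).
#' @return list: `direction`, `universe`, `targeted` (gene vector),
#'   `n_universe`, `n_targeted`, `fraction` (NA with a `note` when the
#'   universe is empty).
#' @export
active_regulation <- function(preferential, targets, category = NULL,
                              direction = c("up", "down")) {
  direction <- match.arg(direction)
  universe <- if (is.null(category)) unique(preferential)
  else intersect(preferential, category)
  targeted <- intersect(universe, targets)
  res <- list(direction = direction,
              universe = sort(universe), targeted = sort(targeted),
              n_universe = length(universe), n_targeted = length(targeted))
  if (length(universe) == 0) {
    res$fraction <- NA_real_
    res$note <- "empty universe: fraction undefined"
  } else {
    res$fraction <- length(targeted) / length(universe)
    res$note <- ""
  }
  res
}
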