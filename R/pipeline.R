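#' Serialize / restore a ground-truth record
#'
#' Truth records produced by the synthetic generators are plain lists of
#' vectors and data.frames; they round-trip through JSON.
#'
#' @param truth truth list.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  ## named atomic vectors serialize as JSON objects, not bare arrays,
  ## so their names survive the round trip
  listify <- function(x) {
    if (is.data.frame(x)) x
    else if (is.list(x)) lapply(x, listify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(listify(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Default configuration for a small synthetic end-to-end run
#'
#' The returned list is a complete [run_pipeline()] configuration for a
#' desk-scale synthetic cohort: 4 regions x 3 samples over 6 planted peak
#' clusters with one distinct region carrying 2 private clusters, planted
#' QC failures, a 3-condition expression design with planted DE genes
#' coupled to the distinct region's clusters, one planted motif and one
#' planted annotation term. All values are plain scalars/vectors so the
#' config round-trips through YAML.
#'
#' @param out_dir run directory.
#' @param seed global seed; stage seeds are derived as `seed + stage
#'   index`.
#' @return nested configuration list.
#' @export
demo_config <- function(out_dir = tempfile("clonatlas_run_"), seed = 1) {
  list(
    out_dir = out_dir,
    seed = seed,
    genome = list(n_chrom = 2, chrom_length = 4e5, n_genes = 240,
                  gene_length = 800),
    cohort = list(
      regions = list(name = c("Dd2", "Dm", "Dl", "Vv"),
                     n_samples = c(3, 3, 3, 3)),
      n_clusters = 6, distinct_region = "Dd2", n_private = 2,
      depth_range = c(2e4, 4e4), n_fail = 2, frip_target = 0.4,
      peaks_per_cluster = 25, peak_width = 400),
    qc = list(min_fragments = 2e4, min_frip = 0.2),
    clustering = list(k = 6, n_restarts = 10,
                      embed_methods = c("pca", "umap"),
                      perplexity = 3, n_neighbors = 5),
    expression = list(conditions = c("Dd2", "D", "V"), n_de = 60,
                      lfc = 2, dispersion = 0.05, n_reps = 2,
                      coupling = 0.7),
    integration = list(clusters = c(1, 2)),   # truth cluster ids (private)
    motifs = list(consensus = c("TGACGTCATG", "CACGTGACTT", "GGGATTACAG",
                                "TTGCCCAAGG"),
                  planted_motif = 1, planted_cluster = 1,
                  prob = 0.8, offset_sd = 0),
    ora = list(n_terms = 15, term_size = 25),
    xspecies = list(regions = c("isocortex", "HPF", "STR", "TH", "CB"),
                    planted_region = "HPF", fold = 3))
}

stage_seed <- function(config, idx) as.integer(config$seed + idx)

#' Run the full pipeline on a configuration
#'
#' Executes the stages in dependency order — simulate, qc, atlas,
#' clustering, annotation, de, integration, motifs, ora, xspecies —
#' writing each stage's outputs under the run directory and a
#' machine-readable `manifest.json` (package version, global and
#' per-stage seeds, output file digests). A stage failure halts the run
#' with an error naming the stage; outputs of completed stages are
#' retained. Rerunning the same configuration reproduces all outputs
#' byte-identically.
#'
#' @param config configuration list as from [demo_config()], or the path
#'   of a YAML file holding one.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = demo_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(config$out_dir, "config.yaml"))
  env <- new.env(parent = emptyenv())
  stages <- list(
    simulate = stage_simulate, qc = stage_qc, atlas = stage_atlas,
    clustering = stage_clustering, annotation = stage_annotation,
    de = stage_de, integration = stage_integration,
    motifs = stage_motifs, ora = stage_ora, xspecies = stage_xspecies)
  seeds <- stats::setNames(
    vapply(seq_along(stages), function(i) stage_seed(config, i),
           integer(1)), names(stages))
  for (i in seq_along(stages)) {
    nm <- names(stages)[i]
    res <- tryCatch(stages[[i]](config, env, seeds[[nm]]),
                    error = function(e)
                      stop("stage '", nm, "' failed: ", conditionMessage(e),
                           call. = FALSE))
  }
  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(config$out_dir, "manifest.json"))
  manifest <- list(
    package = "clonatlas",
    version = as.character(utils::packageVersion("clonatlas")),
    seed = config$seed, stage_seeds = as.list(seeds),
    outputs = stats::setNames(
      as.list(unname(tools::md5sum(files))),
      sub(paste0("^", config$out_dir, "/?"), "", files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

stage_simulate <- function(config, env, seed) {
  g <- config$genome
  env$genome <- generate_genome(g$n_chrom, g$chrom_length, g$n_genes,
                                seed = seed, gene_length = g$gene_length)
  ch <- config$cohort
  regions <- as.data.frame(ch$regions)
  cmap <- design_cluster_map(regions$name, ch$n_clusters,
                             ch$distinct_region, ch$n_private)
  sim <- generate_cohort(env$genome, regions, ch$n_clusters, cmap,
                         distinct_region = ch$distinct_region,
                         depth_range = unlist(ch$depth_range),
                         n_fail = ch$n_fail, frip_target = ch$frip_target,
                         peaks_per_cluster = ch$peaks_per_cluster,
                         peak_width = ch$peak_width,
                         qc_min_fragments = config$qc$min_fragments,
                         qc_min_frip = config$qc$min_frip, seed = seed)
  env$cohort <- sim$cohort
  env$truth <- sim$truth
  ## plant the motif library's chosen PWM into the chosen truth cluster
  mo <- config$motifs
  env$pwms <- stats::setNames(
    lapply(seq_along(mo$consensus), function(i)
      consensus_pwm(mo$consensus[i], name = sprintf("motif_%02d", i),
                    p = 0.97)),
    sprintf("motif_%02d", seq_along(mo$consensus)))
  pl <- plant_motifs(env$genome, env$truth$peak_clusters,
                     env$pwms[[mo$planted_motif]],
                     clusters = mo$planted_cluster,
                     prob = mo$prob, offset_sd = mo$offset_sd, seed = seed)
  env$genome <- pl$genome
  env$truth$motif <- list(motif = names(env$pwms)[mo$planted_motif],
                          cluster = mo$planted_cluster,
                          peaks = pl$truth)
  ## expression with DE genes coupled to the distinct region's clusters
  ex <- config$expression
  planted <- couple_de_to_clusters(env$genome, env$truth$peak_clusters,
                                   config$integration$clusters,
                                   n = ex$n_de, coupling = ex$coupling,
                                   seed = seed)
  env$expr <- generate_expression(env$genome, conditions = ex$conditions,
                                  lfc = ex$lfc, dispersion = ex$dispersion,
                                  n_reps = ex$n_reps, planted = planted,
                                  seed = seed)
  env$truth$de <- env$expr$truth

  dir <- file.path(config$out_dir, "simulate")
  write_genome(env$genome, dir)
  write_cohort(env$cohort, dir)
  write_counts(env$expr$counts, file.path(dir, "counts.tsv"))
  utils::write.table(env$expr$samples, file.path(dir, "rna_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_truth(env$truth, file.path(dir, "truth.json"))
}

stage_qc <- function(config, env, seed) {
  qc <- qc_filter(sample_qc(env$cohort),
                  min_fragments = config$qc$min_fragments,
                  min_frip = config$qc$min_frip)
  env$qc <- qc
  utils::write.table(qc, file.path(config$out_dir, "qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

stage_atlas <- function(config, env, seed) {
  env$atlas <- build_atlas(env$cohort, env$qc,
                           chromosomes = env$genome$chromosomes)
  write_atlas_bed(env$atlas$atlas, file.path(config$out_dir, "atlas.bed"))
  write_matrix_tsv(env$atlas$raw, file.path(config$out_dir, "raw_counts.tsv"),
                   id_col = "peak_id")
  write_matrix_tsv(env$atlas$normalized,
                   file.path(config$out_dir, "normalized.tsv"),
                   id_col = "peak_id")
}

stage_clustering <- function(config, env, seed) {
  cl <- config$clustering
  env$tree <- cluster_samples(env$atlas$normalized)
  env$peak_clusters <- cluster_peaks(env$atlas$normalized, k = cl$k,
                                     seed = seed,
                                     n_restarts = cl$n_restarts)
  linkage <- data.frame(merge1 = env$tree$merge[, 1],
                        merge2 = env$tree$merge[, 2],
                        height = env$tree$height)
  utils::write.table(linkage, file.path(config$out_dir, "sample_linkage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(peak_id = names(env$peak_clusters$labels),
               cluster = unname(env$peak_clusters$labels)),
    file.path(config$out_dir, "peak_clusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  for (m in cl$embed_methods) {
    emb <- embed_samples(env$atlas$normalized, method = m,
                         perplexity = cl$perplexity,
                         n_neighbors = cl$n_neighbors, seed = seed)
    write_matrix_tsv(emb, file.path(config$out_dir,
                                    paste0("embedding_", m, ".tsv")),
                     id_col = "sample_id")
  }
}

stage_annotation <- function(config, env, seed) {
  ann <- assign_targets(env$atlas$atlas, env$genome)
  ctx <- classify_context(env$atlas$atlas, env$genome)
  env$annotation <- merge(ann, ctx, by = "peak_id")
  utils::write.table(env$annotation,
                     file.path(config$out_dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- cluster_context_profile(ctx, env$peak_clusters)
  write_matrix_tsv(prof, file.path(config$out_dir, "cluster_context.tsv"),
                   id_col = "cluster")
}

stage_de <- function(config, env, seed) {
  conds <- config$expression$conditions
  env$de <- run_contrast(env$expr$counts, env$expr$samples,
                         contrast = c(conds[1], conds[2]))
  utils::write.table(env$de, file.path(config$out_dir,
                                       paste0("de_", conds[1], "_vs_",
                                              conds[2], ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  env$pref <- preferential_sets(env$de)
}

stage_integration <- function(config, env, seed) {
  ## translate truth cluster ids into the k-means labels that carry them:
  ## each truth cluster maps to the k-means label holding most of its peaks
  map <- truth_cluster_label_map(env$truth, env$atlas$atlas,
                                 env$peak_clusters)
  kl <- unique(map[as.character(config$integration$clusters)])
  env$targets <- cluster_targets(env$annotation, env$peak_clusters, kl)
  rep_up <- active_regulation(env$pref$up, env$targets, direction = "up")
  rep_down <- active_regulation(env$pref$down, env$targets,
                                direction = "down")
  env$active <- list(up = rep_up, down = rep_down)
  jsonlite::write_json(env$active,
                       file.path(config$out_dir, "active_regulation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

stage_motifs <- function(config, env, seed) {
  env$motif_table <- cluster_motif_enrichment(
    env$genome, env$truth$peak_clusters,
    stats::setNames(env$truth$peak_clusters$cluster,
                    env$truth$peak_clusters$peak_id),
    env$pwms)
  utils::write.table(env$motif_table,
                     file.path(config$out_dir, "motif_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mo <- config$motifs
  planted_peaks <- env$truth$peak_clusters[
    env$truth$peak_clusters$cluster == mo$planted_cluster, ]
  prof <- density_profile(env$genome, planted_peaks,
                          env$pwms[[mo$planted_motif]])
  utils::write.table(prof, file.path(config$out_dir, "motif_density.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

stage_ora <- function(config, env, seed) {
  universe <- env$de$gene_id[!is.na(env$de$padj)]
  study <- intersect(env$pref$up, universe)
  tm <- generate_terms(universe, n_terms = config$ora$n_terms,
                       term_size = config$ora$term_size,
                       planted_study = study, seed = seed)
  env$truth$term <- tm$truth
  write_gmt(tm$terms, file.path(config$out_dir, "terms.gmt"))
  env$ora <- ora(study, universe, tm$terms)
  utils::write.table(env$ora, file.path(config$out_dir, "ora.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

stage_xspecies <- function(config, env, seed) {
  xs <- config$xspecies
  genes <- env$genome$genes$gene_id
  expr <- generate_atlas_expression(genes, xs$regions,
                                    planted_genes = NULL, seed = seed)
  normd <- normalize_atlas(expr)
  bias <- region_bias(env$pref$up, normd)
  ## motif-sharing of the clustered atlas against itself as the foreign
  ## collection exercises the comparison path with a known answer
  gate <- stats::quantile(env$motif_table$p, 0.25)
  sets <- split(env$motif_table$motif[env$motif_table$p <= gate],
                env$motif_table$cluster[env$motif_table$p <= gate])
  cmp <- compare_motif_landscapes(
    sets, sets, env$pwms[config$motifs$planted_motif],
    foreign_peaks = list(
      own = env$truth$peak_clusters[
        env$truth$peak_clusters$cluster == config$motifs$planted_cluster, ]),
    foreign_genome = env$genome)
  out <- list(region_means = as.list(bias$region_means),
              bias_score = bias$bias_score, argmax = bias$argmax,
              share = cmp$share)
  jsonlite::write_json(out, file.path(config$out_dir, "xspecies.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(cmp$profiles,
                     file.path(config$out_dir, "xspecies_profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Map truth cluster ids to fitted k-means labels
#'
#' Each truth cluster is mapped to the k-means label carrying the
#' majority of its peaks (atlas peaks are matched to truth peaks by
#' overlap).
#'
#' @param truth truth list from [generate_cohort()].
#' @param atlas named GRanges of atlas peaks.
#' @param clusters `ocr_clusters` over the atlas.
#' @return named integer vector truth cluster id -> k-means label.
#' @export
truth_cluster_label_map <- function(truth, atlas, clusters) {
  tp <- truth$peak_clusters
  tgr <- GenomicRanges::GRanges(tp$chrom, IRanges::IRanges(tp$start, tp$end))
  ov <- GenomicRanges::findOverlaps(atlas, tgr)
  truth_of_atlas <- rep(NA_integer_, length(atlas))
  truth_of_atlas[S4Vectors::queryHits(ov)] <- tp$cluster[S4Vectors::subjectHits(ov)]
  labels <- clusters$labels[names(atlas)]
  tab <- table(truth = truth_of_atlas, fitted = labels)
  map <- apply(tab, 1, function(r) as.integer(colnames(tab)[which.max(r)]))
  stats::setNames(as.integer(map), rownames(tab))
}
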