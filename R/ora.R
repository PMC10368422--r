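#' Upper-tail hypergeometric enrichment p-value
#'
#' `P(X >= k)` for `X ~ Hypergeom(N, K, n)`: drawing `n` items from a
#' universe of `N` containing `K` marked ones. The shared tail behind
#' both motif and term enrichment.
#'
#' @param k observed marked items in the draw.
#' @param K marked items in the universe.
#' @param n draw size.
#' @param N universe size.
#' @return the one-sided upper-tail p-value (vectorised).
#' @export
hyper_test <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene set against term annotations
#'
#' Hypergeometric upper-tail test per term: with a universe of `N` genes
#' of which `K` carry the term, and a study set of `n` genes of which `k`
#' carry it, the p-value is `P(X >= k)` for `X ~ Hypergeom(N, K, n)`.
#' Fold enrichment is `(k/n) / (K/N)`. P-values are BH-adjusted across
#' all tested terms and rows are sorted by p. The `displayed` flag marks
#' terms at `FDR < 0.01`, the usual dot-plot display gate.
#'
#' @param study character vector of study genes; must be a subset of the
#'   universe.
#' @param universe character vector of universe genes (e.g. all genes
#'   tested for differential expression).
#' @param terms named list term -> gene ids; annotations are intersected
#'   with the universe and terms smaller than `min_term_size` after
#'   intersection are not tested.
#' @param min_term_size smallest testable term (default 3).
#' @param display_fdr display gate on the BH FDR (default 0.01).
#' @return data.frame: `term`, `k`, `n`, `K`, `N`, `fold_enrichment`,
#'   `p`, `fdr`, `displayed`.
#' @export
ora <- function(study, universe, terms, min_term_size = 3,
                display_fdr = 0.01) {
  study <- unique(study); universe <- unique(universe)
  extra <- setdiff(study, universe)
  if (length(extra) > 0)
    stop("study genes outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "),
         if (length(extra) > 5) sprintf(" (+%d more)", length(extra) - 5))
  N <- length(universe); n <- length(study)
  rows <- lapply(names(terms), function(tm) {
    tg <- intersect(terms[[tm]], universe)
    K <- length(tg)
    if (K < min_term_size) return(NULL)
    k <- length(intersect(study, tg))
    p <- hyper_test(k, K, n, N)
    fe <- if (n == 0 || K == 0) NA_real_ else (k / n) / (K / N)
    data.frame(term = tm, k = k, n = n, K = K, N = N,
               fold_enrichment = fe, p = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0),
                      fold_enrichment = numeric(0), p = numeric(0),
                      fdr = numeric(0), displayed = logical(0)))
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$displayed <- out$fdr < display_fdr
  rownames(out) <- NULL
  out[order(out$p), ]
}

#' Read gene-set annotations from a GMT file
#' @param path GMT path (term, description, genes... per line).
#' @return named list term -> gene ids.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write gene-set annotations as GMT
#' @param terms named list term -> gene ids.
#' @param path GMT path.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(names(terms), function(tm) {
    paste(c(tm, "na", terms[[tm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Generate synthetic term annotations with one planted enriched term
#'
#' Random terms are uniform draws from the gene universe; the planted
#' term, when requested, is built so that a given study set is strongly
#' over-represented in it (a known-truth fixture for the ORA stage).
#'
#' @param genes gene universe.
#' @param n_terms number of random terms.
#' @param term_size genes per term.
#' @param planted_study optional study gene set to plant enrichment for.
#' @param planted_frac fraction of the planted term drawn from the study
#'   set (default 0.8).
#' @param seed integer seed.
#' @return list with `terms` (named list, planted term first when
#'   present, named `"planted_term"`) and `truth` (`planted_term` name or
#'   NULL).
#' @export
generate_terms <- function(genes, n_terms = 20, term_size = 30,
                           planted_study = NULL, planted_frac = 0.8,
                           seed = 1) {
  set.seed(seed)
  terms <- lapply(seq_len(n_terms), function(i)
    sample(genes, min(term_size, length(genes))))
  names(terms) <- sprintf("term_%03d", seq_len(n_terms))
  truth <- NULL
  if (!is.null(planted_study)) {
    n_in <- round(planted_frac * term_size)
    n_in <- min(n_in, length(planted_study))
    pt <- c(sample(planted_study, n_in),
            sample(setdiff(genes, planted_study), term_size - n_in))
    terms <- c(list(planted_term = pt), terms)
    truth <- "planted_term"
  }
  list(terms = terms, truth = truth)
}
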