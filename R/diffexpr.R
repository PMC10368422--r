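#' Median-of-ratios size factors
#'
#' The standard depth normalization for count-based differential
#' expression: each gene's geometric mean across samples is a
#' pseudo-reference, and a sample's factor is the median of its ratios to
#' that reference over genes with nonzero counts in every sample.
#'
#' @param counts genes x samples integer matrix.
#' @return named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene with nonzero counts in all samples; ",
         "size factors need a pseudo-reference gene set")
  lc <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lc)
  sf <- apply(exp(lc - geo), 2, stats::median)
  stats::setNames(sf, colnames(counts))
}

## Newton fit (in eta = log q) of one group's NB mean parameter, where
## mu_ij = sf_j * q_i, for all genes at once. Returns q and the expected
## information of eta, I = sum_j mu/(1 + alpha*mu).
fit_group_q <- function(y, sf, alpha, iters = 15) {
  q <- pmax(rowSums(y) / sum(sf), 1e-10)
  eta <- log(q)
  mu <- denom <- NULL
  for (it in seq_len(iters)) {
    mu <- exp(eta) %o% sf
    denom <- 1 + alpha * mu
    U <- rowSums((y - mu) / denom)
    I <- rowSums(mu / denom)
    step <- pmin(pmax(U / pmax(I, 1e-12), -4), 4)
    eta <- pmin(pmax(eta + step, log(1e-10)), 50)
  }
  mu <- exp(eta) %o% sf
  list(q = exp(eta), info = rowSums(mu / (1 + alpha * mu)), mu = mu)
}

## Cox-Reid adjusted profile log-likelihood of the dispersion, profiled
## over the two group means. The CR term -0.5*log det(X'WX) (here the
## product of the two groups' informations) counters the small-sample
## downward bias of plain ML dispersion.
apl_dispersion <- function(y1, y2, sf1, sf2, alpha) {
  f1 <- fit_group_q(y1, sf1, alpha)
  f2 <- fit_group_q(y2, sf2, alpha)
  size <- 1 / alpha
  ll <- rowSums(stats::dnbinom(y1, mu = f1$mu, size = size, log = TRUE)) +
    rowSums(stats::dnbinom(y2, mu = f2$mu, size = size, log = TRUE))
  ll - 0.5 * (log(pmax(f1$info, 1e-12)) + log(pmax(f2$info, 1e-12)))
}

## Vectorised golden-section maximisation of the adjusted likelihood in
## log(alpha) over [1e-8, 50] (the lower bound is the dispersion floor).
estimate_dispersion <- function(y1, y2, sf1, sf2,
                                lower = 1e-8, upper = 50, iters = 35) {
  G <- nrow(y1)
  phi <- (sqrt(5) - 1) / 2
  a <- rep(log(lower), G); b <- rep(log(upper), G)
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- apl_dispersion(y1, y2, sf1, sf2, exp(x1))
  f2 <- apl_dispersion(y1, y2, sf1, sf2, exp(x2))
  for (it in seq_len(iters)) {
    right <- f1 < f2          # maximum lies right of x1
    a[right] <- x1[right]; x1[right] <- x2[right]; f1[right] <- f2[right]
    x2[right] <- a[right] + phi * (b[right] - a[right])
    left <- !right
    b[left] <- x2[left]; x2[left] <- x1[left]; f2[left] <- f1[left]
    x1[left] <- b[left] - phi * (b[left] - a[left])
    xnew <- ifelse(right, x2, x1)
    fnew <- apl_dispersion(y1, y2, sf1, sf2, exp(xnew))
    f2[right] <- fnew[right]; f1[left] <- fnew[left]
  }
  exp((a + b) / 2)
}

#' Negative binomial Wald test for a two-group contrast
#'
#' Per-gene NB generalized linear model with log link and design
#' `intercept + group`, equivalent here to one mean parameter per group
#' scaled by the sample size factors. The gene-wise dispersion
#' (`Var = mu + alpha * mu^2`) is estimated by Cox-Reid adjusted maximum
#' likelihood with a floor at 1e-8; no shrinkage across genes is applied.
#' The Wald statistic is the log2 fold change over its standard error,
#' referred to a standard normal (two-sided), with Benjamini-Hochberg
#' adjustment across tested genes. Genes with all-zero counts are excluded
#' from testing and from the BH denominator.
#'
#' The reported `log2fc` is the second factor level over the first
#' (so swapping the two labels negates every estimate).
#'
#' @param counts genes x samples integer matrix.
#' @param groups two-level factor (or coercible) over the samples; each
#'   level needs at least 2 samples.
#' @param sf optional per-sample size factors; computed by
#'   [size_factors()] when NULL.
#' @param sig_level BH-adjusted significance gate (default 0.05).
#' @return data.frame (one row per input gene): `gene_id`, `base_mean`,
#'   `log2fc`, `se`, `stat`, `wald_p`, `padj`, `significant`; NA test
#'   columns for untested (all-zero) genes.
#' @export
nb_wald <- function(counts, groups, sf = NULL, sig_level = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) != 2)
    stop("groups must have exactly 2 levels, got ", nlevels(groups))
  if (any(table(groups) < 2))
    stop("each group needs at least 2 samples for a dispersion estimate")
  if (length(groups) != ncol(counts))
    stop("groups length must match the number of samples")
  if (is.null(sf)) sf <- size_factors(counts)
  tested <- rowSums(counts) > 0
  y <- counts[tested, , drop = FALSE]
  i1 <- groups == levels(groups)[1]
  y1 <- y[, i1, drop = FALSE];  sf1 <- sf[i1]
  y2 <- y[, !i1, drop = FALSE]; sf2 <- sf[!i1]

  alpha_mle <- estimate_dispersion(y1, y2, sf1, sf2)
  ## Moderation across genes: with few replicates the per-gene estimate is
  ## noisy and its underestimates inflate the Wald statistic, so each gene's
  ## dispersion is floored at the cohort-wide median estimate. Overestimates
  ## only cost power and are left alone.
  alpha_floor <- stats::median(alpha_mle)
  alpha <- pmax(alpha_mle, alpha_floor)
  fitA <- fit_group_q(y1, sf1, alpha)
  fitB <- fit_group_q(y2, sf2, alpha)
  log2fc <- (log(fitB$q) - log(fitA$q)) / log(2)
  se <- sqrt(1 / pmax(fitA$info, 1e-12) +
             1 / pmax(fitB$info, 1e-12)) / log(2)
  stat <- log2fc / se
  p <- 2 * stats::pnorm(-abs(stat))
  padj <- stats::p.adjust(p, method = "BH")

  out <- data.frame(
    gene_id = rownames(counts),
    base_mean = rowMeans(sweep(counts, 2, sf, "/")),
    log2fc = NA_real_, se = NA_real_, stat = NA_real_,
    wald_p = NA_real_, padj = NA_real_, dispersion = NA_real_)
  out$log2fc[tested] <- log2fc
  out$se[tested] <- se
  out$stat[tested] <- stat
  out$wald_p[tested] <- p
  out$padj[tested] <- padj
  out$dispersion[tested] <- alpha
  out$significant <- !is.na(out$padj) & out$padj < sig_level
  rownames(out) <- NULL
  out
}

#' Significantly up/down gene sets from a DE table
#'
#' For the first-region-versus-rest contrast these are the "preferentially
#' expressed" (up) and "preferentially depleted" (down) sets at the
#' `padj < 0.05` gate: significant genes split by the sign of the log2
#' fold change. The two sets are disjoint by construction.
#'
#' @param de DE table from [nb_wald()].
#' @return list with character vectors `up` and `down`.
#' @export
preferential_sets <- function(de) {
  list(up = de$gene_id[de$significant & !is.na(de$log2fc) & de$log2fc > 0],
       down = de$gene_id[de$significant & !is.na(de$log2fc) & de$log2fc < 0])
}

#' Run one named contrast from a counts matrix and sample sheet
#'
#' @param counts genes x samples matrix.
#' @param samples data.frame (`sample_id`, `condition`).
#' @param contrast length-2 character `c(comparison, reference)`: the
#'   reported log2 fold change is `comparison` over `reference` (so
#'   `c("Dd2", "D")` gives positive values for genes higher in Dd2).
#' @param ... passed to [nb_wald()].
#' @export
run_contrast <- function(counts, samples, contrast, ...) {
  stopifnot(length(contrast) == 2,
            all(contrast %in% samples$condition))
  keep <- samples$condition %in% contrast
  ids <- samples$sample_id[keep]
  nb_wald(counts[, ids, drop = FALSE],
          factor(samples$condition[keep], levels = rev(contrast)), ...)
}
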