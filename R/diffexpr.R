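#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across genes (restricted
#' to genes with a positive geometric mean over all samples) of the ratio of
#' the sample's count to the gene's geometric mean.
#'
#' @param counts Count matrix (genes x samples).
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  .assert_unit(counts, "counts")
  logc <- log(counts)
  loggm <- rowMeans(logc) # -Inf for any gene with a zero
  usable <- is.finite(loggm)
  if (!any(usable)) {
    stop("no gene has nonzero counts in every sample; cannot normalize",
         call. = FALSE)
  }
  sf <- apply(logc[usable, , drop = FALSE], 2, function(lc) {
    exp(stats::median(lc - loggm[usable]))
  })
  stats::setNames(sf, colnames(counts))
}

#' Method-of-moments dispersion estimates
#'
#' On size-factor-normalized counts, estimates the negative-binomial
#' dispersion phi of each gene as `(s^2 - mean) / mean^2`, floored at
#' `floor` (genes whose sample variance does not exceed the mean get the
#' floor).
#'
#' @param counts Count matrix.
#' @param sf Size factors from [size_factors()].
#' @param floor Minimum dispersion returned.
#' @return Named non-negative numeric vector, one phi per gene.
#' @export
estimate_dispersion <- function(counts, sf = size_factors(counts),
                                floor = 1e-8) {
  q <- sweep(counts, 2, sf, "/")
  m <- rowMeans(q)
  v <- apply(q, 1, stats::var)
  phi <- (v - m) / m^2
  phi[!is.finite(phi)] <- floor
  stats::setNames(pmax(floor, phi), rownames(counts))
}

#' Negative-binomial Wald differential expression
#'
#' Group means are estimated on normalized counts; the log2 fold change is
#' `log2(muA + eps) - log2(muB + eps)`; its standard error comes from the
#' delta method applied to the negative-binomial variance
#' `Var(c/s) = mu/s + phi mu^2`; the Wald statistic is referred to the
#' standard normal and p-values are Benjamini-Hochberg adjusted.
#'
#' @param counts Count matrix.
#' @param sf Size factors.
#' @param dispersions Per-gene dispersions (named, covering all genes).
#' @param group_a,group_b Disjoint sample-id vectors (each of size >= 2);
#'   the reported fold change is A relative to B.
#' @param eps Pseudo-mean added inside the log2 to avoid log of zero.
#' @return Data frame with columns `gene`, `baseMean`, `log2FoldChange`,
#'   `lfcSE`, `stat`, `pvalue`, `padj`.
#' @export
nb_wald_test <- function(counts, sf, dispersions, group_a, group_b,
                         eps = 0.5) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups must be disjoint", call. = FALSE)
  }
  if (!all(c(group_a, group_b) %in% colnames(counts))) {
    stop("group sample ids not all present in the count matrix", call. = FALSE)
  }
  phi <- dispersions[rownames(counts)]
  if (anyNA(phi)) stop("dispersions must cover every gene", call. = FALSE)
  q <- sweep(counts, 2, sf, "/")
  qa <- q[, group_a, drop = FALSE]
  qb <- q[, group_b, drop = FALSE]
  na <- length(group_a); nb <- length(group_b)
  mu_a <- rowMeans(qa); mu_b <- rowMeans(qb)
  # Var(mean of c_ij/s_j) = (1/n^2) sum_j (mu/s_j + phi mu^2)
  va <- (mu_a * sum(1 / sf[group_a]) + na * phi * mu_a^2) / na^2
  vb <- (mu_b * sum(1 / sf[group_b]) + nb * phi * mu_b^2) / nb^2
  lfc <- log2(mu_a + eps) - log2(mu_b + eps)
  se <- sqrt(va / ((mu_a + eps)^2 * log(2)^2) +
             vb / ((mu_b + eps)^2 * log(2)^2))
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(gene = rownames(counts),
             baseMean = rowMeans(q[, c(group_a, group_b), drop = FALSE]),
             log2FoldChange = lfc, lfcSE = se, stat = z, pvalue = p,
             padj = bh_adjust(p), row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control with monotonicity, capped at 1.
#'
#' @param p Vector of p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Significantly upregulated genes
#'
#' Volcano-style selection: `log2FoldChange > lfc_min` and raw Wald
#' `pvalue < p_max`. For the downregulated side, call on the negated
#' contrast (swap the groups).
#'
#' @param de Result of [nb_wald_test()].
#' @param lfc_min Fold-change threshold (log2 scale).
#' @param p_max Raw p-value threshold.
#' @return Character vector of gene ids.
#' @export
significant_up <- function(de, lfc_min = 1, p_max = 0.05) {
  stopifnot(lfc_min > 0, p_max > 0)
  de$gene[de$log2FoldChange > lfc_min & de$pvalue < p_max]
}

#' Preranked gene list from a differential expression result
#'
#' Genes ordered by descending ranking statistic; exact ties are broken by
#' lexicographic gene id so the ordering is deterministic.
#'
#' @param de Result of [nb_wald_test()].
#' @param metric Column used as ranking statistic (default the Wald
#'   statistic).
#' @return Named numeric vector of statistics, sorted descending.
#' @export
ranked_list <- function(de, metric = "stat") {
  s <- de[[metric]]
  if (is.null(s)) stop("unknown ranking metric: ", metric, call. = FALSE)
  bad <- !is.finite(s)
  if (any(bad)) {
    stop("non-finite ranking statistic for gene(s): ",
         paste(utils::head(de$gene[bad], 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(de$gene)) stop("duplicate genes in DE result", call. = FALSE)
  ord <- order(-s, de$gene)
  stats::setNames(s[ord], de$gene[ord])
}
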