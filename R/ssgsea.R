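#' Single-sample GSEA scores
#'
#' For each sample, genes are ranked by expression (competition ranking with
#' average ties; exact ties in the ordering are broken by gene id so the
#' walk is deterministic). Walking the genes from highest to lowest
#' expression, the score of a gene set is the sum over all positions of the
#' difference between the weighted in-set empirical CDF (weights
#' `rank^alpha`) and the unweighted out-of-set CDF. Because the statistic
#' depends on ranks only, any strictly increasing transform of a sample's
#' expression leaves its scores unchanged. With `normalize = TRUE` the whole
#' score matrix is divided by its range (max minus min), which couples
#' samples scored together; validation cohorts should therefore be scored
#' within their own matrix.
#'
#' @param tpm Expression matrix (TPM or any within-sample monotone scale).
#' @param sets Named list of gene-id vectors; each must share at least one
#'   gene with the matrix and must not cover all of its genes.
#' @param alpha Rank-weighting exponent.
#' @param normalize Divide scores by the global range of the matrix.
#' @return Numeric matrix, pathways x samples.
#' @export
ssgsea_score <- function(tpm, sets, alpha = 0.25, normalize = TRUE) {
  genes <- rownames(tpm)
  n <- length(genes)
  idx_sets <- lapply(sets, function(s) which(genes %in% s))
  empty <- names(sets)[lengths(idx_sets) == 0]
  if (length(empty) > 0) {
    stop("gene set(s) with no gene in the matrix: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  full <- names(sets)[lengths(idx_sets) == n]
  if (length(full) > 0) {
    stop("gene set(s) covering all genes: ", paste(full, collapse = ", "),
         call. = FALSE)
  }
  scores <- matrix(NA_real_, length(sets), ncol(tpm),
                   dimnames = list(names(sets), colnames(tpm)))
  for (j in seq_len(ncol(tpm))) {
    x <- tpm[, j]
    r <- rank(x, ties.method = "average")
    ord <- order(-x, genes)
    w <- r[ord]^alpha
    for (k in seq_along(idx_sets)) {
      hit <- logical(n)
      hit[idx_sets[[k]]] <- TRUE
      hit <- hit[ord]
      m <- sum(hit)
      cdf_in <- cumsum(w * hit) / sum(w[hit])
      cdf_out <- cumsum(!hit) / (n - m)
      scores[k, j] <- sum(cdf_in - cdf_out)
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  scores
}

#' Welch t-tests with FDR across pathways
#'
#' Per pathway, an unequal-variance two-sided t-test (Welch-Satterthwaite
#' degrees of freedom) comparing responder and nonresponder scores, with
#' Benjamini-Hochberg adjustment across pathways. Degenerate rows (zero
#' pooled variance) report t = 0, p = 1 when the means coincide and the
#' limiting-normal p (0 for any mean difference) otherwise.
#'
#' @param scores Pathway x sample score matrix.
#' @param labels Character vector (`R`/`NR`) aligned with columns.
#' @return Data frame with `pathway`, `t`, `df`, `pvalue`, `fdr`.
#' @export
welch_fdr <- function(scores, labels) {
  stopifnot(ncol(scores) == length(labels))
  a <- labels == "R"; b <- labels == "NR"
  if (sum(a) < 2 || sum(b) < 2) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  res <- t(apply(scores, 1, function(x) {
    xa <- x[a]; xb <- x[b]
    va <- stats::var(xa) / length(xa); vb <- stats::var(xb) / length(xb)
    d <- mean(xa) - mean(xb)
    if (va + vb == 0) {
      if (d == 0) return(c(0, Inf, 1))
      return(c(sign(d) * Inf, Inf, 0))
    }
    tt <- d / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(xa) - 1) + vb^2 / (length(xb) - 1))
    c(tt, df, 2 * stats::pt(-abs(tt), df))
  }))
  data.frame(pathway = rownames(scores), t = res[, 1], df = res[, 2],
             pvalue = res[, 3], fdr = bh_adjust(res[, 3]), row.names = NULL)
}
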