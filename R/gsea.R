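#' Weighted Kolmogorov-Smirnov enrichment score for one gene set
#'
#' Walks the ranked list accumulating `|r|^p / sum_S |r|^p` at gene-set hits
#' and `1/(N - N_hit)` at misses; the enrichment score is the signed maximal
#' deviation of the running sum from zero (ties between the positive and
#' negative extreme resolve to the positive one). The leading edge contains
#' the set members at or before the peak for positive scores, at or after it
#' for negative scores. If every set member has a zero ranking statistic the
#' hit increments fall back to equal weights.
#'
#' @param ranked Named numeric vector sorted in descending order (see
#'   [ranked_list()]).
#' @param geneset Character vector of gene ids.
#' @param p Weighting exponent applied to the ranking statistic.
#' @return List with `es`, `running` (length-N running sum), `peak`
#'   (position of the extreme deviation), and `leading_edge`.
#' @export
gsea_es <- function(ranked, geneset, p = 1) {
  n <- length(ranked)
  hit <- names(ranked) %in% geneset
  m <- sum(hit)
  if (m == 0) stop("gene set has no gene in the ranked list", call. = FALSE)
  if (m == n) stop("gene set covers the entire ranked list", call. = FALSE)
  w <- abs(ranked)^p * hit
  if (sum(w) == 0) w <- as.numeric(hit)
  p_hit <- cumsum(w) / sum(w)
  p_miss <- cumsum(!hit) / (n - m)
  running <- unname(p_hit - p_miss)
  pos_peak <- which.max(running)
  neg_peak <- which.min(running)
  if (running[pos_peak] >= -running[neg_peak]) {
    es <- running[pos_peak]
    peak <- pos_peak
    le <- names(ranked)[hit & seq_len(n) <= peak]
  } else {
    es <- running[neg_peak]
    peak <- neg_peak
    le <- names(ranked)[hit & seq_len(n) >= peak]
  }
  list(es = es, running = running, peak = peak, leading_edge = le)
}

# Enrichment score from sorted hit positions only, O(|S|).
# absw must align with pos (both ordered by increasing position).
.es_from_positions <- function(absw, pos, n) {
  m <- length(pos)
  if (sum(absw) == 0) absw <- rep(1, m)
  cw <- cumsum(absw) / sum(absw)
  drift <- (pos - seq_len(m)) / (n - m)
  at <- cw - drift           # running sum right after each hit
  before <- c(0, cw[-m]) - drift # running sum just before each hit
  max_at <- max(at)
  min_before <- min(before)
  if (max_at >= -min_before) max_at else min_before
}

#' Permutation p-value and normalized enrichment score
#'
#' Null enrichment scores come from gene-set-size-matched random draws from
#' the ranked universe. The p-value counts permuted scores of the same sign
#' at least as extreme as the observed one, with the +1 smoothing that keeps
#' p strictly positive; NES divides the observed score by the mean magnitude
#' of same-sign permuted scores.
#'
#' @inheritParams gsea_es
#' @param n_perm Number of random gene sets (>= 100).
#' @param seed Integer seed.
#' @return List with `es`, `nes`, `pval`, `leading_edge`, `peak`,
#'   `n_same_sign`, and `unstable` (`TRUE` when no permutation matched the
#'   observed sign, in which case `nes` is `NA`).
#' @export
gsea_permutation <- function(ranked, geneset, n_perm = 10000, seed = 1L,
                             p = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  obs <- gsea_es(ranked, geneset, p = p)
  n <- length(ranked)
  m <- sum(names(ranked) %in% geneset)
  absr <- abs(ranked)^p
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_perm), function(b) {
    pos <- sort.int(sample.int(n, m))
    .es_from_positions(absr[pos], pos, n)
  }, numeric(1))
  same <- sign(perm) == sign(obs$es)
  n_same <- sum(same)
  if (n_same == 0) {
    pval <- 1 / (1 + n_perm)
    nes <- NA_real_
    unstable <- TRUE
  } else {
    pval <- (1 + sum(same & abs(perm) >= abs(obs$es))) / (1 + n_same)
    nes <- obs$es / mean(abs(perm[same]))
    unstable <- FALSE
  }
  list(es = obs$es, nes = nes, pval = pval, leading_edge = obs$leading_edge,
       peak = obs$peak, n_same_sign = n_same, unstable = unstable)
}

#' Preranked GSEA over a gene-set collection
#'
#' Runs [gsea_permutation()] for every set with at least `min_size` genes in
#' the ranked list (sets with no overlap, or covering the whole list, are
#' dropped with a warning) and adjusts the permutation p-values by
#' Benjamini-Hochberg across all tested sets.
#'
#' @inheritParams gsea_permutation
#' @param sets Named list of gene-id vectors.
#' @param min_size Minimum overlap with the ranked list.
#' @return Data frame with columns `pathway`, `size`, `es`, `nes`, `pval`,
#'   `padj`, and a list-column `leading_edge`.
#' @export
gsea_collection <- function(ranked, sets, n_perm = 10000, seed = 1L, p = 1,
                            min_size = 1) {
  universe <- names(ranked)
  sizes <- vapply(sets, function(s) sum(universe %in% s), integer(1))
  keep <- sizes >= min_size & sizes < length(universe)
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " gene set(s) with no usable overlap")
  }
  sets <- sets[keep]
  res <- lapply(seq_along(sets), function(k) {
    gsea_permutation(ranked, sets[[k]], n_perm = n_perm,
                     seed = as.integer(seed) + k, p = p)
  })
  out <- data.frame(pathway = names(sets), size = sizes[keep],
                    es = vapply(res, `[[`, 0, "es"),
                    nes = vapply(res, `[[`, 0, "nes"),
                    pval = vapply(res, `[[`, 0, "pval"),
                    row.names = NULL)
  out$padj <- bh_adjust(out$pval)
  out$leading_edge <- I(lapply(res, `[[`, "leading_edge"))
  out
}

#' Select candidate pathways from a GSEA result
#'
#' Keeps positively enriched pathways (`es > 0`) passing the FDR threshold,
#' orders them by descending NES (ties broken by smaller p-value, then
#' name), and truncates to the top `top_k`.
#'
#' @param gsea Data frame from [gsea_collection()].
#' @param fdr_max Adjusted-p threshold.
#' @param top_k Maximum number of candidates retained.
#' @return List of class `candidate_set` with `table` (filtered, ordered
#'   rows) and `leading_edge` (named list of gene vectors).
#' @export
select_candidates <- function(gsea, fdr_max = 0.05, top_k = 15) {
  keep <- gsea$es > 0 & gsea$padj < fdr_max & !is.na(gsea$nes)
  if (!any(keep)) {
    stop(structure(class = c("passig_empty_candidates", "error", "condition"),
                   list(message = paste0(
                     "no pathway passed ES > 0 and FDR < ", fdr_max),
                     call = NULL)))
  }
  sub <- gsea[keep, , drop = FALSE]
  ord <- order(-sub$nes, sub$pval, sub$pathway)
  sub <- sub[utils::head(ord, top_k), , drop = FALSE]
  rownames(sub) <- NULL
  le <- stats::setNames(lapply(sub$leading_edge, identity), sub$pathway)
  structure(list(table = sub, leading_edge = le), class = "candidate_set")
}

#' Write a GSEA result table to TSV
#'
#' The leading-edge list-column is comma-joined.
#'
#' @param gsea Data frame from [gsea_collection()].
#' @param path Output path.
#' @export
write_gsea_result <- function(gsea, path) {
  out <- gsea
  out$leading_edge <- vapply(gsea$leading_edge, paste, "", collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
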