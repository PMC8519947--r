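#' ROC curve and AUC
#'
#' Builds the ROC curve over the unique score thresholds (predicting `R`
#' for scores at or above each threshold) and computes the AUC with the
#' Mann-Whitney concordance formula, which counts ties as half-concordant
#' and equals the trapezoidal area under the curve.
#'
#' @param scores Numeric scores, higher meaning more responder-like.
#' @param labels `"R"`/`"NR"` labels aligned with `scores`.
#' @return `roc_curve` list with `thresholds`, `fpr`, `tpr`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == "R"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes required", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / n0, numeric(1))
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' Confusion-matrix metrics
#'
#' Accuracy and the Matthews correlation coefficient; when any factor of
#' the MCC denominator is zero (e.g. an all-one-class prediction) the MCC
#' is defined as 0.
#'
#' @param pred,truth Aligned `"R"`/`"NR"` label vectors (`R` positive).
#' @return List with `tp`, `fp`, `tn`, `fn`, `accuracy`, `mcc`.
#' @export
confusion_metrics <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("pred and truth must have equal length", call. = FALSE)
  }
  tp <- sum(pred == "R" & truth == "R")
  fp <- sum(pred == "R" & truth == "NR")
  tn <- sum(pred == "NR" & truth == "NR")
  fn <- sum(pred == "NR" & truth == "R")
  n <- tp + fp + tn + fn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / n, mcc = mcc)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Normal approximation with tie correction; the exact null distribution is
#' used for small untied samples (both sizes at most 8). `alternative =
#' "greater"` tests whether `x` is stochastically greater than `y`.
#'
#' @param x,y Numeric vectors.
#' @param alternative `"greater"`, `"less"`, or `"two.sided"`.
#' @return List with `statistic` (the Mann-Whitney U of `x`) and `p.value`.
#' @export
rank_sum_test <- function(x, y,
                          alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) {
    stop("non-empty vectors required", call. = FALSE)
  }
  exact <- min(length(x), length(y)) <= 8 &&
    !any(duplicated(c(x, y)))
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = exact, correct = !exact))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Stratified-resampling comparison of signature AUCs
#'
#' For each of `n_rep` repetitions, samples a fraction of the cohort
#' without replacement, stratified by cohort x class so the responder
#' proportion of every cohort is maintained (per-stratum sizes are rounded
#' up), computes each signature's AUC on the subsample, and compares the
#' target signature's AUC vector against every other signature with a
#' one-sided rank-sum test (alternative: target greater).
#'
#' @param score_table Signatures x samples numeric matrix of scores.
#' @param labels `"R"`/`"NR"` labels per sample.
#' @param strata Cohort labels per sample (a single value is fine).
#' @param n_rep Number of resampling repetitions.
#' @param frac Subsample fraction per stratum.
#' @param seed Integer seed.
#' @param target Row name of the signature being compared (default the
#'   first row).
#' @return `signature_comparison` list with the AUC matrix
#'   (`n_rep` x signatures), per-signature `mean` and `sd`, and the
#'   one-sided `p` versus each comparator.
#' @export
compare_signatures_resampling <- function(score_table, labels, strata,
                                          n_rep = 1000, frac = 0.8,
                                          seed = 1L,
                                          target = rownames(score_table)[1]) {
  if (is.null(rownames(score_table)) || nrow(score_table) < 2) {
    stop("need a named score table with >= 2 signatures", call. = FALSE)
  }
  if (length(strata) == 1) strata <- rep(strata, length(labels))
  key <- paste(strata, labels, sep = "\r")
  groups <- split(seq_along(labels), key)
  for (g in split(labels, strata)) {
    if (length(unique(g)) < 2) {
      stop("every cohort stratum must contain both classes", call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  aucs <- matrix(NA_real_, n_rep, nrow(score_table),
                 dimnames = list(NULL, rownames(score_table)))
  for (b in seq_len(n_rep)) {
    idx <- unlist(lapply(groups, function(g) {
      sample(g, ceiling(frac * length(g)))
    }), use.names = FALSE)
    yl <- labels[idx]
    for (s in rownames(score_table)) {
      aucs[b, s] <- roc_auc(score_table[s, idx], yl)$auc
    }
  }
  others <- setdiff(rownames(score_table), target)
  p <- vapply(others, function(s) {
    rank_sum_test(aucs[, target], aucs[, s], "greater")$p.value
  }, numeric(1))
  structure(list(auc = aucs, mean = colMeans(aucs),
                 sd = apply(aucs, 2, stats::sd), target = target, p = p),
            class = "signature_comparison")
}

#' Scores for published expression signatures
#'
#' Generic scoring engine for literature signatures defined as: `mean` -
#' the mean of `log2(TPM + 1)` over a gene set; `geomean` - the geometric
#' mean of `TPM + 1` (cytolytic-activity style); `ratio` -
#' `log2((TPM_num + 1)/(TPM_den + 1))` of two genes; `pairs` - the count of
#' gene pairs `(a, b)` with expression of `a` below expression of `b`
#' (IMPRES-style). Definitions are supplied as a list (see
#' [read_signature_definitions()] for the bundled, user-editable
#' reconstructions).
#'
#' @param tpm TPM expression matrix.
#' @param definitions Named list; each element has a `type` field plus
#'   `genes` (mean/geomean), `num`/`den` (ratio), or `pairs` (list of
#'   2-vectors).
#' @param max_missing Maximum tolerated fraction of missing genes per
#'   signature before erroring.
#' @return Signatures x samples numeric matrix.
#' @export
published_signature_scores <- function(tpm, definitions, max_missing = 0.5) {
  genes <- rownames(tpm)
  out <- matrix(NA_real_, length(definitions), ncol(tpm),
                dimnames = list(names(definitions), colnames(tpm)))
  for (nm in names(definitions)) {
    d <- definitions[[nm]]
    need <- switch(d$type,
                   mean = , geomean = d$genes,
                   ratio = c(d$num, d$den),
                   pairs = unique(unlist(d$pairs)),
                   stop("unknown signature type: ", d$type, call. = FALSE))
    missing <- setdiff(need, genes)
    if (length(missing) / length(need) > max_missing ||
        (d$type == "ratio" && length(missing) > 0)) {
      stop("signature ", nm, " missing gene(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    out[nm, ] <- switch(d$type,
      mean = colMeans(log2(tpm[intersect(d$genes, genes), , drop = FALSE] + 1)),
      geomean = exp(colMeans(log(tpm[intersect(d$genes, genes), ,
                                     drop = FALSE] + 1))),
      ratio = log2((tpm[d$num, ] + 1) / (tpm[d$den, ] + 1)),
      pairs = {
        keep <- Filter(function(p) all(p %in% genes), d$pairs)
        colSums(do.call(rbind, lapply(keep, function(p) {
          tpm[p[1], ] < tpm[p[2], ]
        })))
      })
  }
  out
}

#' Load published-signature definitions from JSON
#'
#' The package bundles `extdata/published_signatures_reconstruction.json`,
#' a clearly labeled reconstruction of common immune signature gene lists
#' (interferon-gamma, T-cell-inflamed GEP, chemokine, cytolytic activity,
#' MHC-I/II, CD8A/CSF1R ratio, and a checkpoint gene-pair score). The exact
#' published lists live in their source papers; edit this file to match
#' your annotation before drawing comparative conclusions.
#'
#' @param path Path to a definitions JSON; default the bundled file.
#' @return Named list of definitions for [published_signature_scores()].
#' @export
read_signature_definitions <- function(path = system.file(
  "extdata", "published_signatures_reconstruction.json", package = "passig")) {
  defs <- jsonlite::read_json(path, simplifyVector = FALSE)
  defs <- defs[!startsWith(names(defs), "_")] # top-level comments
  lapply(defs, function(d) {
    d$genes <- as.character(unlist(d$genes))
    if (!is.null(d$pairs)) d$pairs <- lapply(d$pairs, as.character)
    d
  })
}
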