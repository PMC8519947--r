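#' Analysis options for PASS signature construction
#'
#' Defaults follow the published workflow: volcano thresholds of
#' log2 fold change 1 at raw p 0.05, GSEA candidate filter ES > 0 at
#' FDR < 0.05 truncated to the top 15 pathways by NES, 10,000 GSEA
#' permutations, ssGSEA exponent 0.25 with range normalization, an equal
#' L1/L2 elastic-net blend, and three-fold cross-validation.
#'
#' @param lfc_min,p_max Volcano thresholds for the upregulated-gene count.
#' @param gsea_fdr_max Adjusted-p threshold for candidate pathways.
#' @param top_k Maximum number of candidate pathways.
#' @param n_perm GSEA permutations.
#' @param gsea_p GSEA weighting exponent.
#' @param ssgsea_alpha ssGSEA rank-weight exponent.
#' @param ssgsea_normalize Range-normalize the ssGSEA matrix.
#' @param alpha_mix Elastic-net mixing parameter.
#' @param n_folds Cross-validation folds.
#' @param ranking_metric DE column used to rank genes for GSEA.
#' @param eps Pseudo-mean for the DE log fold change.
#' @param dispersion_floor Minimum method-of-moments dispersion.
#' @param min_per_class Minimum samples per class required for training.
#' @param seed Integer seed; per-stage seeds are derived from it by fixed
#'   offsets (GSEA: seed + 101, model fit: seed + 202).
#' @return A `pass_options` list.
#' @export
pass_options <- function(lfc_min = 1, p_max = 0.05, gsea_fdr_max = 0.05,
                         top_k = 15, n_perm = 10000, gsea_p = 1,
                         ssgsea_alpha = 0.25, ssgsea_normalize = TRUE,
                         alpha_mix = 0.5, n_folds = 3,
                         ranking_metric = "stat", eps = 0.5,
                         dispersion_floor = 1e-8, min_per_class = 5,
                         seed = 1L) {
  structure(list(lfc_min = lfc_min, p_max = p_max,
                 gsea_fdr_max = gsea_fdr_max, top_k = top_k, n_perm = n_perm,
                 gsea_p = gsea_p, ssgsea_alpha = ssgsea_alpha,
                 ssgsea_normalize = ssgsea_normalize, alpha_mix = alpha_mix,
                 n_folds = n_folds, ranking_metric = ranking_metric,
                 eps = eps, dispersion_floor = dispersion_floor,
                 min_per_class = min_per_class, seed = as.integer(seed)),
            class = "pass_options")
}

#' Weighted-average pathway signature score
#'
#' The PASS score of a sample is the weighted average of its pathway scores
#' with the model effect sizes as weights, normalized by the sum of their
#' absolute values (so positive rescaling of the coefficient vector leaves
#' scores unchanged, and mixed-sign coefficients remain well defined).
#'
#' @param signature A `pass_signature` (or any object with a named `beta`).
#' @param X Pathway x sample score matrix containing every pathway with a
#'   nonzero coefficient.
#' @return Named numeric vector of per-sample scores.
#' @export
pass_score <- function(signature, X) {
  beta <- signature$beta
  bnz <- beta[beta != 0]
  if (length(bnz) == 0) stop("all coefficients are zero", call. = FALSE)
  missing <- setdiff(names(bnz), rownames(X))
  if (length(missing) > 0) {
    stop("score matrix lacks pathway(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  colSums(X[names(bnz), , drop = FALSE] * bnz) / sum(abs(bnz))
}

#' Per-sample odds under the logistic model
#'
#' `odds = exp(a0 + sum_k beta_k x_k) = p/(1-p)` of being a responder.
#' Unlike [pass_score()], odds are not invariant to rescaling the
#' coefficients.
#'
#' @param model An `enlr_model` or `pass_signature` (has `a0` and `beta`).
#' @param X Pathway x sample score matrix.
#' @return Named numeric vector of odds.
#' @export
sample_odds <- function(model, X) {
  beta <- model$beta
  use <- intersect(names(beta)[beta != 0], rownames(X))
  if (!all(names(beta)[beta != 0] %in% rownames(X))) {
    stop("score matrix lacks pathways with nonzero coefficients",
         call. = FALSE)
  }
  eta <- model$a0 + if (length(use) > 0)
    colSums(X[use, , drop = FALSE] * beta[use]) else rep(0, ncol(X))
  exp(eta)
}

#' Youden-index classification cutoff
#'
#' Candidate thresholds are the midpoints of consecutive sorted unique
#' scores plus infinite sentinels; samples scoring strictly above the
#' threshold are called responders. Returns the threshold maximizing
#' J = sensitivity + specificity - 1, breaking ties toward the smallest
#' threshold.
#'
#' @param scores Numeric scores.
#' @param labels `"R"`/`"NR"` labels aligned with `scores`.
#' @return The cutoff value (possibly `-Inf` when all scores tie).
#' @export
youden_cutoff <- function(scores, labels) {
  pos <- labels == "R"
  if (!any(pos) || all(pos)) stop("both classes required", call. = FALSE)
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  j <- vapply(thr, function(t) {
    sens <- mean(scores[pos] > t)
    spec <- mean(scores[!pos] <= t)
    sens + spec - 1
  }, numeric(1))
  thr[which.max(j)] # which.max takes the first (smallest) maximizer
}

.stage_seed <- function(seed, stage) {
  as.integer(seed) + switch(stage, gsea = 101L, enlr = 202L, compare = 303L)
}

.training_samples <- function(samples, counts, timepoint, opts) {
  sub <- samples[samples$timepoint == timepoint &
                 samples$response %in% c("R", "NR"), , drop = FALSE]
  missing <- setdiff(sub$sample_id, colnames(counts))
  if (length(missing) > 0) {
    stop("samples absent from the count matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  tab <- table(sub$response)
  if (length(tab) < 2 || min(tab) < opts$min_per_class) {
    stop("need at least ", opts$min_per_class, " samples per class at ",
         timepoint, call. = FALSE)
  }
  sub
}

.fit_signature <- function(counts, sub, candidates, lengths, opts,
                           timepoint, stages = list()) {
  tpm <- counts_to_tpm(counts[, sub$sample_id, drop = FALSE], lengths)
  ssg <- ssgsea_score(tpm, candidates$leading_edge,
                      alpha = opts$ssgsea_alpha,
                      normalize = opts$ssgsea_normalize)
  model <- fit_enlr(ssg, sub$response, alpha_mix = opts$alpha_mix,
                    n_folds = opts$n_folds,
                    seed = .stage_seed(opts$seed, "enlr"))
  selected <- names(model$beta)[model$beta != 0]
  if (length(selected) > 0) {
    scores <- pass_score(model, ssg)
    cutoff <- youden_cutoff(scores, sub$response)
    auc <- roc_auc(scores, sub$response)$auc
  } else {
    scores <- stats::setNames(rep(0, nrow(sub)), sub$sample_id)
    cutoff <- NA_real_
    auc <- 0.5
  }
  structure(c(list(
    timepoint = timepoint,
    candidates = candidates$table[, c("pathway", "size", "es", "nes",
                                      "pval", "padj")],
    leading_edge = candidates$leading_edge,
    beta = model$beta, a0 = model$a0, selected = selected,
    cutoff = cutoff, alpha_mix = opts$alpha_mix,
    lambda = model$lambda_choice, seed = opts$seed,
    training = list(scores = scores, labels = stats::setNames(
      sub$response, sub$sample_id), auc = auc),
    model = model, options = opts), stages), class = "pass_signature")
}

#' Train a PASS signature at one timepoint
#'
#' Runs the full construction pipeline on the samples of the requested
#' timepoint: responder-vs-nonresponder NB Wald differential expression, a
#' Wald-statistic-ranked gene list, permutation GSEA over the collection,
#' candidate filtering (ES > 0, FDR < threshold, top-k by NES), ssGSEA on
#' the candidates' leading-edge gene sets, and the cost-sensitive
#' elastic-net fit whose nonzero effect sizes define the signature. The
#' Youden cutoff is derived from the training PASS scores.
#'
#' @param counts Count matrix covering the cohort.
#' @param samples Sample table (see [validate_sample_table()]).
#' @param sets Gene-set collection (named list).
#' @param lengths Named gene-length vector for TPM conversion.
#' @param timepoint `"PRE"` or `"ON"`.
#' @param opts A [pass_options()].
#' @return A `pass_signature` with candidate table, leading edges, effect
#'   sizes, intercept, cutoff, training scores, and the underlying
#'   `enlr_model`; the DE and GSEA tables are attached as `de` and `gsea`.
#' @export
train_signature <- function(counts, samples, sets, lengths,
                            timepoint = c("PRE", "ON"),
                            opts = pass_options()) {
  timepoint <- match.arg(timepoint)
  sub <- .training_samples(samples, counts, timepoint, opts)
  cts <- counts[, sub$sample_id, drop = FALSE]
  attr(cts, "unit") <- "counts"
  sf <- size_factors(cts)
  disp <- estimate_dispersion(cts, sf, floor = opts$dispersion_floor)
  de <- nb_wald_test(cts, sf, disp,
                     group_a = sub$sample_id[sub$response == "R"],
                     group_b = sub$sample_id[sub$response == "NR"],
                     eps = opts$eps)
  ranked <- ranked_list(de, metric = opts$ranking_metric)
  gsea <- gsea_collection(ranked, sets, n_perm = opts$n_perm,
                          seed = .stage_seed(opts$seed, "gsea"),
                          p = opts$gsea_p)
  candidates <- select_candidates(gsea, fdr_max = opts$gsea_fdr_max,
                                  top_k = opts$top_k)
  .fit_signature(counts, sub, candidates, lengths, opts, timepoint,
                 stages = list(de = de, gsea = gsea,
                               n_up = length(significant_up(
                                 de, opts$lfc_min, opts$p_max))))
}

#' Train the paired time-response signatures
#'
#' Candidate pathways come from an unpaired differential expression of
#' responder on-treatment versus responder pre-treatment samples followed
#' by GSEA and the usual filter. Two independent elastic-net models are
#' then fit on those shared candidates: one classifying R vs NR among
#' pre-treatment samples, one among on-treatment samples.
#'
#' @inheritParams train_signature
#' @return List with elements `pre` and `on`, both `pass_signature`s
#'   referencing the identical candidate pathway list.
#' @export
train_time_signatures <- function(counts, samples, sets, lengths,
                                  opts = pass_options()) {
  r_pre <- samples$sample_id[samples$response == "R" &
                             samples$timepoint == "PRE"]
  r_on <- samples$sample_id[samples$response == "R" &
                            samples$timepoint == "ON"]
  if (length(r_pre) < 2 || length(r_on) < 2) {
    stop("responders required at both timepoints", call. = FALSE)
  }
  ids <- c(r_pre, r_on)
  cts <- counts[, ids, drop = FALSE]
  attr(cts, "unit") <- "counts"
  sf <- size_factors(cts)
  disp <- estimate_dispersion(cts, sf, floor = opts$dispersion_floor)
  de <- nb_wald_test(cts, sf, disp, group_a = r_on, group_b = r_pre,
                     eps = opts$eps)
  ranked <- ranked_list(de, metric = opts$ranking_metric)
  gsea <- gsea_collection(ranked, sets, n_perm = opts$n_perm,
                          seed = .stage_seed(opts$seed, "gsea"),
                          p = opts$gsea_p)
  candidates <- select_candidates(gsea, fdr_max = opts$gsea_fdr_max,
                                  top_k = opts$top_k)
  out <- lapply(c(PRE = "PRE", ON = "ON"), function(tp) {
    sub <- .training_samples(samples, counts, tp, opts)
    .fit_signature(counts, sub, candidates, lengths, opts, tp,
                   stages = list(de = de, gsea = gsea))
  })
  list(pre = out$PRE, on = out$ON)
}

#' Score a cohort with a trained signature
#'
#' Computes TPM, ssGSEA on the signature's candidate leading-edge sets
#' (range normalization within this cohort's matrix), the PASS score,
#' odds, the predicted class at the training Youden cutoff, and the
#' high/low stratum by mean odds. No refitting happens. Leading-edge genes
#' absent from the cohort are dropped with a warning; a set losing more
#' than half its genes is an error.
#'
#' @param signature A `pass_signature`.
#' @param counts Cohort count matrix (all columns are scored).
#' @param lengths Named gene-length vector.
#' @return Data frame (`sample_id`, `score`, `odds`, `predicted`,
#'   `stratum`) with the ssGSEA matrix attached as attribute `"ssgsea"`.
#' @export
score_cohort <- function(signature, counts, lengths) {
  genes <- rownames(counts)
  le <- lapply(signature$leading_edge, function(s) intersect(s, genes))
  lost <- mapply(function(orig, kept) 1 - length(kept) / length(orig),
                 signature$leading_edge, le)
  if (any(lost > 0.5)) {
    stop("more than half of leading-edge genes missing for: ",
         paste(names(le)[lost > 0.5], collapse = ", "), call. = FALSE)
  }
  if (any(lost > 0)) {
    warning("dropped ", sum(vapply(signature$leading_edge, length, 1L)) -
              sum(vapply(le, length, 1L)),
            " leading-edge gene(s) absent from the cohort")
  }
  tpm <- counts_to_tpm(counts, lengths)
  opts <- signature$options
  ssg <- ssgsea_score(tpm, le, alpha = opts$ssgsea_alpha,
                      normalize = opts$ssgsea_normalize)
  if (length(signature$selected) > 0) {
    score <- pass_score(signature, ssg)
    predicted <- ifelse(score > signature$cutoff, "R", "NR")
  } else {
    warning("signature has no selected pathway; scores are constant")
    score <- stats::setNames(rep(0, ncol(counts)), colnames(counts))
    predicted <- rep(NA_character_, ncol(counts))
  }
  odds <- sample_odds(signature, ssg)
  out <- data.frame(sample_id = colnames(counts), score = unname(score),
                    odds = unname(odds), predicted = predicted,
                    stratum = stratify_by_mean_odds(odds),
                    row.names = NULL)
  attr(out, "ssgsea") <- ssg
  out
}

#' Serialize a PASS signature to JSON
#'
#' Writes the portable part of the signature (candidates, leading edges,
#' effect sizes, intercept, cutoff, options, seed); the fitted glmnet
#' object and training tables are not serialized.
#'
#' @param signature A `pass_signature`.
#' @param path Output path.
#' @export
write_signature <- function(signature, path) {
  core <- list(
    timepoint = signature$timepoint,
    candidates = signature$candidates,
    leading_edge = signature$leading_edge,
    beta = as.list(signature$beta), a0 = signature$a0,
    selected = signature$selected, cutoff = signature$cutoff,
    alpha_mix = signature$alpha_mix, lambda = signature$lambda,
    seed = signature$seed,
    options = unclass(signature$options))
  jsonlite::write_json(core, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a PASS signature from JSON
#' @param path Path written by [write_signature()].
#' @return A `pass_signature`.
#' @export
read_signature <- function(path) {
  core <- jsonlite::read_json(path, simplifyVector = TRUE)
  core$beta <- unlist(core$beta)
  core$leading_edge <- lapply(core$leading_edge, as.character)
  core$options <- do.call(pass_options, core$options)
  structure(core, class = "pass_signature")
}

#' @export
print.pass_signature <- function(x, ...) {
  cat("PASS signature (", x$timepoint, ")\n", sep = "")
  cat("  candidates:", nrow(x$candidates),
      " selected:", length(x$selected), "\n")
  if (length(x$selected) > 0) {
    b <- x$beta[x$selected]
    for (k in seq_along(b)) {
      cat(sprintf("    %-30s %+.4f\n", names(b)[k], b[k]))
    }
  }
  cat("  Youden cutoff:", signif(x$cutoff, 4), "\n")
  invisible(x)
}
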