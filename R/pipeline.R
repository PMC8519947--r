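# End-to-end orchestration: reads standard-format inputs, runs the PASS
# construction/validation/comparison flows, and writes TSV/JSON artifacts
# stamped with a configuration hash and seed so identical configurations
# produce identical outputs.

.config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.read_cohort_files <- function(paths) {
  list(counts = read_counts(paths$counts),
       samples = read_sample_table(paths$samples),
       sets = if (!is.null(paths$gmt)) read_gmt(paths$gmt) else NULL,
       lengths = read_gene_lengths(paths$lengths))
}

.stamp <- function(obj, hash, seed) {
  obj$config_hash <- hash
  obj$seed <- seed
  obj
}

#' Train a PASS signature from files on disk
#'
#' Reads the counts/sample/GMT/length files named in `paths`, runs
#' [train_signature()], and writes the signature JSON, the DE and GSEA
#' tables, the training score table and a JSON report (stage dimensions,
#' candidate and selected pathways, training AUC and cutoff) under
#' `out_dir`.
#'
#' @param paths List with `counts`, `samples`, `gmt`, `lengths` file paths.
#' @param timepoint `"PRE"` or `"ON"`.
#' @param opts A [pass_options()].
#' @param out_dir Output directory.
#' @return The trained `pass_signature`, invisibly; artifacts on disk.
#' @export
run_train <- function(paths, timepoint, opts = pass_options(),
                      out_dir = ".") {
  for (p in unlist(paths)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(list(paths = paths, timepoint = timepoint,
                            opts = unclass(opts)))
  dat <- .read_cohort_files(paths)
  sig <- train_signature(dat$counts, dat$samples, dat$sets, dat$lengths,
                         timepoint = timepoint, opts = opts)
  write_signature(sig, file.path(out_dir, "signature.json"))
  utils::write.table(sig$de, file.path(out_dir, "de.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gsea_result(sig$gsea, file.path(out_dir, "gsea.tsv"))
  utils::write.table(
    data.frame(sample_id = names(sig$training$scores),
               score = unname(sig$training$scores),
               response = unname(sig$training$labels)),
    file.path(out_dir, "training_scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  report <- .stamp(list(
    timepoint = timepoint,
    n_samples = length(sig$training$labels),
    n_genes = nrow(dat$counts),
    n_pathways_tested = nrow(sig$gsea),
    n_genes_up = sig$n_up,
    n_candidates = nrow(sig$candidates),
    selected = sig$selected,
    training_auc = sig$training$auc,
    cutoff = sig$cutoff), hash, opts$seed)
  jsonlite::write_json(report, file.path(out_dir, "train_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sig)
}

#' Validate a trained signature on a cohort
#'
#' Scores the cohort with the training signature (no refitting) and writes
#' the prediction table plus a metrics JSON: AUC, accuracy and MCC at the
#' training cutoff, the one-sided rank-sum p comparing responder and
#' nonresponder scores, and Kaplan-Meier / log-rank / Cox summaries by
#' mean-odds strata for whichever endpoints the sample table carries.
#' Samples without an `R`/`NR` label are scored but excluded from metrics.
#'
#' @param signature A `pass_signature` or path to a signature JSON.
#' @param paths List with `counts`, `samples`, `lengths` file paths.
#' @param timepoint Optional timepoint filter (`"PRE"`/`"ON"`).
#' @param out_dir Output directory.
#' @return List with `predictions` and `metrics`, invisibly.
#' @export
run_validate <- function(signature, paths, timepoint = NULL, out_dir = ".") {
  if (is.character(signature)) signature <- read_signature(signature)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(list(paths = paths, timepoint = timepoint,
                            cutoff = signature$cutoff,
                            beta = as.list(signature$beta)))
  dat <- .read_cohort_files(paths)
  samples <- dat$samples
  if (!is.null(timepoint)) {
    samples <- samples[samples$timepoint == timepoint, , drop = FALSE]
  }
  counts <- dat$counts[, samples$sample_id, drop = FALSE]
  attr(counts, "unit") <- "counts"
  pred <- score_cohort(signature, counts, dat$lengths)
  utils::write.table(pred, file.path(out_dir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- samples$response[match(pred$sample_id, samples$sample_id)]
  use <- lab %in% c("R", "NR")
  metrics <- list(n = nrow(pred), n_labeled = sum(use))
  if (length(unique(lab[use])) == 2) {
    metrics$auc <- roc_auc(pred$score[use], lab[use])$auc
    if (!is.na(signature$cutoff)) {
      cm <- confusion_metrics(pred$predicted[use], lab[use])
      metrics$accuracy <- cm$accuracy
      metrics$mcc <- cm$mcc
    }
    metrics$rank_sum_p <- rank_sum_test(pred$score[use & lab == "R"],
                                        pred$score[use & lab == "NR"],
                                        "greater")$p.value
  } else {
    warning("cohort has a single labeled class; AUC not computed")
  }
  for (ep in c("pfs", "os")) {
    rep_ep <- survival_report(pred, samples, ep)
    if (!is.null(rep_ep)) {
      metrics[[paste0(ep, "_logrank_p")]] <- rep_ep$logrank$p.value
      metrics[[paste0(ep, "_hr_low_vs_high")]] <- rep_ep$cox$hr
      metrics[[paste0(ep, "_hr_ci")]] <- rep_ep$cox$ci
    }
  }
  metrics <- .stamp(metrics, hash, signature$seed)
  jsonlite::write_json(metrics, file.path(out_dir, "validate_metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(predictions = pred, metrics = metrics))
}

#' Compare signature scores across cohorts by stratified resampling
#'
#' Takes per-sample scores for several signatures over one or more cohorts,
#' runs [compare_signatures_resampling()], and writes the per-signature
#' mean/sd AUC table and pairwise p-values.
#'
#' @param score_table Signatures x samples matrix.
#' @param labels,strata Per-sample labels and cohort identifiers.
#' @param n_rep,frac,seed Resampling settings.
#' @param target Signature row compared against the rest.
#' @param out_dir Output directory.
#' @return The `signature_comparison`, invisibly.
#' @export
run_compare <- function(score_table, labels, strata, n_rep = 1000,
                        frac = 0.8, seed = 1L,
                        target = rownames(score_table)[1], out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cmp <- compare_signatures_resampling(score_table, labels, strata,
                                       n_rep = n_rep, frac = frac,
                                       seed = .stage_seed(seed, "compare"),
                                       target = target)
  tab <- data.frame(signature = names(cmp$mean), mean_auc = cmp$mean,
                    sd_auc = cmp$sd, row.names = NULL)
  utils::write.table(tab, file.path(out_dir, "comparison_auc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    .stamp(list(target = target, p = as.list(cmp$p)),
           .config_hash(list(n_rep = n_rep, frac = frac, seed = seed)),
           seed),
    file.path(out_dir, "comparison_p.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(cmp)
}

#' Train and validate in one call
#'
#' Convenience wrapper: trains on the training cohort files at the given
#' timepoint and validates on each cohort in `validation`, writing every
#' artifact under per-step subdirectories of `out_dir`.
#'
#' @param train_paths,validation Named path lists; `validation` is a list
#'   of such lists (one per cohort).
#' @inheritParams run_train
#' @return List with the signature and the per-cohort validation results,
#'   invisibly.
#' @export
run_all <- function(train_paths, validation = list(), timepoint,
                    opts = pass_options(), out_dir = ".") {
  sig <- run_train(train_paths, timepoint, opts,
                   out_dir = file.path(out_dir, "train"))
  vals <- lapply(seq_along(validation), function(i) {
    nm <- names(validation)[i]
    if (is.null(nm) || nm == "") nm <- paste0("cohort", i)
    run_validate(sig, validation[[i]], timepoint = timepoint,
                 out_dir = file.path(out_dir, paste0("validate_", nm)))
  })
  invisible(list(signature = sig, validation = vals))
}
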