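#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix (genes in rows, samples in
#' columns) carrying a `unit` attribute that records whether it holds raw
#' counts or TPM values. Counts must be non-negative integers; TPM values
#' non-negative reals.
#'
#' @param values Numeric matrix with unique rownames (gene identifiers) and
#'   unique colnames (sample identifiers).
#' @param unit Either `"counts"` or `"tpm"`.
#' @return The matrix with a `unit` attribute set, after validation.
#' @export
expression_matrix <- function(values, unit = c("counts", "tpm")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix requires gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate gene identifiers: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    stop("duplicate sample identifiers: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values)) stop("missing values are not allowed", call. = FALSE)
  if (any(values < 0)) stop("expression values must be >= 0", call. = FALSE)
  if (unit == "counts" && any(values != round(values))) {
    stop("count matrix must contain integers only", call. = FALSE)
  }
  attr(values, "unit") <- unit
  values
}

#' Unit tag of an expression matrix
#' @param x Expression matrix.
#' @return `"counts"`, `"tpm"`, or `NULL` when untagged.
#' @export
expression_unit <- function(x) attr(x, "unit")

.assert_unit <- function(x, unit) {
  got <- expression_unit(x)
  if (!is.null(got) && !identical(got, unit)) {
    stop("expected a ", unit, " matrix, got ", got, call. = FALSE)
  }
  invisible(x)
}

#' Convert raw counts to TPM
#'
#' Transcripts per kilobase million: each count is divided by the gene's
#' effective length in kilobases to give a rate, and rates are rescaled
#' within each sample to sum to one million. Every column of the result
#' therefore sums to 1e6.
#'
#' @param counts Count matrix (genes x samples).
#' @param lengths Named numeric vector of effective gene lengths in base
#'   pairs; must cover every gene in `counts` with positive lengths.
#' @return TPM expression matrix of the same dimensions.
#' @export
counts_to_tpm <- function(counts, lengths) {
  .assert_unit(counts, "counts")
  genes <- rownames(counts)
  missing <- setdiff(genes, names(lengths))
  if (length(missing) > 0) {
    stop("no gene length for: ", paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ..." else "", call. = FALSE)
  }
  len <- lengths[genes]
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop("gene lengths must be positive and finite", call. = FALSE)
  }
  zero_col <- colSums(counts) == 0
  if (any(zero_col)) {
    stop("all-zero sample column(s): ",
         paste(colnames(counts)[zero_col], collapse = ", "), call. = FALSE)
  }
  rate <- counts / (len / 1e3)
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  expression_matrix(tpm, unit = "tpm")
}

#' Classify treatment response from RECIST and progression-free survival
#'
#' Complete and partial responses are responders; stable disease is a
#' responder only when progression-free survival exceeds 180 days;
#' progressive disease is a nonresponder; non-evaluable stays `NE`.
#' The 180-day boundary itself is classified as nonresponder (strict
#' inequality for responders).
#'
#' @param recist Character vector of RECIST codes
#'   (`CR`, `PR`, `SD`, `PD`, `NE`).
#' @param pfs_days Numeric vector of progression-free survival in days;
#'   required (non-missing) wherever `recist` is `SD`.
#' @return Character vector with values `R`, `NR`, or `NE`.
#' @export
classify_response <- function(recist, pfs_days = rep(NA_real_, length(recist))) {
  if (length(pfs_days) != length(recist)) {
    stop("recist and pfs_days must have equal length", call. = FALSE)
  }
  valid <- c("CR", "PR", "SD", "PD", "NE")
  bad <- setdiff(unique(recist), valid)
  if (length(bad) > 0) {
    stop("unknown RECIST code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sd_missing <- recist == "SD" & is.na(pfs_days)
  if (any(sd_missing)) {
    stop("SD sample(s) without PFS cannot be labeled (positions ",
         paste(which(sd_missing), collapse = ", "), ")", call. = FALSE)
  }
  out <- rep(NA_character_, length(recist))
  out[recist %in% c("CR", "PR")] <- "R"
  out[recist == "PD"] <- "NR"
  out[recist == "NE"] <- "NE"
  sd <- recist == "SD"
  out[sd] <- ifelse(pfs_days[sd] > 180, "R", "NR")
  out
}
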