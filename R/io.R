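#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a tab-delimited file whose header row names the samples and whose
#' first column holds gene identifiers. Duplicate identifiers, non-numeric
#' cells and ragged rows are rejected with the offending line named.
#'
#' @param path Path to the TSV file.
#' @param unit Unit tag for the returned matrix (`"counts"` or `"tpm"`).
#' @return An [expression_matrix()].
#' @export
read_counts <- function(path, unit = "counts") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop("ragged row at line ", bad, " of ", path, call. = FALSE)
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop("expected gene column plus >=1 sample", call. = FALSE)
  genes <- tab[[1]]
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop("duplicate gene row(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric cell at data line ", bad[1], ", column ",
         colnames(tab)[bad[2] + 1], call. = FALSE)
  }
  if (unit == "counts" && all(num == round(num))) storage.mode(num) <- "integer"
  dimnames(num) <- list(genes, colnames(tab)[-1])
  expression_matrix(num, unit = unit)
}

#' Write a count/TPM matrix to TSV
#'
#' Integer counts are written without decimals so that a read/write
#' round-trip is exact.
#'
#' @param x Expression matrix.
#' @param path Output path.
#' @export
write_counts <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT dialect: one set per line, `name TAB description TAB gene...`.
#' Set order is preserved; duplicate set names and lines with fewer than
#' three fields are errors.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors; descriptions kept in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3)
  if (length(short) > 0) {
    stop("GMT line ", short[1], " has fewer than 3 fields", call. = FALSE)
  }
  nm <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(nm)) {
    dup <- unique(nm[duplicated(nm)])
    stop("duplicate gene-set name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(vapply(fields, `[[`, "", 2), nm)
  sets
}

#' Write a gene-set collection to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = attr(sets, "descriptions")) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("gene sets must have unique names", call. = FALSE)
  }
  if (any(lengths(sets) == 0)) stop("empty gene set(s)", call. = FALSE)
  desc <- if (is.null(descriptions)) rep("", length(sets)) else
    ifelse(is.na(descriptions[names(sets)]), "", descriptions[names(sets)])
  lines <- mapply(function(nm, d, genes) {
    paste(c(nm, d, genes), collapse = "\t")
  }, names(sets), desc, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-length table from TSV
#' @param path Two-column TSV (`gene_id`, `length`).
#' @return Named numeric vector of lengths in base pairs.
#' @export
read_gene_lengths <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "")
  if (ncol(tab) < 2) stop("expected gene_id and length columns", call. = FALSE)
  len <- as.numeric(tab[[2]])
  if (anyNA(len) || any(len <= 0)) {
    stop("gene lengths must be positive numbers", call. = FALSE)
  }
  stats::setNames(len, as.character(tab[[1]]))
}

#' Write a gene-length table to TSV
#' @param lengths Named numeric vector of gene lengths.
#' @param path Output path.
#' @export
write_gene_lengths <- function(lengths, path) {
  utils::write.table(
    data.frame(gene_id = names(lengths), length = as.integer(lengths)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.sample_table_required <- c("sample_id", "patient_id", "timepoint", "recist")

#' Validate (and label) a sample annotation table
#'
#' Checks identifier uniqueness, timepoint/RECIST/event-flag domains, and
#' derives the `response` column from RECIST + PFS via [classify_response()]
#' when absent.
#'
#' @param tab Data frame with at least `sample_id`, `patient_id`,
#'   `timepoint`, `recist`; optionally `cohort`, `pfs_days`, `pfs_event`,
#'   `os_days`, `os_event`, `response`.
#' @return The validated data frame with a populated `response` column.
#' @export
validate_sample_table <- function(tab) {
  missing <- setdiff(.sample_table_required, names(tab))
  if (length(missing) > 0) {
    stop("sample table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample_id(s): ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(tab$timepoint %in% c("PRE", "ON"))) {
    stop("timepoint must be PRE or ON", call. = FALSE)
  }
  for (col in c("pfs_event", "os_event")) {
    if (col %in% names(tab)) {
      v <- tab[[col]]
      if (!all(is.na(v) | v %in% c(0, 1))) {
        stop(col, " must be 0/1 or missing", call. = FALSE)
      }
    }
  }
  for (col in c("pfs_days", "os_days")) {
    if (col %in% names(tab) && any(tab[[col]] < 0, na.rm = TRUE)) {
      stop(col, " must be non-negative", call. = FALSE)
    }
  }
  if (!"response" %in% names(tab)) {
    pfs <- if ("pfs_days" %in% names(tab)) tab$pfs_days else
      rep(NA_real_, nrow(tab))
    tab$response <- classify_response(tab$recist, pfs)
  } else {
    if (!all(tab$response %in% c("R", "NR", "NE"))) {
      stop("response must be R, NR or NE", call. = FALSE)
    }
    if (any(tab$recist == "NE" & tab$response != "NE")) {
      stop("response must be NE when recist is NE", call. = FALSE)
    }
  }
  tab
}

#' Read a sample annotation table from TSV
#' @param path Path to the TSV file.
#' @return Validated data frame (see [validate_sample_table()]).
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  validate_sample_table(tab)
}

#' Write a sample annotation table to TSV
#' @param tab Sample table data frame.
#' @param path Output path.
#' @export
write_sample_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
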