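# Readers/writers for the delimited-text formats the tool consumes and
# produces. No binary formats: TSV/CSV in, tidy TSV with a plain-text
# reproducibility header out.

.sep_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a marker matrix from delimited text
#'
#' Reads a TSV (default) or CSV (by extension) with a header row of
#' identifiers and identifiers in the first column. The EWAS convention —
#' features in rows, samples in columns — is the default orientation; pass
#' `"samples_by_features"` for the transpose (the returned matrix is always
#' features x samples).
#'
#' Cells that fail numeric conversion become missing; any feature with a
#' missing value is dropped (complete-case policy) with a message reporting
#' the count.
#'
#' @param path file path.
#' @param orientation `"features_by_samples"` (default) or
#'   `"samples_by_features"`.
#' @return numeric matrix, features x samples, with feature/sample ids as
#'   dimnames.
#' @export
read_marker_matrix <- function(path,
                               orientation = c("features_by_samples",
                                               "samples_by_features")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) .stop("io", sprintf("file not found: %s", path))
  raw <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    .stop("io", sprintf("empty or malformed matrix file: %s", path))
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    .stop("duplicate_ids", sprintf("duplicate identifiers in %s", path))
  mat <- suppressWarnings(
    vapply(raw[-1L], function(col) as.numeric(col), numeric(nrow(raw))))
  mat <- matrix(mat, nrow = nrow(raw),
                dimnames = list(ids, colnames(raw)[-1L]))
  if (orientation == "samples_by_features") mat <- t(mat)
  bad <- rowSums(is.na(mat)) > 0L
  if (any(bad)) {
    message(sprintf("read_marker_matrix: dropped %d feature(s) with missing values",
                    sum(bad)))
    mat <- mat[!bad, , drop = FALSE]
  }
  if (nrow(mat) == 0L) .stop("io", "no complete features left after filtering")
  mat
}

#' Read a phenotype table
#'
#' Reads a delimited table with sample identifiers (first column unless
#' `sample_id_column` names another), one outcome column and optional
#' covariate columns. A two-level non-numeric outcome is recoded 0/1 (levels
#' in sorted order; mapping reported via a message).
#'
#' @param path file path.
#' @param outcome_column name of the outcome column.
#' @param covariate_columns optional character vector of covariate column
#'   names (must be numeric).
#' @param sample_id_column optional name of the id column (default: first).
#' @return list with `outcome` (numeric), `covariates` (matrix or NULL),
#'   `sample_ids` (character) and `coding` (named 0/1 mapping or NULL).
#' @export
read_phenotype <- function(path, outcome_column, covariate_columns = NULL,
                           sample_id_column = NULL) {
  if (!file.exists(path)) .stop("io", sprintf("file not found: %s", path))
  tab <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  if (is.null(sample_id_column)) sample_id_column <- colnames(tab)[1L]
  for (col in c(sample_id_column, outcome_column, covariate_columns))
    if (!col %in% colnames(tab))
      .stop("io", sprintf("column '%s' not found in %s", col, path))
  sample_ids <- as.character(tab[[sample_id_column]])
  if (anyDuplicated(sample_ids))
    .stop("duplicate_ids", "duplicate sample identifiers in phenotype table")
  out <- tab[[outcome_column]]
  coding <- NULL
  if (!is.numeric(out)) {
    lev <- sort(unique(as.character(out)))
    if (length(lev) != 2L)
      .stop("io", sprintf(
        "outcome column '%s' is non-numeric with %d levels; need numeric or two levels",
        outcome_column, length(lev)))
    coding <- stats::setNames(c(0, 1), lev)
    message(sprintf("read_phenotype: coded outcome '%s' = 0, '%s' = 1",
                    lev[1L], lev[2L]))
    out <- coding[as.character(out)]
  }
  covariates <- NULL
  if (!is.null(covariate_columns)) {
    covariates <- as.matrix(tab[covariate_columns])
    if (!is.numeric(covariates))
      .stop("io", "covariate columns must be numeric")
  }
  list(outcome = as.numeric(out), covariates = covariates,
       sample_ids = sample_ids, coding = coding)
}

#' Assemble a dataset from a marker matrix and a phenotype table
#'
#' Aligns samples by identifier (intersection of marker columns and
#' phenotype rows; order-independent) and applies the complete-case policy
#' across outcome and covariates.
#'
#' @param markers features x samples numeric matrix with sample ids as
#'   column names (e.g. from [read_marker_matrix]).
#' @param phenotype list from [read_phenotype].
#' @return an [ewas_dataset].
#' @export
assemble_dataset <- function(markers, phenotype) {
  common <- intersect(colnames(markers), phenotype$sample_ids)
  if (length(common) == 0L)
    .stop("io", "no overlapping sample identifiers between markers and phenotype")
  dropped <- ncol(markers) - length(common)
  if (dropped > 0L)
    message(sprintf("assemble_dataset: %d marker sample(s) without phenotype dropped",
                    dropped))
  pidx <- match(common, phenotype$sample_ids)
  out <- phenotype$outcome[pidx]
  cov <- if (is.null(phenotype$covariates)) NULL
         else phenotype$covariates[pidx, , drop = FALSE]
  keep <- !is.na(out)
  if (!is.null(cov)) keep <- keep & rowSums(is.na(cov)) == 0L
  if (any(!keep))
    message(sprintf("assemble_dataset: %d sample(s) with missing phenotype dropped",
                    sum(!keep)))
  common <- common[keep]
  ewas_dataset(markers[, common, drop = FALSE], out[keep],
               covariates = if (is.null(cov)) NULL else cov[keep, , drop = FALSE],
               sample_ids = common)
}

#' Write a results table with a reproducibility header
#'
#' Writes tab-separated results sorted by ascending p-value, preceded by
#' `#`-prefixed metadata lines (software version plus whatever key-value
#' pairs are supplied: seed, method, k, adjustment, thresholds). Re-readable
#' with [read_results].
#'
#' @param results a result data.frame (from [robust_ewas],
#'   [full_sample_ewas], [split_half_replication] or a simulation study).
#' @param path output path.
#' @param metadata named list written into the header.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, metadata = list()) {
  pcol <- intersect(c("p_meta", "p", "p_discovery"), names(results))[1L]
  df <- as.data.frame(results)
  if (!is.na(pcol)) df <- df[order(df[[pcol]]), , drop = FALSE]
  meta <- c(list(software = paste0("robustewas ",
                                   as.character(utils::packageVersion("robustewas")))),
            metadata)
  hdr <- sprintf("# %s: %s", names(meta),
                 vapply(meta, function(v) paste(format(v), collapse = " "),
                        character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results]
#'
#' @param path file path.
#' @return data.frame with the header metadata attached as attribute
#'   `"metadata"` (named character vector).
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- NULL
  if (length(hdr)) {
    kv <- sub("^# *", "", lines[hdr])
    keys <- sub(":.*$", "", kv)
    vals <- sub("^[^:]*: *", "", kv)
    meta <- stats::setNames(vals, keys)
  }
  df <- utils::read.table(text = lines[setdiff(seq_along(lines), hdr)],
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "metadata") <- meta
  df
}
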