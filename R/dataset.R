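#' Assemble an E/TWAS dataset
#'
#' Bundles a marker matrix (features x samples), an outcome vector and an
#' optional covariate matrix into a validated container used by all
#' association functions. Markers are methylation beta values, expression
#' levels or any other per-sample quantitative marker; the outcome is a
#' continuous phenotype or a binary (0/1) case/control indicator.
#'
#' All inputs must be complete: missing-value handling (complete-case
#' filtering) is the file readers' responsibility, never performed silently
#' here or inside a fit.
#'
#' @param markers numeric matrix, m features x n samples.
#' @param outcome numeric vector of length n; a binary outcome must be coded
#'   0/1 (two distinct values).
#' @param covariates optional numeric matrix, n samples x c covariates.
#' @param sample_ids,feature_ids optional character identifiers; taken from
#'   `dimnames(markers)` when present, generated otherwise. Must be unique.
#' @return An object of class `ewas_dataset`: a list with elements
#'   `markers`, `outcome`, `covariates`, `sample_ids`, `feature_ids`.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(20), nrow = 4)
#' d <- ewas_dataset(m, outcome = rnorm(5))
#' d
#' @export
ewas_dataset <- function(markers, outcome, covariates = NULL,
                         sample_ids = NULL, feature_ids = NULL) {
  if (!is.matrix(markers) || !is.numeric(markers))
    .stop("bad_input", "`markers` must be a numeric matrix (features x samples)")
  n <- ncol(markers)
  m <- nrow(markers)
  if (length(outcome) != n)
    .stop("dimension", sprintf(
      "outcome length (%d) does not match number of samples (%d)",
      length(outcome), n))
  if (!is.numeric(outcome))
    .stop("bad_input", "`outcome` must be numeric (binary outcomes coded 0/1)")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (!is.numeric(covariates))
      .stop("bad_input", "`covariates` must be numeric")
    if (nrow(covariates) != n)
      .stop("dimension", sprintf(
        "covariates have %d rows but there are %d samples",
        nrow(covariates), n))
  }
  if (anyNA(markers) || anyNA(outcome) || (!is.null(covariates) && anyNA(covariates)))
    .stop("missing_values",
          "dataset contains missing values; apply complete-case filtering in the reader first")
  if (is.null(sample_ids)) sample_ids <- colnames(markers)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (is.null(feature_ids)) feature_ids <- rownames(markers)
  if (is.null(feature_ids)) feature_ids <- paste0("feat", seq_len(m))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != n || length(feature_ids) != m)
    .stop("dimension", "identifier lengths do not match the marker matrix")
  if (anyDuplicated(sample_ids))
    .stop("duplicate_ids", "sample_ids are not unique")
  if (anyDuplicated(feature_ids))
    .stop("duplicate_ids", "feature_ids are not unique")
  dimnames(markers) <- list(feature_ids, sample_ids)
  structure(list(markers = markers, outcome = as.numeric(outcome),
                 covariates = covariates, sample_ids = sample_ids,
                 feature_ids = feature_ids),
            class = "ewas_dataset")
}

#' @export
print.ewas_dataset <- function(x, ...) {
  cat(sprintf("ewas_dataset: %d features x %d samples\n",
              length(x$feature_ids), length(x$sample_ids)))
  cat(sprintf("  outcome: %s\n",
              if (.is_binary(x$outcome)) "binary (0/1)" else "continuous"))
  cat(sprintf("  covariates: %d\n",
              if (is.null(x$covariates)) 0L else ncol(x$covariates)))
  invisible(x)
}

#' @export
dim.ewas_dataset <- function(x) dim(x$markers)
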