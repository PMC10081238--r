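# Signed T-to-Z transformation, Stouffer combination and multiple-testing
# adjustment: the meta-analytic core of the robust E/TWAS method.

#' Transform a t statistic into a signed Z statistic
#'
#' Maps a t statistic with `df` residual degrees of freedom to the standard
#' normal quantile with the same one-sided tail probability, preserving sign
#' and (exactly) the two-sided p-value. Computed on the log-probability scale
#' so the mapping stays accurate far into the tails. This exact tail mapping
#' matters because fold-level degrees of freedom are small (fold size minus
#' the number of coefficients), where t and normal tails differ materially;
#' the naive identity z = t would be anticonservative.
#'
#' @param t_stat numeric vector of t statistics (finite).
#' @param df degrees of freedom (scalar or vector, `>= 1`).
#' @return numeric vector of signed Z statistics.
#' @examples
#' t_to_signed_z(2.5, df = 8)
#' @export
t_to_signed_z <- function(t_stat, df) {
  if (length(t_stat) == 0L) .stop("empty_meta", "no t statistics supplied")
  if (any(!is.finite(t_stat)))
    .stop("nonfinite_statistic", "non-finite t statistic cannot be transformed")
  if (any(df < 1)) .stop("bad_input", "`df` must be >= 1")
  log_tail <- stats::pt(abs(t_stat), df, lower.tail = FALSE, log.p = TRUE)
  sign(t_stat) * stats::qnorm(log_tail, lower.tail = FALSE, log.p = TRUE)
}

#' Combine fold-level Z statistics with Stouffer's method
#'
#' `z_meta = sum(w * z) / sqrt(sum(w^2))`. The default weights are all 1:
#' folds are constructed equal-sized, so sqrt(n)-proportional weighting is
#' equivalent up to the unavoidable +/-1 size rounding. Supply `weights` for
#' genuinely uneven folds.
#'
#' @param fold_z numeric vector of signed Z statistics, one per fold.
#' @param weights optional positive weights, same length as `fold_z`.
#' @return list with `z_meta` and the two-sided normal `p_meta`.
#' @examples
#' stouffer_combine(c(1, 1, 1, 1))  # z_meta = 2
#' @export
stouffer_combine <- function(fold_z, weights = NULL) {
  if (length(fold_z) == 0L) .stop("empty_meta", "no fold Z statistics to combine")
  if (is.null(weights)) weights <- rep.int(1, length(fold_z))
  if (length(weights) != length(fold_z))
    .stop("dimension", "`weights` must match `fold_z` in length")
  if (any(weights <= 0)) .stop("bad_input", "weights must all be positive")
  z_meta <- sum(weights * fold_z) / sqrt(sum(weights^2))
  list(z_meta = z_meta,
       p_meta = 2 * stats::pnorm(abs(z_meta), lower.tail = FALSE))
}

#' Multiple-testing adjustment of p-values
#'
#' `bonferroni` gives `min(1, m * p)`; `bh` the Benjamini-Hochberg step-up
#' adjusted values; `none` returns the input.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method one of `"bonferroni"`, `"bh"`, `"none"`.
#' @return adjusted p-values, same length as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh", "none")) {
  method <- match.arg(method)
  if (length(p) && (anyNA(p) || any(p < 0 | p > 1)))
    .stop("domain", "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = switch(method,
                                     bonferroni = "bonferroni",
                                     bh = "BH",
                                     none = "none"))
}

# Per-fold t statistics for every feature of `data` within fold assignment
# `fa`. Returns list(z = m x k matrix of signed Z, t = m x k, df = length-k).
.fold_stats <- function(data, fa, model_orientation) {
  m <- length(data$feature_ids)
  k <- fa$k
  zmat <- matrix(NA_real_, m, k)
  tmat <- matrix(NA_real_, m, k)
  dfs <- integer(k)
  ncov <- if (is.null(data$covariates)) 0L else ncol(data$covariates)
  for (j in seq_len(k)) {
    idx <- which(fa$fold_of_sample == j)
    yj <- data$outcome[idx]
    if (is.null(data$covariates)) {
      ft <- tryCatch(.row_cor_t(data$markers[, idx, drop = FALSE], yj),
                     robustewas_error = function(e)
                       .stop("degenerate_predictor",
                             sprintf("fold %d: %s", j, conditionMessage(e))))
      tmat[, j] <- ft$t
      dfs[j] <- ft$df
    } else {
      cj <- data$covariates[idx, , drop = FALSE]
      for (i in seq_len(m)) {
        st <- tryCatch(
          fit_marker_association(yj, data$markers[i, idx], cj,
                                 model_orientation = model_orientation),
          robustewas_error = function(e)
            .stop("fit_failed", sprintf("feature %s, fold %d: %s",
                                        data$feature_ids[i], j,
                                        conditionMessage(e))))
        tmat[i, j] <- st$t_stat
        dfs[j] <- st$df
      }
    }
    zmat[, j] <- t_to_signed_z(tmat[, j], dfs[j])
  }
  list(z = zmat, t = tmat, df = dfs, ncov = ncov)
}

#' Robust E/TWAS: k-fold association testing with Stouffer meta-analysis
#'
#' The robust association procedure: (i) partition the sample into k equal,
#' non-overlapping folds (stratified on a binary outcome so every fold holds
#' both classes); (ii) run the covariate-adjusted association test separately
#' in each fold, refitting the full model per fold; (iii) transform each
#' fold's T statistic into a signed Z statistic and combine them across folds
#' with Stouffer's method; (iv) adjust the meta-analysis p-values for
#' multiple testing. An outlier or other artefact only contaminates the fold
#' containing it, so its influence on the combined statistic is diluted by a
#' factor `1/sqrt(k)`.
#'
#' With `k = 1` the procedure reduces to the full-sample analysis expressed
#' on the Z scale.
#'
#' @param data an [ewas_dataset].
#' @param k number of folds.
#' @param seed integer seed for the fold assignment.
#' @param adjust multiple-testing method, see [adjust_pvalues].
#' @param weights optional Stouffer weights, length k (default equal).
#' @param folds optional precomputed [partition_folds] result; overrides
#'   `k`/`seed`.
#' @param stratify `NULL` (default: stratify on the outcome when binary),
#'   `FALSE`, or an explicit length-n label vector.
#' @param model_orientation see [fit_marker_association].
#' @return data.frame of class `robust_ewas_result`, one row per feature:
#'   `feature_id`, `z_meta`, `p_meta`, `p_adjusted`, `n_used`, and per-fold
#'   columns `fold_z1..fold_zk`. The fold assignment, seed and fold degrees
#'   of freedom are attached as attributes.
#' @examples
#' fx <- generate_fixture_ewas(m = 5, n = 60, n_true = 1, effect_rho = 0.6,
#'                             seed = 1)
#' robust_ewas(fx$dataset, k = 3, seed = 2)
#' @export
robust_ewas <- function(data, k, seed, adjust = c("bonferroni", "bh", "none"),
                        weights = NULL, folds = NULL, stratify = NULL,
                        model_orientation = c("marker_as_response",
                                              "outcome_as_response")) {
  adjust <- match.arg(adjust)
  model_orientation <- match.arg(model_orientation)
  if (!inherits(data, "ewas_dataset"))
    .stop("bad_input", "`data` must be an ewas_dataset")
  n <- length(data$outcome)
  ncov <- if (is.null(data$covariates)) 0L else ncol(data$covariates)
  if (is.null(folds)) {
    strata <- if (is.null(stratify)) {
      if (.is_binary(data$outcome)) data$outcome else NULL
    } else if (isFALSE(stratify)) NULL else stratify
    folds <- partition_folds(n, k, seed, strata = strata,
                             min_fold_size = ncov + 3L)
  } else {
    if (!inherits(folds, "fold_assignment"))
      .stop("bad_input", "`folds` must come from partition_folds()")
    k <- folds$k
    seed <- folds$seed
  }
  fs <- .fold_stats(data, folds, model_orientation)
  if (is.null(weights)) weights <- rep.int(1, k)
  if (length(weights) != k) .stop("dimension", "`weights` must have length k")
  if (any(weights <= 0)) .stop("bad_input", "weights must all be positive")
  z_meta <- as.vector(fs$z %*% weights) / sqrt(sum(weights^2))
  p_meta <- 2 * stats::pnorm(abs(z_meta), lower.tail = FALSE)
  res <- data.frame(feature_id = data$feature_ids,
                    z_meta = z_meta,
                    p_meta = p_meta,
                    p_adjusted = adjust_pvalues(p_meta, adjust),
                    n_used = n,
                    stringsAsFactors = FALSE)
  zcols <- as.data.frame(fs$z)
  names(zcols) <- paste0("fold_z", seq_len(k))
  res <- cbind(res, zcols)
  attr(res, "fold_assignment") <- folds
  attr(res, "fold_df") <- fs$df
  attr(res, "k") <- k
  attr(res, "seed") <- seed
  attr(res, "adjust") <- adjust
  class(res) <- c("robust_ewas_result", "data.frame")
  res
}
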