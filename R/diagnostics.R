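# Post-hoc quality diagnostics: genomic inflation lambda, MAD-based residual
# outlier flags, and per-feature outlier-sensitivity refits.

#' Genomic inflation factor lambda
#'
#' Ratio of the median of the observed 1-df chi-square association statistics
#' to the null median (`qchisq(0.5, 1)`, about 0.4549). P-values are mapped
#' to chi-square quantiles through the upper tail. A lambda near 1 indicates
#' the bulk of the tests is well calibrated.
#'
#' @param stats_or_p numeric vector of two-sided p-values (in `(0, 1]`) or of
#'   1-df chi-square statistics, per `input_scale`.
#' @param input_scale `"p_value"` (default) or `"chisq1"`.
#' @return scalar lambda.
#' @examples
#' p <- (seq_len(10001) - 0.5) / 10001   # exact null quantile grid
#' inflation_lambda(p)                   # 1 by construction
#' @export
inflation_lambda <- function(stats_or_p, input_scale = c("p_value", "chisq1")) {
  input_scale <- match.arg(input_scale)
  if (length(stats_or_p) == 0L) .stop("empty_input", "no statistics supplied")
  if (anyNA(stats_or_p)) .stop("missing_values", "missing values in input")
  if (input_scale == "p_value") {
    if (any(stats_or_p < 0 | stats_or_p > 1))
      .stop("domain", "p-values must lie in [0, 1]")
    if (any(stats_or_p == 0)) {
      warning("p-values equal to 0 mapped to the largest finite chi-square quantile")
      stats_or_p[stats_or_p == 0] <- .Machine$double.xmin
    }
    chisq <- stats::qchisq(stats_or_p, df = 1, lower.tail = FALSE)
  } else {
    if (any(stats_or_p < 0)) .stop("domain", "chi-square statistics must be >= 0")
    chisq <- stats_or_p
  }
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Flag residual outliers by the MAD criterion
#'
#' Flags observation i when `|r_i - median(r)| / mad(r) > threshold`, where
#' `mad()` carries the 1.4826 normal-consistency constant, so the score is a
#' robust z-score and the default threshold of 3 flags observations more than
#' three robust standard deviations from the centre. If the MAD is zero
#' (degenerate spread) nothing is flagged and a warning is issued.
#'
#' @param residuals numeric vector of model residuals, length >= 4.
#' @param threshold positive cutoff on the robust z-score (default 3).
#' @return logical vector, TRUE where flagged.
#' @examples
#' mad_outlier_flags(c(1, 2, 3, 4, 100))
#' @export
mad_outlier_flags <- function(residuals, threshold = 3) {
  if (length(residuals) < 4L)
    .stop("insufficient_sample", "need at least 4 residuals")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    .stop("bad_input", "`threshold` must be a positive scalar")
  if (anyNA(residuals)) .stop("missing_values", "missing residuals")
  s <- stats::mad(residuals)   # 1.4826 * median absolute deviation
  if (s == 0) {
    warning("MAD of residuals is zero; no outliers flagged")
    return(rep(FALSE, length(residuals)))
  }
  abs(residuals - stats::median(residuals)) / s > threshold
}

#' Outlier-sensitivity refit for a single marker
#'
#' Audits whether a finding is driven by outliers: fits the full
#' covariate-adjusted model, flags residual outliers by the MAD criterion,
#' refits without the flagged samples, and compares the p-values. A finding
#' is marked outlier-driven when removing the flagged observations makes the
#' p-value more than `ratio_cut` times larger (evidence weakens at least
#' 100-fold under the default). The direction of the comparison is part of
#' the output (`p_ratio = p_trimmed / p_full`) so it can be audited.
#'
#' @inheritParams fit_marker_association
#' @param threshold MAD robust-z cutoff passed to [mad_outlier_flags].
#' @param ratio_cut p-value ratio above which the finding is called
#'   outlier-driven (default 100).
#' @param sample_ids optional identifiers reported for flagged samples.
#' @return An object of class `outlier_sensitivity`: list with `p_full`,
#'   `p_trimmed`, `p_ratio`, `n_flagged`, `flagged_ids`, `outlier_driven`.
#' @export
outlier_sensitivity <- function(y, x, covariates = NULL, threshold = 3,
                                ratio_cut = 100, sample_ids = NULL,
                                model_orientation = c("marker_as_response",
                                                      "outcome_as_response")) {
  model_orientation <- match.arg(model_orientation)
  full <- fit_marker_association(y, x, covariates,
                                 model_orientation = model_orientation)
  flags <- if (is.finite(threshold))
    mad_outlier_flags(full$residuals, threshold)
  else rep(FALSE, length(full$residuals))
  if (is.null(sample_ids)) sample_ids <- as.character(seq_along(y))
  if (any(flags)) {
    keep <- !flags
    ncov <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
    if (sum(keep) < ncov + 4L)
      .stop("insufficient_sample",
            "too few samples remain after removing flagged outliers")
    trimmed <- fit_marker_association(
      y[keep], x[keep],
      if (is.null(covariates)) NULL else as.matrix(covariates)[keep, , drop = FALSE],
      model_orientation = model_orientation)
    p_trimmed <- trimmed$p_two_sided
  } else {
    p_trimmed <- full$p_two_sided
  }
  p_ratio <- p_trimmed / full$p_two_sided
  structure(list(p_full = full$p_two_sided,
                 p_trimmed = p_trimmed,
                 p_ratio = p_ratio,
                 n_flagged = sum(flags),
                 flagged_ids = sample_ids[flags],
                 outlier_driven = p_ratio > ratio_cut,
                 threshold = threshold,
                 ratio_cut = ratio_cut),
            class = "outlier_sensitivity")
}

#' @export
print.outlier_sensitivity <- function(x, ...) {
  cat(sprintf(paste0("outlier_sensitivity: p_full = %.3g, p_trimmed = %.3g ",
                     "(%d sample(s) removed)\n"),
              x$p_full, x$p_trimmed, x$n_flagged))
  cat(sprintf("  p_trimmed / p_full = %.3g -> %soutlier-driven (cut %g)\n",
              x$p_ratio, if (x$outlier_driven) "" else "not ", x$ratio_cut))
  invisible(x)
}
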