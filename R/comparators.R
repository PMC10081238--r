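# Baseline strategies the robust k-fold method is evaluated against:
# conventional full-sample analysis and split-half discovery/replication.

#' Full-sample E/TWAS
#'
#' Conventional association analysis: one covariate-adjusted linear test per
#' feature using the entire sample at once, reporting the native t-scale
#' two-sided p-value.
#'
#' @inheritParams robust_ewas
#' @return data.frame, one row per feature: `feature_id`, `beta`, `t_stat`,
#'   `df`, `p`, `p_adjusted`, `n_used`.
#' @export
full_sample_ewas <- function(data, adjust = c("bonferroni", "bh", "none"),
                             model_orientation = c("marker_as_response",
                                                   "outcome_as_response")) {
  adjust <- match.arg(adjust)
  model_orientation <- match.arg(model_orientation)
  if (!inherits(data, "ewas_dataset"))
    .stop("bad_input", "`data` must be an ewas_dataset")
  n <- length(data$outcome)
  m <- length(data$feature_ids)
  if (is.null(data$covariates)) {
    ft <- .row_cor_t(data$markers, data$outcome)
    # beta of the tested coefficient in the requested orientation
    beta <- if (model_orientation == "marker_as_response")
      ft$sxy / ft$syy else ft$sxy / ft$sxx
    t_stat <- ft$t
    df <- rep.int(ft$df, m)
  } else {
    beta <- t_stat <- numeric(m)
    df <- integer(m)
    for (i in seq_len(m)) {
      st <- fit_marker_association(data$outcome, data$markers[i, ],
                                   data$covariates,
                                   model_orientation = model_orientation)
      beta[i] <- st$beta; t_stat[i] <- st$t_stat; df[i] <- st$df
    }
  }
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  res <- data.frame(feature_id = data$feature_ids, beta = beta,
                    t_stat = t_stat, df = df, p = p,
                    p_adjusted = adjust_pvalues(p, adjust),
                    n_used = n, stringsAsFactors = FALSE)
  attr(res, "adjust") <- adjust
  class(res) <- c("full_ewas_result", "data.frame")
  res
}

# One-sided replication p in the discovery direction: tail of t beyond t_rep
# on the side sign_d points to.
.one_sided_rep_p <- function(t_rep, df, sign_d) {
  stats::pt(sign_d * t_rep, df, lower.tail = FALSE)
}

#' Split-half discovery/replication analysis
#'
#' The sample is randomly split into a discovery half and a replication half
#' (sizes differ by at most one; stratified on a binary outcome). Each
#' feature is tested two-sided in the discovery half; features with
#' `p_discovery < alpha_discovery` proceed to a one-sided test in the
#' replication half assuming the discovery direction of effect. A feature is
#' declared only when it passes both stages.
#'
#' @inheritParams robust_ewas
#' @param alpha_discovery two-sided discovery threshold in (0, 1).
#' @param alpha_replication one-sided replication threshold in (0, 1).
#' @return data.frame of class `split_half_result`, one row per feature:
#'   `feature_id`, `p_discovery`, `direction_discovery` (+1/-1),
#'   `tested_in_replication`, `p_replication_one_sided` (NA unless tested)
#'   and `declared`.
#' @export
split_half_replication <- function(data, alpha_discovery = 0.05,
                                   alpha_replication = 0.05, seed,
                                   stratify = NULL,
                                   model_orientation = c("marker_as_response",
                                                         "outcome_as_response")) {
  model_orientation <- match.arg(model_orientation)
  if (!inherits(data, "ewas_dataset"))
    .stop("bad_input", "`data` must be an ewas_dataset")
  if (alpha_discovery <= 0 || alpha_discovery >= 1 ||
      alpha_replication <= 0 || alpha_replication >= 1)
    .stop("domain", "alpha thresholds must lie in (0, 1)")
  n <- length(data$outcome)
  ncov <- if (is.null(data$covariates)) 0L else ncol(data$covariates)
  if (n < 2L * (ncov + 3L))
    .stop("insufficient_sample", "sample too small to split in half and fit")
  strata <- if (is.null(stratify)) {
    if (.is_binary(data$outcome)) data$outcome else NULL
  } else if (isFALSE(stratify)) NULL else stratify
  halves <- partition_folds(n, 2L, seed, strata = strata,
                            min_fold_size = ncov + 3L)
  fs <- .fold_stats(data, halves, model_orientation)
  t_disc <- fs$t[, 1L]; df_disc <- fs$df[1L]
  t_rep <- fs$t[, 2L]; df_rep <- fs$df[2L]
  p_disc <- 2 * stats::pt(abs(t_disc), df_disc, lower.tail = FALSE)
  dir_disc <- ifelse(t_disc >= 0, 1L, -1L)
  tested <- p_disc < alpha_discovery
  p_rep <- rep(NA_real_, length(t_disc))
  p_rep[tested] <- .one_sided_rep_p(t_rep[tested], df_rep, dir_disc[tested])
  declared <- tested & !is.na(p_rep) & p_rep < alpha_replication
  res <- data.frame(feature_id = data$feature_ids,
                    p_discovery = p_disc,
                    direction_discovery = dir_disc,
                    tested_in_replication = tested,
                    p_replication_one_sided = p_rep,
                    declared = declared,
                    stringsAsFactors = FALSE)
  attr(res, "half_assignment") <- halves
  attr(res, "alpha_discovery") <- alpha_discovery
  attr(res, "alpha_replication") <- alpha_replication
  class(res) <- c("split_half_result", "data.frame")
  res
}
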