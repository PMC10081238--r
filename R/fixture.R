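#' Generate a synthetic EWAS-like dataset with known truths
#'
#' Builds a marker matrix with `n_true` features truly correlated with the
#' outcome at `effect_rho` and the remainder null, optionally with shared
#' covariates loading on outcome and markers and with injected outliers, all
#' recorded in a truth table. Deterministic given `seed` (drawn in its own
#' RNG substream).
#'
#' The generator emulates the statistical skeleton of an E/TWAS — a common
#' outcome, many conditionally independent quantitative markers, optional
#' confounding covariates, and point outliers — not array-specific noise
#' (beta-value heteroscedasticity, batch structure, probe cross-reactivity).
#'
#' @param m number of features.
#' @param n number of samples.
#' @param n_true number of truly associated features (`<= m`).
#' @param effect_rho correlation between each true feature's marker core and
#'   the outcome core, before covariate contributions.
#' @param outlier_spec optional list with elements `type` ("univariate" or
#'   "bivariate"), `count`, `magnitude`, and `features` (indices of features
#'   whose marker values are altered). Univariate outliers alter only marker
#'   values of the listed features; bivariate outliers additionally set the
#'   (shared) outcome of the affected individuals to a same-sign extreme.
#' @param covariate_spec optional list with `n_covariates`,
#'   `outcome_loading`, `marker_loading`: standard-normal covariates added
#'   (times their loading) to the outcome and to every marker.
#' @param seed integer seed.
#' @return list with `dataset` (an [ewas_dataset]) and `truth` (data.frame
#'   with `feature_id`, `is_true`, `effect_rho`, `n_outliers`), plus
#'   `outlier_individuals` when outliers were injected.
#' @export
generate_fixture_ewas <- function(m, n, n_true = 0, effect_rho = 0.3,
                                  outlier_spec = NULL, covariate_spec = NULL,
                                  seed = 1) {
  if (n_true > m) .stop("bad_config", "`n_true` cannot exceed `m`")
  if (abs(effect_rho) >= 1) .stop("bad_config", "`effect_rho` must lie in (-1, 1)")
  .with_seed(seed, {
    y0 <- stats::rnorm(n)
    markers <- matrix(stats::rnorm(m * n), nrow = m)
    if (n_true > 0) {
      for (i in seq_len(n_true))
        markers[i, ] <- effect_rho * y0 + sqrt(1 - effect_rho^2) * markers[i, ]
    }
    y <- y0
    covariates <- NULL
    if (!is.null(covariate_spec)) {
      c_ <- covariate_spec$n_covariates %||% 2L
      lo <- covariate_spec$outcome_loading %||% 0.3
      lm_ <- covariate_spec$marker_loading %||% 0.3
      covariates <- matrix(stats::rnorm(n * c_), nrow = n,
                           dimnames = list(NULL, paste0("cov", seq_len(c_))))
      shared <- as.vector(covariates %*% rep.int(1, c_))
      y <- y + lo * shared
      markers <- markers + matrix(lm_ * shared, nrow = m, ncol = n,
                                  byrow = TRUE)
    }
    n_out <- integer(m)
    out_ids <- integer(0)
    if (!is.null(outlier_spec)) {
      cnt <- outlier_spec$count %||% 1L
      mag <- outlier_spec$magnitude %||% 6
      feats <- outlier_spec$features %||% 1L
      type <- match.arg(outlier_spec$type, c("univariate", "bivariate"))
      out_ids <- sample.int(n, cnt)
      s <- sample(c(-1, 1), cnt, replace = TRUE)
      for (f in feats) markers[f, out_ids] <- s * mag
      if (type == "bivariate") y[out_ids] <- s * mag
      n_out[feats] <- as.integer(cnt)
    }
    feature_ids <- sprintf("feat%04d", seq_len(m))
    ds <- ewas_dataset(markers, y, covariates,
                       sample_ids = sprintf("S%04d", seq_len(n)),
                       feature_ids = feature_ids)
    truth <- data.frame(feature_id = feature_ids,
                        is_true = seq_len(m) <= n_true,
                        effect_rho = ifelse(seq_len(m) <= n_true, effect_rho, 0),
                        n_outliers = n_out,
                        stringsAsFactors = FALSE)
    list(dataset = ds, truth = truth, outlier_individuals = out_ids,
         seed = as.integer(seed))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
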