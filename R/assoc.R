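# Single-marker covariate-adjusted linear association testing: the unit
# statistic every other module (k-fold meta-analysis, comparators,
# diagnostics, simulations) is built on.

# Closed-form simple regression of `resp` on `pred` with intercept.
# Exact OLS; used on the covariate-free path where the simulation studies
# make ~10^6 calls. Returns NULL statistics cleanly only for valid input;
# validation lives in fit_marker_association().
.simple_fit <- function(resp, pred) {
  n <- length(resp)
  pm <- mean(pred)
  rm_ <- mean(resp)
  pc <- pred - pm
  sxx <- sum(pc * pc)
  sxy <- sum(pc * resp)          # == sum(pc * (resp - rm_)) since sum(pc) = 0
  beta <- sxy / sxx
  fitted <- rm_ + beta * pc
  res <- resp - fitted
  df <- n - 2L
  sigma2 <- sum(res * res) / df
  se <- sqrt(sigma2 / sxx)
  list(beta = beta, se = se, t = beta / se, df = df, residuals = res)
}

# t statistic of the correlation between y and x (equals the simple-regression
# t in either orientation). Hot path for the simulation studies.
.cor_t <- function(y, x) {
  n <- length(y)
  r <- stats::cor(x, y)
  list(t = r * sqrt((n - 2L) / (1 - r * r)), df = n - 2L)
}

#' Covariate-adjusted single-marker association test
#'
#' Fits an ordinary-least-squares linear model with intercept linking one
#' marker to the outcome, optionally adjusting for covariates, and returns
#' the t test of the marker-outcome coefficient together with the model
#' residuals (used downstream for MAD outlier diagnostics).
#'
#' Under the default orientation `marker_as_response` the model is
#' `marker ~ intercept + outcome + covariates` (the conventional EWAS
#' formulation). With `outcome_as_response` the roles of marker and outcome
#' are swapped. Without covariates the two orientations give the identical
#' t statistic (both equal the correlation t).
#'
#' Binary outcomes are treated as 0/1 numeric regressors. Inputs must be
#' complete cases; row-wise deletion is the caller's job.
#'
#' @param y numeric outcome vector.
#' @param x numeric marker vector, same length as `y`.
#' @param covariates optional numeric matrix, `length(y)` rows.
#' @param model_orientation `"marker_as_response"` (default) or
#'   `"outcome_as_response"`.
#' @return An object of class `assoc_stat`: list with `beta`, `t_stat`,
#'   `df`, `p_two_sided`, `residuals`, `n_used`.
#' @examples
#' fit_marker_association(y = c(1, 3, 2, 4), x = c(0, 1, 2, 3),
#'                        model_orientation = "outcome_as_response")
#' @export
fit_marker_association <- function(y, x, covariates = NULL,
                                   model_orientation = c("marker_as_response",
                                                         "outcome_as_response")) {
  model_orientation <- match.arg(model_orientation)
  n <- length(y)
  if (length(x) != n)
    .stop("dimension", "`y` and `x` have different lengths")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n)
      .stop("dimension", "`covariates` must have one row per sample")
  }
  if (anyNA(y) || anyNA(x) || (!is.null(covariates) && anyNA(covariates)))
    .stop("missing_values", "complete cases required; filter missing values first")

  if (model_orientation == "marker_as_response") {
    resp <- x; tested <- y
  } else {
    resp <- y; tested <- x
  }
  if (stats::var(tested) == 0)
    .stop("degenerate_predictor",
          "tested variable has zero variance; coefficient undefined")

  if (is.null(covariates)) {
    if (n - 2L < 1L)
      .stop("insufficient_sample",
            sprintf("n = %d leaves no residual degrees of freedom", n))
    f <- .simple_fit(resp, tested)
  } else {
    X <- cbind(`(Intercept)` = 1, tested = tested, covariates)
    p <- ncol(X)
    if (n - p < 1L)
      .stop("insufficient_sample",
            sprintf("n = %d with %d coefficients leaves no residual df", n, p))
    qrX <- qr(X)
    if (qrX$rank < p)
      .stop("collinearity", "design matrix is rank deficient (collinear covariates)")
    coefs <- qr.coef(qrX, resp)
    res <- qr.resid(qrX, resp)
    df <- n - p
    sigma2 <- sum(res * res) / df
    ord <- order(qrX$pivot)
    xtxinv <- chol2inv(qr.R(qrX))[ord, ord, drop = FALSE]
    beta <- unname(coefs["tested"])
    se <- sqrt(sigma2 * xtxinv[2L, 2L])
    f <- list(beta = beta, se = se, t = beta / se, df = df, residuals = res)
  }
  structure(list(beta = f$beta,
                 t_stat = f$t,
                 df = as.integer(f$df),
                 p_two_sided = 2 * stats::pt(abs(f$t), f$df, lower.tail = FALSE),
                 residuals = as.numeric(f$residuals),
                 n_used = n,
                 model_orientation = model_orientation),
            class = "assoc_stat")
}

#' @export
print.assoc_stat <- function(x, ...) {
  cat(sprintf("assoc_stat (%s): beta = %.4g, t = %.3f on %d df, p = %.3g (n = %d)\n",
              x$model_orientation, x$beta, x$t_stat, x$df, x$p_two_sided, x$n_used))
  invisible(x)
}

# Vectorised per-feature correlation t statistics: rows of M (features) vs y.
# Exact match to the covariate-free fit_marker_association t for each row.
.row_cor_t <- function(M, y) {
  n <- length(y)
  yc <- y - mean(y)
  syy <- sum(yc * yc)
  Mc <- M - rowMeans(M)
  sxy <- as.vector(Mc %*% yc)
  sxx <- rowSums(Mc * Mc)
  if (any(sxx == 0))
    .stop("degenerate_predictor",
          sprintf("feature(s) with zero variance in this subset: %s",
                  paste(utils::head(which(sxx == 0), 5L), collapse = ", ")))
  r2 <- (sxy * sxy) / (sxx * syy)
  t <- sign(sxy) * sqrt(r2 * (n - 2L) / pmax(1 - r2, .Machine$double.xmin))
  list(t = t, df = n - 2L, sxy = sxy, sxx = sxx, syy = syy)
}
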