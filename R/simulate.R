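# Simulation study: type-I error and power of full-sample, split-half and
# robust k-fold association analysis under no, univariate, and bivariate
# outliers. Data are bivariate-normal (outcome, marker) pairs; outliers are
# injected by REPLACING values so the nominal sample size is preserved.

#' Simulation configuration
#'
#' Collects the design of one simulation experiment. The defaults are the
#' study conditions of the evaluation this package reproduces: 10,000
#' replicates of a single marker at sample size 250; outcome-marker
#' correlation 0 for type-I error (tested at alpha 0.05) or 0.3 for power
#' (tested at alpha 0.001); either five univariate outliers or one
#' concordant bivariate outlier, placed 6 population SDs from the mean; fold
#' counts 2, 5, 10, 20, 25.
#'
#' @param n sample size per replicate.
#' @param n_sims number of Monte-Carlo replicates.
#' @param rho population outcome-marker correlation, `|rho| < 1`.
#' @param n_univariate_outliers outliers altering EITHER the outcome OR the
#'   marker of a distinct individual, never both.
#' @param n_bivariate_outliers outliers altering BOTH variables of the same
#'   individual.
#' @param outlier_magnitude distance of replaced values from the population
#'   mean, in population SDs.
#' @param concordant should bivariate outliers use same-sign extremes (the
#'   hazardous case: they manufacture spurious association)?
#' @param univariate_first which variable the alternating univariate
#'   assignment starts with: `"x"` (marker; default, so five outliers split
#'   3 marker / 2 outcome), `"y"`, or `"random"`.
#' @param alpha significance threshold for counting rejections.
#' @param k_values fold counts for the robust method.
#' @param methods subset of `c("full", "split_half", "robust")`.
#' @param seed integer master seed; the full result is bit-reproducible
#'   given the configuration and seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n = 250, n_sims = 10000, rho = 0,
                       n_univariate_outliers = 0, n_bivariate_outliers = 0,
                       outlier_magnitude = 6, concordant = TRUE,
                       univariate_first = c("x", "y", "random"),
                       alpha = 0.05, k_values = c(2, 5, 10, 20, 25),
                       methods = c("full", "split_half", "robust"),
                       seed = 1) {
  univariate_first <- match.arg(univariate_first)
  methods <- match.arg(methods, several.ok = TRUE)
  if (!.is_count(n) || n < 10) .stop("bad_config", "`n` must be an integer >= 10")
  if (!.is_count(n_sims) || n_sims < 1)
    .stop("bad_config", "`n_sims` must be a positive integer")
  if (abs(rho) >= 1) .stop("bad_config", "`rho` must lie in (-1, 1)")
  if (n_univariate_outliers + n_bivariate_outliers > n)
    .stop("bad_config", "more outliers than samples")
  if (alpha <= 0 || alpha >= 1) .stop("bad_config", "`alpha` must lie in (0, 1)")
  if ("robust" %in% methods && any(k_values > n / 2))
    .stop("bad_config", "each k must be at most n/2")
  structure(list(n = as.integer(n), n_sims = as.integer(n_sims), rho = rho,
                 n_univariate_outliers = as.integer(n_univariate_outliers),
                 n_bivariate_outliers = as.integer(n_bivariate_outliers),
                 outlier_magnitude = outlier_magnitude,
                 concordant = isTRUE(concordant),
                 univariate_first = univariate_first,
                 alpha = alpha, k_values = as.integer(k_values),
                 methods = methods, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw one bivariate-normal outcome/marker pair
#'
#' `y ~ N(0,1)` and `x = rho * y + sqrt(1 - rho^2) * e` with `e ~ N(0,1)`,
#' so `(y, x)` is standard bivariate normal with population correlation
#' `rho`. Draws from the current RNG stream (seed with `set.seed()`).
#'
#' @param n sample size.
#' @param rho population correlation, `|rho| < 1`.
#' @return list with numeric vectors `y` and `x`.
#' @export
generate_pair <- function(n, rho) {
  if (abs(rho) >= 1) .stop("domain", "`rho` must lie in (-1, 1)")
  y <- stats::rnorm(n)
  x <- rho * y + sqrt(1 - rho^2) * stats::rnorm(n)
  list(y = y, x = x)
}

#' Inject univariate outliers
#'
#' Picks `count` distinct individuals; each has EITHER its outcome OR its
#' marker value replaced by a value `magnitude` population SDs from the mean
#' (random sign) — never both variables in the same individual. The
#' variable assignment alternates across the affected individuals, starting
#' with `first` ("x" = marker by default, so count 5 gives 3 marker / 2
#' outcome alterations).
#'
#' @param y,x numeric vectors (standard-normal scale: population mean 0,
#'   SD 1).
#' @param count number of affected individuals.
#' @param magnitude distance from the mean in population SDs.
#' @param first `"x"`, `"y"`, or `"random"`.
#' @return list with modified `y`, `x`, and `affected` (data.frame of
#'   `index` and `variable`).
#' @export
inject_univariate_outliers <- function(y, x, count, magnitude,
                                       first = c("x", "y", "random")) {
  first <- match.arg(first)
  n <- length(y)
  if (count > n) .stop("domain", "`count` exceeds the number of samples")
  if (count == 0L)
    return(list(y = y, x = x,
                affected = data.frame(index = integer(0),
                                      variable = character(0))))
  idx <- sample.int(n, count)
  start_x <- switch(first, x = TRUE, y = FALSE,
                    random = sample(c(TRUE, FALSE), 1L))
  on_x <- rep_len(c(start_x, !start_x), count)
  vals <- sample(c(-1, 1), count, replace = TRUE) * magnitude
  x[idx[on_x]] <- vals[on_x]
  y[idx[!on_x]] <- vals[!on_x]
  list(y = y, x = x,
       affected = data.frame(index = idx,
                             variable = ifelse(on_x, "x", "y"),
                             stringsAsFactors = FALSE))
}

#' Inject bivariate outliers
#'
#' Picks `count` distinct individuals and replaces BOTH their outcome and
#' marker values with extremes `magnitude` population SDs from the mean.
#' Concordant outliers (default) use the same random sign for both
#' variables, which manufactures spurious positive association evidence —
#' the hazardous case; discordant ones use opposite signs.
#'
#' @inheritParams inject_univariate_outliers
#' @param concordant same-sign extremes?
#' @return list with modified `y`, `x`, and `affected` indices.
#' @export
inject_bivariate_outlier <- function(y, x, count, magnitude,
                                     concordant = TRUE) {
  n <- length(y)
  if (count > n) .stop("domain", "`count` exceeds the number of samples")
  if (count == 0L)
    return(list(y = y, x = x, affected = integer(0)))
  idx <- sample.int(n, count)
  s <- sample(c(-1, 1), count, replace = TRUE)
  y[idx] <- s * magnitude
  x[idx] <- if (isTRUE(concordant)) s * magnitude else -s * magnitude
  list(y = y, x = x, affected = idx)
}

# Apply the configured outlier scenario to one replicate.
.apply_outliers <- function(y, x, config) {
  if (config$n_univariate_outliers > 0L) {
    o <- inject_univariate_outliers(y, x, config$n_univariate_outliers,
                                    config$outlier_magnitude,
                                    first = config$univariate_first)
    y <- o$y; x <- o$x
  }
  if (config$n_bivariate_outliers > 0L) {
    o <- inject_bivariate_outlier(y, x, config$n_bivariate_outliers,
                                  config$outlier_magnitude,
                                  concordant = config$concordant)
    y <- o$y; x <- o$x
  }
  list(y = y, x = x)
}

.scenario_label <- function(config) {
  parts <- character(0)
  if (config$n_univariate_outliers > 0L)
    parts <- c(parts, sprintf("univariate%d", config$n_univariate_outliers))
  if (config$n_bivariate_outliers > 0L)
    parts <- c(parts, sprintf("bivariate%d%s", config$n_bivariate_outliers,
                              if (config$concordant) "" else "_discordant"))
  if (!length(parts)) return("none")
  paste0(paste(parts, collapse = "+"), "_mag", config$outlier_magnitude)
}

# Monte-Carlo engine shared by the type-I and power studies.
.run_sim_study <- function(config) {
  n <- config$n
  n_sims <- config$n_sims
  alpha <- config$alpha
  kv <- if ("robust" %in% config$methods) config$k_values else integer(0)
  zcrit <- stats::qnorm(1 - alpha / 2)
  do_full <- "full" %in% config$methods
  do_split <- "split_half" %in% config$methods

  full_rej <- 0L
  robust_rej <- stats::setNames(integer(length(kv)), as.character(kv))
  split_disc <- 0L; split_joint <- 0L

  set.seed(config$seed)
  for (s in seq_len(n_sims)) {
    pair <- generate_pair(n, config$rho)
    d <- .apply_outliers(pair$y, pair$x, config)
    y <- d$y; x <- d$x
    if (do_full) {
      ft <- .cor_t(y, x)
      p <- 2 * stats::pt(abs(ft$t), ft$df, lower.tail = FALSE)
      if (p < alpha) full_rej <- full_rej + 1L
    }
    for (ki in seq_along(kv)) {
      k <- kv[ki]
      fa <- partition_folds(n, k, .draw_seed())
      tv <- numeric(k); dfv <- numeric(k)
      for (j in seq_len(k)) {
        idx <- fa$fold_of_sample == j
        ft <- .cor_t(y[idx], x[idx])
        tv[j] <- ft$t; dfv[j] <- ft$df
      }
      z <- t_to_signed_z(tv, dfv)
      if (abs(sum(z)) / sqrt(k) > zcrit)
        robust_rej[ki] <- robust_rej[ki] + 1L
    }
    if (do_split) {
      fa <- partition_folds(n, 2L, .draw_seed())
      h1 <- fa$fold_of_sample == 1L
      ftd <- .cor_t(y[h1], x[h1])
      p_d <- 2 * stats::pt(abs(ftd$t), ftd$df, lower.tail = FALSE)
      if (p_d < alpha) {
        split_disc <- split_disc + 1L
        ftr <- .cor_t(y[!h1], x[!h1])
        p_r <- .one_sided_rep_p(ftr$t, ftr$df, sign(ftd$t))
        if (p_r < alpha) split_joint <- split_joint + 1L
      }
    }
  }

  scenario <- .scenario_label(config)
  rows <- list()
  mk_row <- function(method, k, metric, count, denom)
    data.frame(method = method, k = k, metric = metric, scenario = scenario,
               alpha = alpha, rate = count / denom,
               se = sqrt((count / denom) * (1 - count / denom) / denom),
               n_used = denom, stringsAsFactors = FALSE)
  if (do_full)
    rows <- c(rows, list(mk_row("full", NA_integer_, "rejection",
                                full_rej, n_sims)))
  for (ki in seq_along(kv))
    rows <- c(rows, list(mk_row("robust", kv[ki], "rejection",
                                robust_rej[ki], n_sims)))
  if (do_split) {
    rows <- c(rows, list(
      mk_row("split_half", NA_integer_, "conditional", split_joint,
             max(split_disc, 1L)),
      mk_row("split_half", NA_integer_, "joint", split_joint, n_sims)))
  }
  res <- do.call(rbind, rows)
  attr(res, "config") <- config
  attr(res, "n_discoveries") <- split_disc
  class(res) <- c("ewas_sim_result", "data.frame")
  res
}

#' Type-I error simulation study
#'
#' Draws `n_sims` null replicates (`rho` must be 0), injects the configured
#' outliers, runs each configured method, and reports empirical rejection
#' rates at `alpha` with Monte-Carlo standard errors. For split-half
#' replication both the conditional replication rate among discoveries (the
#' rate on the alpha scale) and the joint discovery-and-replication rate are
#' reported.
#'
#' @param config a [sim_config] with `rho = 0`.
#' @return data.frame of class `ewas_sim_result` with columns `method`, `k`,
#'   `metric`, `scenario`, `alpha`, `rate`, `se`, `n_used`.
#' @export
run_type1_study <- function(config) {
  if (!inherits(config, "sim_config")) .stop("bad_input", "need a sim_config")
  if (config$rho != 0)
    .stop("bad_config", "type-I study requires rho = 0 (no true association)")
  .run_sim_study(config)
}

#' Power simulation study
#'
#' As [run_type1_study] but with a true outcome-marker correlation
#' (`rho != 0`); a rejection is a correct detection. Power is studied in the
#' absence of outliers and with univariate outliers only — a bivariate
#' outlier on a truly associated marker can push detection either way and is
#' excluded by design.
#'
#' @param config a [sim_config] with `rho != 0` and no bivariate outliers.
#' @return data.frame of class `ewas_sim_result`; for split-half the `joint`
#'   rate (discovered AND replicated) is the power metric.
#' @export
run_power_study <- function(config) {
  if (!inherits(config, "sim_config")) .stop("bad_input", "need a sim_config")
  if (config$rho == 0)
    .stop("bad_config", "power study requires a nonzero rho")
  if (config$n_bivariate_outliers > 0L)
    .stop("bad_config", "bivariate outliers are excluded from the power study")
  .run_sim_study(config)
}

#' @export
print.ewas_sim_result <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Simulation study: n = %d, n_sims = %d, rho = %g, scenario %s\n",
              cfg$n, cfg$n_sims, cfg$rho, .scenario_label(cfg)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot rejection rates from a simulation study
#'
#' Rejection rate against fold count for the robust method, with horizontal
#' reference lines for the full-sample and split-half rates and the nominal
#' alpha.
#'
#' @param x an `ewas_sim_result`.
#' @param ... passed to [plot()].
#' @export
plot.ewas_sim_result <- function(x, ...) {
  cfg <- attr(x, "config")
  rob <- x[x$method == "robust", ]
  full <- x[x$method == "full", ]
  cond <- x[x$method == "split_half" & x$metric == "conditional", ]
  ylim <- range(0, x$rate, cfg$alpha)
  if (nrow(rob)) {
    plot(rob$k, rob$rate, type = "b", pch = 19, xlab = "folds (k)",
         ylab = "rejection rate", ylim = ylim, ...)
  } else {
    plot(1, type = "n", xlab = "", ylab = "rejection rate", ylim = ylim, ...)
  }
  graphics::abline(h = cfg$alpha, lty = 3)
  if (nrow(full)) graphics::abline(h = full$rate, col = 2, lty = 2)
  if (nrow(cond)) graphics::abline(h = cond$rate, col = 4, lty = 2)
  graphics::legend("topright", bty = "n", lty = c(1, 2, 2, 3),
                   col = c(1, 2, 4, 1), pch = c(19, NA, NA, NA),
                   legend = c("robust k-fold", "full sample",
                              "split-half (conditional)", "nominal alpha"))
  invisible(x)
}
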