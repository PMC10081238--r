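# Unit statistic: covariate-adjusted single-marker linear association test.

test_that("simple regression matches the hand-computed closed form and lm", {
  x <- c(0, 1, 2, 3)
  y <- c(1, 3, 2, 4)
  st <- fit_marker_association(y, x, model_orientation = "outcome_as_response")
  # Sxy = 4.0, Sxx = 5.0 -> slope 0.8
  expect_equal(st$beta, 0.8)
  ref <- summary(lm(y ~ x))
  expect_equal(st$t_stat, ref$coefficients["x", "t value"], tolerance = 1e-12)
  expect_equal(st$p_two_sided, ref$coefficients["x", "Pr(>|t|)"],
               tolerance = 1e-12)
  expect_equal(st$df, ref$df[2])
  expect_equal(st$residuals, unname(residuals(lm(y ~ x))), tolerance = 1e-12)
})

test_that("covariate-adjusted fit matches the lm oracle in both orientations", {
  inp <- make_fit_inputs(40, n_cov = 3, seed = 7)
  for (orient in c("marker_as_response", "outcome_as_response")) {
    st <- fit_marker_association(inp$y, inp$x, inp$covariates,
                                 model_orientation = orient)
    resp <- if (orient == "marker_as_response") inp$x else inp$y
    tested <- if (orient == "marker_as_response") inp$y else inp$x
    ref <- summary(lm(resp ~ tested + inp$covariates))
    expect_equal(st$beta, ref$coefficients["tested", "Estimate"],
                 tolerance = 1e-10)
    expect_equal(st$t_stat, ref$coefficients["tested", "t value"],
                 tolerance = 1e-10)
    expect_equal(st$p_two_sided, ref$coefficients["tested", "Pr(>|t|)"],
                 tolerance = 1e-10)
    expect_equal(st$df, ref$df[2])
    expect_identical(st$df, st$n_used - 5L)
    expect_equal(sign(st$t_stat), sign(st$beta))
  }
})

test_that("orientations agree exactly when there are no covariates", {
  for (seed in 1:5) {
    inp <- make_fit_inputs(25, seed = seed)
    t1 <- fit_marker_association(inp$y, inp$x,
                                 model_orientation = "marker_as_response")$t_stat
    t2 <- fit_marker_association(inp$y, inp$x,
                                 model_orientation = "outcome_as_response")$t_stat
    r <- cor(inp$x, inp$y)
    t_cor <- r * sqrt(23 / (1 - r^2))
    expect_equal(t1, t2, tolerance = 1e-12)
    expect_equal(t1, t_cor, tolerance = 1e-12)
  }
})

test_that("permuting sample order leaves the statistic unchanged", {
  inp <- make_fit_inputs(30, n_cov = 2, seed = 3)
  st <- fit_marker_association(inp$y, inp$x, inp$covariates)
  set.seed(4)
  perm <- sample(30)
  stp <- fit_marker_association(inp$y[perm], inp$x[perm],
                                inp$covariates[perm, ])
  expect_equal(stp$t_stat, st$t_stat, tolerance = 1e-10)
  expect_equal(stp$p_two_sided, st$p_two_sided, tolerance = 1e-10)
  expect_equal(stp$residuals, st$residuals[perm], tolerance = 1e-10)
})

test_that("a covariate orthogonal to marker and outcome only changes df", {
  set.seed(11)
  n <- 50
  y <- rnorm(n)
  x <- rnorm(n)
  z <- residuals(lm(rnorm(n) ~ x + y))  # orthogonal to 1, x and y
  st0 <- fit_marker_association(y, x)
  st1 <- fit_marker_association(y, x, covariates = cbind(z))
  expect_identical(st1$df, st0$df - 1L)
  expect_equal(st1$beta, st0$beta, tolerance = 1e-10)
  expect_equal(st1$t_stat, st0$t_stat * sqrt(st1$df / st0$df),
               tolerance = 1e-10)
})

test_that("degenerate inputs raise classed errors", {
  y <- rnorm(10)
  expect_error(fit_marker_association(y, rep(1, 10),
                                      model_orientation = "outcome_as_response"),
               class = "robustewas_degenerate_predictor")
  # constant outcome as tested variable under the default orientation
  expect_error(fit_marker_association(rep(0, 10), y),
               class = "robustewas_degenerate_predictor")
  expect_error(fit_marker_association(c(1, 2), c(3, 1)),
               class = "robustewas_insufficient_sample")
  cc <- cbind(a = rnorm(10), b = 0)  # second column collinear with intercept
  cc[, 2] <- cc[, 1] * 2
  expect_error(fit_marker_association(y, rnorm(10), covariates = cc),
               class = "robustewas_collinearity")
  expect_error(fit_marker_association(y, rnorm(9)),
               class = "robustewas_dimension")
  expect_error(fit_marker_association(c(y[-1], NA), rnorm(10)),
               class = "robustewas_missing_values")
})

test_that("vectorised per-feature t equals the per-feature fit", {
  set.seed(21)
  M <- matrix(rnorm(8 * 30), nrow = 8)
  y <- rnorm(30)
  vt <- robustewas:::.row_cor_t(M, y)
  for (i in 1:8) {
    st <- fit_marker_association(y, M[i, ])
    expect_equal(vt$t[i], st$t_stat, tolerance = 1e-10)
  }
  expect_identical(vt$df, 28L)
})
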