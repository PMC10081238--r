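# Data generation, outlier injection and the Monte-Carlo study engine.

test_that("generate_pair hits the target population correlation", {
  set.seed(25)
  p0 <- generate_pair(1e6, 0)
  expect_lt(abs(cor(p0$y, p0$x)), 0.005)
  p3 <- generate_pair(1e6, 0.3)
  expect_lt(abs(cor(p3$y, p3$x) - 0.3), 0.005)
  set.seed(26); a <- generate_pair(100, 0.3)
  set.seed(26); b <- generate_pair(100, 0.3)
  expect_identical(a, b)
  expect_error(generate_pair(10, 1), class = "robustewas_domain")
})

test_that("univariate outliers hit one variable of distinct individuals", {
  set.seed(27)
  y <- rnorm(50); x <- rnorm(50)
  o <- inject_univariate_outliers(y, x, count = 5, magnitude = 6)
  expect_identical(nrow(o$affected), 5L)
  expect_false(anyDuplicated(o$affected$index) > 0)
  # marker-first alternation: 3 marker, 2 outcome alterations
  expect_identical(as.vector(table(o$affected$variable)[c("x", "y")]),
                   c(3L, 2L))
  for (i in seq_len(5)) {
    idx <- o$affected$index[i]
    if (o$affected$variable[i] == "x") {
      expect_identical(abs(o$x[idx]), 6)
      expect_identical(o$y[idx], y[idx])   # never both variables
    } else {
      expect_identical(abs(o$y[idx]), 6)
      expect_identical(o$x[idx], x[idx])
    }
  }
  # untouched samples unchanged; count 0 is a no-op
  un <- setdiff(seq_len(50), o$affected$index)
  expect_identical(o$y[un], y[un])
  o0 <- inject_univariate_outliers(y, x, count = 0, magnitude = 6)
  expect_identical(o0$y, y)
  expect_identical(o0$x, x)
  expect_error(inject_univariate_outliers(y, x, 51, 6),
               class = "robustewas_domain")
})

test_that("bivariate outliers alter both variables with controlled signs", {
  set.seed(28)
  y <- rnorm(30); x <- rnorm(30)
  oc <- inject_bivariate_outlier(y, x, count = 2, magnitude = 5)
  expect_identical(length(oc$affected), 2L)
  expect_identical(oc$y[oc$affected], oc$x[oc$affected])     # concordant
  expect_identical(abs(oc$y[oc$affected]), rep(5, 2))
  od <- inject_bivariate_outlier(y, x, count = 1, magnitude = 5,
                                 concordant = FALSE)
  expect_identical(od$y[od$affected], -od$x[od$affected])
  o0 <- inject_bivariate_outlier(y, x, count = 0, magnitude = 5)
  expect_identical(o0$y, y)
})

test_that("study results are exact counts with correct Monte-Carlo SEs", {
  cfg <- sim_config(n = 60, n_sims = 400, rho = 0, k_values = c(2, 5),
                    seed = 29)
  res <- run_type1_study(cfg)
  counts <- res$rate * res$n_used
  expect_equal(counts, round(counts), tolerance = 1e-9)
  expect_equal(res$se, sqrt(res$rate * (1 - res$rate) / res$n_used))
  res2 <- run_type1_study(cfg)
  expect_identical(res$rate, res2$rate)  # bit-reproducible given the seed
  expect_identical(sort(unique(res$method)),
                   c("full", "robust", "split_half"))
})

test_that("study preconditions are enforced", {
  expect_error(run_type1_study(sim_config(rho = 0.3, n_sims = 10)),
               class = "robustewas_bad_config")
  expect_error(run_power_study(sim_config(rho = 0, n_sims = 10)),
               class = "robustewas_bad_config")
  expect_error(
    run_power_study(sim_config(rho = 0.3, n_bivariate_outliers = 1,
                               n_sims = 10)),
    class = "robustewas_bad_config")
  expect_error(sim_config(n = 100, k_values = 60),
               class = "robustewas_bad_config")
  expect_error(sim_config(alpha = 0), class = "robustewas_bad_config")
})

test_that("fixture generator produces calibrated nulls and known truths", {
  fx <- generate_fixture_ewas(m = 2000, n = 250, n_true = 0, seed = 30)
  full <- full_sample_ewas(fx$dataset, adjust = "bonferroni")
  expect_lte(sum(full$p_adjusted < 0.05), 1L)    # ~Binomial(1, 0.05) hits
  expect_lt(abs(inflation_lambda(full$p) - 1), 0.1)

  fx2 <- generate_fixture_ewas(m = 2000, n = 250, n_true = 0, seed = 30)
  expect_identical(fx$dataset$markers, fx2$dataset$markers)
})

test_that("strong true effects are fully recovered by full-sample analysis", {
  fx <- generate_fixture_ewas(m = 1000, n = 250, n_true = 10,
                              effect_rho = 0.5, seed = 31)
  full <- full_sample_ewas(fx$dataset, adjust = "bonferroni")
  hits <- full$p_adjusted < 0.05
  expect_true(all(hits[fx$truth$is_true]))   # power ~ 1 at r = 0.5, n = 250
  expect_lte(sum(hits[!fx$truth$is_true]), 1L)
})

test_that("fixture covariates and injected outliers are recorded", {
  fx <- generate_fixture_ewas(
    m = 50, n = 120, n_true = 2, effect_rho = 0.4,
    covariate_spec = list(n_covariates = 2, outcome_loading = 0.3,
                          marker_loading = 0.3),
    outlier_spec = list(type = "bivariate", count = 1, magnitude = 6,
                        features = 5L),
    seed = 32)
  expect_identical(ncol(fx$dataset$covariates), 2L)
  expect_identical(fx$truth$n_outliers[5], 1L)
  id <- fx$outlier_individuals
  expect_identical(abs(fx$dataset$markers[5, id]), 6)
  expect_identical(fx$dataset$outcome[id], fx$dataset$markers[5, id])
})
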