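# End-to-end robust k-fold engine.

test_that("k = 1 reduces to the full-sample analysis on the Z scale", {
  ds <- make_null_dataset(12, 40, seed = 5)
  r1 <- robust_ewas(ds, k = 1, seed = 3)
  full <- full_sample_ewas(ds)
  expect_true(all(abs(r1$p_meta - full$p) < 1e-12))
  expect_equal(r1$fold_z1, t_to_signed_z(full$t_stat, full$df),
               tolerance = 1e-12)

  # with covariates (per-fold refit path)
  set.seed(6)
  cov <- matrix(rnorm(40 * 2), ncol = 2)
  dsc <- ewas_dataset(ds$markers, ds$outcome, covariates = cov)
  r1c <- robust_ewas(dsc, k = 1, seed = 3)
  fullc <- full_sample_ewas(dsc)
  expect_true(all(abs(r1c$p_meta - fullc$p) < 1e-12))
})

test_that("z_meta is invariant to permuting fold labels", {
  ds <- make_null_dataset(6, 55, seed = 9)
  fa <- partition_folds(55, 5, seed = 2)
  base <- robust_ewas(ds, folds = fa)
  set.seed(10)
  relabel <- sample(5)
  fa2 <- fa
  fa2$fold_of_sample <- relabel[fa$fold_of_sample]
  perm <- robust_ewas(ds, folds = fa2)
  expect_equal(perm$z_meta, base$z_meta, tolerance = 1e-12)
  expect_equal(perm$p_meta, base$p_meta, tolerance = 1e-12)
})

test_that("one contaminated fold shifts z_meta by exactly delta_z / sqrt(k)", {
  set.seed(31)
  n <- 240
  y <- rnorm(n)
  x <- rnorm(n)
  for (k in c(2, 5, 10, 20)) {
    fa <- partition_folds(n, k, seed = k)
    ds0 <- ewas_dataset(matrix(x, 1), y)
    base <- robust_ewas(ds0, folds = fa)
    target <- which(fa$fold_of_sample == 1L)[1L]
    y2 <- y; x2 <- x
    y2[target] <- 8; x2[target] <- 8
    pert <- robust_ewas(ewas_dataset(matrix(x2, 1), y2), folds = fa)
    dz <- as.numeric(pert[1, paste0("fold_z", 1:k)] -
                       base[1, paste0("fold_z", 1:k)])
    expect_true(all(abs(dz[-1]) < 1e-12))  # only the contaminated fold moves
    expect_equal(pert$z_meta - base$z_meta, dz[1] / sqrt(k),
                 tolerance = 1e-10)
  }
})

test_that("meta p-values are uniform under the global null", {
  fx <- generate_fixture_ewas(m = 10000, n = 250, n_true = 0, seed = 77)
  res <- robust_ewas(fx$dataset, k = 5, seed = 78)
  expect_equal(res$p_meta, 2 * pnorm(abs(res$z_meta), lower.tail = FALSE),
               tolerance = 1e-12)
  ks <- suppressWarnings(ks.test(res$p_meta, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("binary outcomes are stratified so every fold holds both classes", {
  ds <- make_null_dataset(3, 41, seed = 12, binary_outcome = TRUE)
  res <- robust_ewas(ds, k = 5, seed = 1)
  fa <- attr(res, "fold_assignment")
  expect_true(fa$stratified)
  for (j in 1:5)
    expect_identical(sort(unique(ds$outcome[fa$fold_of_sample == j])), c(0, 1))
})

test_that("adjustment columns and determinism contracts hold", {
  ds <- make_null_dataset(20, 60, seed = 14)
  res <- robust_ewas(ds, k = 4, seed = 2, adjust = "bonferroni")
  expect_equal(res$p_adjusted, pmin(1, 20 * res$p_meta))
  res_bh <- robust_ewas(ds, k = 4, seed = 2, adjust = "bh")
  expect_equal(res_bh$p_adjusted, bh_stepup_oracle(res_bh$p_meta))
  expect_true(all(res$p_adjusted >= res$p_meta))
  again <- robust_ewas(ds, k = 4, seed = 2)
  expect_equal(again$z_meta, res$z_meta)

  # degenerate feature is reported with fold context
  bad <- ds
  bad$markers[3, ] <- 1
  expect_error(robust_ewas(bad, k = 4, seed = 2),
               class = "robustewas_degenerate_predictor")
})
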