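test_that("correlation repair yields a unit-diagonal PD matrix near the target", {
  C <- mmp_descriptor_correlation()
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(min(ev), 0)                       # printed matrix is indefinite
  R <- repair_correlation(C, eig_floor = 0.05)
  expect_equal(diag(R), rep(1, 5), ignore_attr = TRUE)
  expect_gte(min(eigen(R, symmetric = TRUE)$values), 0.05 - 1e-8)
  expect_lt(max(abs(R - C)), 0.06)
  expect_gt(attr(R, "frobenius_distance"), 0)
  expect_error(repair_correlation(matrix(c(1, 0.5, 0.2, 1), 2, 2)),
               "not symmetric")
})

test_that("sampled descriptors reproduce the target correlation structure", {
  spec <- synthetic_spec(seed = 7)
  X <- sample_descriptors(10000, spec)
  target <- repair_correlation(spec$target_correlation, spec$eig_floor)
  ## published LUMO-MASEOAT correlation, stochastic tolerance
  expect_lt(abs(cor(X[, "LUMO"], X[, "MASEOAT"]) - 0.1171), 0.05)
  ## convergence: all entries near the (repaired) target at large n
  Xl <- sample_descriptors(1e5, spec)
  Z <- scale(Xl)
  expect_lt(max(abs(cor(Z) - target)), 0.02)
  ## requested location/scale
  expect_equal(unname(colMeans(Xl)), spec$descriptor_means, tolerance = 0.05)
  expect_equal(unname(apply(Xl, 2, sd)), spec$descriptor_sds, tolerance = 0.05)
})

test_that("identity target gives independent descriptors; seeds reproduce", {
  spec <- synthetic_spec(target_correlation = diag(5), seed = 3)
  X <- sample_descriptors(10000, spec)
  off <- cor(X)[upper.tri(diag(5))]
  expect_lt(max(abs(off)), 0.05)
  expect_identical(sample_descriptors(50, spec), sample_descriptors(50, spec))
  spec2 <- synthetic_spec(target_correlation = diag(5), seed = 4)
  expect_false(identical(sample_descriptors(50, spec),
                         sample_descriptors(50, spec2)))
})

test_that("indefinite target with repair disabled is an error", {
  spec <- synthetic_spec(repair = FALSE)
  expect_error(sample_descriptors(10, spec), "not positive definite")
})

test_that("activity simulation is the stated linear model plus noise", {
  co <- mmp_hm_coefficients("equation")
  ## intercept-only evaluation of the published coefficients
  X0 <- matrix(0, 4, 5, dimnames = list(NULL, mmp_descriptor_names()))
  expect_equal(simulate_activity(X0, co, noise_sd = 0), rep(-195.01, 4))

  ## noiseless: OLS refit recovers the generating coefficients exactly
  spec <- synthetic_spec(seed = 5)
  X <- sample_descriptors(40, spec)
  y <- simulate_activity(X, co, noise_sd = 0)
  expect_equal(unname(oracle_normal_equations(X, y)), unname(co),
               tolerance = 1e-8)

  ## exact linearity against a plain dot product
  manual <- co[1] + drop(X %*% co[-1])
  expect_identical(simulate_activity(X, co, noise_sd = 0), unname(manual))

  expect_error(simulate_activity(X[, 1:3], co), "coefficients")
})

test_that("at the study noise level the fitted residual error is near 0.23", {
  spec <- synthetic_spec(seed = 21)
  X <- sample_descriptors(1000, spec)
  y <- simulate_activity(X, spec$true_coefficients, noise_sd = 0.23,
                         seed = 99)
  fit <- fit_ols(X, y)
  s <- sqrt(sum(fit$residuals^2) / fit$df_residual)
  expect_lt(abs(s - 0.23), 0.03)
})

test_that("decoys are constructed to trip their target rules", {
  spec <- synthetic_spec(seed = 13,
                         decoys = c(collinear = 1, near_constant = 1,
                                    missing = 1, noise = 2))
  base <- descriptor_table(sample_descriptors(21, spec),
                           activity = rnorm(21))
  tab <- add_decoys(base, spec)
  expect_identical(ncol(tab$values), 10L)

  ## collinear decoy correlates strongly with its parent
  expect_gte(abs(cor(tab$values[, "LUMO"], tab$values[, "LUMO_coll1"])), 0.9)
  ## near-constant decoy sits below the rule-2 variance floor
  nc <- tab$values[, "NEARCONST_1"]
  expect_lt(sd(nc) / abs(mean(nc)), 1e-6)
  ## the missing-value decoy is exactly the flagged column
  expect_identical(missing_descriptors(tab), "HASMISS_1")

  expect_error(add_decoys(toy_table(5, 2), spec), "lacks true descriptors")
})

test_that("make_benchmark composes a reproducible 21 + 12 study", {
  bench <- make_benchmark(synthetic_spec(seed = 1))
  expect_identical(nrow(bench$train$values), 21L)
  expect_identical(nrow(bench$test$values), 12L)
  expect_setequal(bench$truth$true_descriptor_names, mmp_descriptor_names())

  bench2 <- make_benchmark(synthetic_spec(seed = 1))
  expect_identical(bench$train$values, bench2$train$values)
  bench3 <- make_benchmark(synthetic_spec(seed = 2))
  expect_false(identical(bench$train$activity, bench3$train$activity))

  ## benchmark tables round-trip through the CSV sidecar format
  dir <- withr::local_tempdir()
  write_benchmark(bench, dir)
  back <- read_descriptor_table(file.path(dir, "train.csv"))
  expect_identical(back$values, bench$train$values)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(unlist(truth$coefficients),
               bench$truth$coefficients, tolerance = 1e-15)
})
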