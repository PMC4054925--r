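test_that("exact linear data are interpolated exactly", {
  x <- matrix(1:8, ncol = 1, dimnames = list(NULL, "x"))
  fit <- fit_ols(x, 1 + 2 * x[, 1])
  expect_equal(unname(coef(fit)), c(1, 2), tolerance = 1e-12)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-12)
})

test_that("coefficients match the normal-equations oracle", {
  set.seed(31)
  for (rep in 1:5) {
    X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- rnorm(10)
    fit <- fit_ols(X, y)
    expect_equal(unname(coef(fit)), unname(oracle_normal_equations(X, y)),
                 tolerance = 1e-10)
  }
})

test_that("t statistics are coefficient over error", {
  ## the published MRECO coefficient/error pair reproduces its printed t
  expect_equal(-3.6715 / 0.6720, -5.4635, tolerance = 5e-5)
  set.seed(5)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  fit <- fit_ols(X, rnorm(20))
  expect_equal(fit$t_values, fit$coefficients / fit$standard_errors)
})

test_that("model statistics follow their definitions", {
  set.seed(8)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 1 + X[, 1] - 2 * X[, 2] + rnorm(20, 0, 0.5)
  fit <- fit_ols(X, y)
  st <- model_stats(fit)
  sse <- sum(residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  expect_equal(st$r_squared, 1 - sse / sst)
  expect_equal(st$rms^2 * st$n, sse)                    # RMS invariant
  expect_equal(st$std_error_s, sqrt(sse / (20 - 3 - 1)))
  expect_equal(st$f_statistic, ((sst - sse) / 3) / (sse / 16))
  expect_lte(st$q_squared_loo, st$r_squared)            # PRESS >= SSE

  ## perfect fit
  fit2 <- fit_ols(X, 2 - X[, 3])
  st2 <- model_stats(fit2)
  expect_equal(st2$r_squared, 1, tolerance = 1e-12)
  expect_equal(st2$rms, 0, tolerance = 1e-8)

  expect_error(model_stats(fit_ols(X, rnorm(20)), X, rep(1, 20)),
               "zero-variance")
})

test_that("activity orthogonal to the design gives R2 near 0 and small F", {
  set.seed(12)
  X <- matrix(rnorm(100), 50, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(50)
  y <- y - X %*% oracle_normal_equations(X, y)[-1] * 0  # keep raw noise
  fit <- fit_ols(X, y)
  st <- model_stats(fit)
  expect_lt(st$r_squared, 0.15)
  expect_lt(st$f_statistic, qf(0.99, 2, 47))
})

test_that("hat-matrix LOO Q2 equals the naive refitting oracle", {
  set.seed(17)
  for (rep in 1:5) {
    X <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("a", "b")))
    y <- X[, 1] + rnorm(15)
    expect_equal(loo_q2(X, y), oracle_loo_q2(X, y), tolerance = 1e-8)
  }
  ## exact linear data: Q2 = 1
  x <- matrix(seq(-3, 3, length.out = 12), ncol = 1,
              dimnames = list(NULL, "x"))
  expect_equal(loo_q2(x, 2 - 5 * x[, 1]), 1, tolerance = 1e-10)
})

test_that("residuals are orthogonal to every design column", {
  set.seed(23)
  for (rep in 1:5) {
    X <- scale(matrix(rnorm(80), 20, 4))
    colnames(X) <- paste0("d", 1:4)
    fit <- fit_ols(X, rnorm(20))
    expect_lt(max(abs(crossprod(cbind(1, X), residuals(fit)))), 1e-8)
  }
})

test_that("degenerate designs raise informative errors", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_ols(X[1:3, ], rnorm(3)), "n > k")
  Xs <- cbind(X, a2 = 2 * X[, "a"])
  expect_error(fit_ols(Xs, rnorm(10)), "singular design.*a2|a2.*singular design")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(fit_ols(Xna, rnorm(10)), "missing values")
})

test_that("prediction reproduces fitted values and validates its input", {
  tab <- toy_table(8, 3)
  fit <- fit_ols(tab)
  expect_equal(unname(predict(fit, tab)), unname(fitted(fit)))

  ## zero-slope model predicts the constant intercept
  flat <- fit
  flat$coefficients[] <- c(2.5, 0, 0, 0)
  expect_equal(unname(predict(flat, tab)), rep(2.5, 8))

  expect_error(predict(fit, tab$values[, 1:2]), "absent from newdata: D3")
  bad <- tab$values; bad[2, "D1"] <- NA
  expect_error(predict(fit, bad), "missing values in required descriptor")
})

test_that("models serialize to JSON and come back usable", {
  tab <- toy_table(9, 3)
  fit <- fit_ols(tab)
  path <- withr::local_tempfile(fileext = ".json")
  write_qsar_lm(fit, path, provenance = list(seed = 1))
  back <- read_qsar_lm(path)
  expect_equal(back$coefficients, fit$coefficients, tolerance = 1e-15)
  expect_equal(unname(predict(back, tab)), unname(fitted(fit)),
               tolerance = 1e-12)
})

test_that("external prediction statistics report both R2 conventions", {
  obs <- c(1, 2, 3, 4, 5)
  pred <- obs + 10                       # perfectly correlated, badly biased
  ps <- prediction_stats(obs, pred)
  expect_equal(ps$r_squared_cor, 1)
  expect_lt(ps$r_squared_identity, 0)
  expect_equal(ps$rms, 10)
})
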