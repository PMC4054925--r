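test_that("the linear model evaluates its printed coefficients", {
  zero <- c(LUMO = 0, MRECO = 0, KSIND = 0, ZX = 0, MASEOAT = 0)
  expect_equal(predict_mmp_hm(zero), -195.01)
  expect_equal(predict_mmp_hm(replace(zero, "LUMO", 1)), -195.01 + 2.4570)
  ## the two printed coefficient variants differ only in MASEOAT
  co_eq <- mmp_hm_coefficients("equation")
  co_tab <- mmp_hm_coefficients("table")
  expect_equal(co_eq[["MASEOAT"]], 0.84804)
  expect_equal(co_tab[["MASEOAT"]], 0.84808)
  expect_identical(co_eq[-6], co_tab[-6])
})

test_that("linear predictions match an independent transcription", {
  set.seed(14)
  m <- matrix(rnorm(250), 50, 5,
              dimnames = list(NULL, mmp_descriptor_names()))
  got <- predict_mmp_hm(m)
  want <- oracle_published_linear(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5])
  expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
  got_t <- predict_mmp_hm(m, variant = "table")
  want_t <- oracle_published_linear(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5],
                                    maseoat_slope = 0.84808)
  expect_equal(got_t, want_t, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the linear model is exactly linear", {
  set.seed(15)
  a <- rnorm(5); b <- rnorm(5)
  names(a) <- names(b) <- mmp_descriptor_names()
  lhs <- predict_mmp_hm(a + b) - (-195.01)
  rhs <- (predict_mmp_hm(a) - (-195.01)) + (predict_mmp_hm(b) - (-195.01))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("coefficient t tests reproduce the printed values", {
  tt <- mmp_hm_ttests()
  t_of <- function(term) tt$t[tt$term == term]
  expect_equal(t_of("LUMO"), 4.8720, tolerance = 5e-5)
  expect_equal(t_of("MRECO"), -5.4635, tolerance = 5e-5)
  expect_equal(t_of("ZX"), -3.2726, tolerance = 5e-5)
  expect_equal(t_of("MASEOAT"), 1.9458, tolerance = 5e-5)
  ## intercept and KSIND carry slightly more printed rounding
  expect_equal(t_of("(Intercept)"), -1.5463, tolerance = 1.5e-4)
  expect_equal(t_of("KSIND"), -2.6816, tolerance = 1.5e-4)
})

test_that("the GEP model is the sum of its five gene terms", {
  set.seed(16)
  m <- matrix(rnorm(100, 0, 0.8), 20, 5,
              dimnames = list(NULL, mmp_descriptor_names()))
  m[, "KSIND"] <- abs(m[, "KSIND"]) + 3   # keep term 5 mostly finite
  terms <- mmp_gep_terms(m)
  expect_identical(ncol(terms), 5L)
  pred <- predict_mmp_gep(m)
  expect_same_numeric(pred, unname(rowSums(terms)), tol = 1e-12)
})

test_that("GEP predictions match an independent transcription", {
  set.seed(17)
  m <- matrix(rnorm(500), 100, 5,
              dimnames = list(NULL, mmp_descriptor_names()))
  got <- predict_mmp_gep(m)
  want <- oracle_published_gep(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5])
  expect_same_numeric(got, unname(want), tol = 1e-12)
})

test_that("a negative radicand in gene five is flagged, not masked", {
  v <- c(LUMO = 0.1, MRECO = 0.2, KSIND = -50, ZX = 0.3, MASEOAT = 0.5)
  ## KSIND very negative makes the term-5 radicand negative
  pred <- predict_mmp_gep(rbind(v))
  expect_false(is.finite(pred[1]))
  expect_true(attr(pred, "nonfinite")[1])
})

test_that("prediction input is validated", {
  m <- matrix(rnorm(8), 2, 4,
              dimnames = list(NULL, mmp_descriptor_names()[1:4]))
  expect_error(predict_mmp_hm(m), "MASEOAT")
  m2 <- matrix(c(1, NA, rep(1, 8)), 2, 5,
               dimnames = list(NULL, mmp_descriptor_names()))
  expect_error(predict_mmp_gep(m2), "missing")
})
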