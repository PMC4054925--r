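## constructed table whose columns each trip one pre-filter rule
prefilter_fixture <- function() {
  set.seed(41)
  n <- 21
  good <- rnorm(n)
  y <- 2 * good + rnorm(n, 0, 0.3)
  miss <- rnorm(n); miss[4] <- NA
  nearconst <- rep(3, n) + rnorm(n, 0, 1e-9)
  ## exactly orthogonal to y: one-parameter slope, F and t are 0
  ortho <- rnorm(n)
  ortho <- lm.fit(cbind(1, y), ortho)$residuals
  weak <- rnorm(n)  # unrelated noise
  X <- cbind(GOOD = good, MISS = miss, NEARCONST = nearconst,
             ORTHO = ortho, WEAK = weak)
  descriptor_table(X, activity = y)
}

test_that("each pre-filter rule excludes its target descriptor, in order", {
  tab <- prefilter_fixture()
  pre <- hm_prefilter(tab, hm_config())
  expect_identical(pre$excluded[["MISS"]], 1L)
  expect_identical(pre$excluded[["NEARCONST"]], 2L)
  expect_identical(pre$excluded[["ORTHO"]], 3L)   # F = 0 < 1
  expect_true("GOOD" %in% pre$survivors)

  ## rule 4 fires between the F cut and the t threshold
  r <- cor(tab$values[, "WEAK"], tab$activity)
  tval <- abs(r) * sqrt(19 / (1 - r^2))
  if (tval^2 >= 1 && tval < 1.5) {
    expect_identical(pre$excluded[["WEAK"]], 4L)
  }

  ## one-parameter F oracle: direct single-descriptor fit
  f <- summary(lm(tab$activity ~ tab$values[, "ORTHO"]))$fstatistic[["value"]]
  expect_lt(f, 1)
})

test_that("collinearity control accepts weak pairs and rejects decoys", {
  spec <- synthetic_spec(seed = 19)
  bench <- make_benchmark(spec)
  tab <- bench$train
  expect_true(collinearity_ok(c("LUMO", "MASEOAT"), tab))
  expect_false(collinearity_ok(c("LUMO", "LUMO_coll1"), tab))
  expect_true(collinearity_ok("LUMO", tab))          # singleton: no pairs
  expect_true(collinearity_ok(character(0), tab))
})

test_that("chosen models never contain a collinear pair", {
  for (seed in c(2, 5, 9)) {
    bench <- make_benchmark(synthetic_spec(seed = seed))
    hm <- hm_fit(bench$train, hm_config(min_abs_t = 0, min_one_param_F = 0))
    C <- abs(cor(bench$train$values[, hm$descriptors, drop = FALSE]))
    diag(C) <- 0
    expect_lt(max(C), 0.8)
  }
})

test_that("beam search agrees with exhaustive enumeration for small pools", {
  for (seed in c(3, 7)) {
    bench <- make_benchmark(synthetic_spec(seed = seed))
    cfg_beam <- hm_config(min_abs_t = 0, min_one_param_F = 0,
                          max_subset_size = 3)
    cfg_exh <- hm_config(min_abs_t = 0, min_one_param_F = 0,
                         max_subset_size = 3, search = "exhaustive")
    hb <- hm_fit(bench$train, cfg_beam)
    he <- hm_fit(bench$train, cfg_exh)
    for (k in 1:3) {
      expect_equal(hb$best_by_size[[k]]$r_squared,
                   he$best_by_size[[k]]$r_squared, tolerance = 1e-10)
      expect_identical(hb$best_by_size[[k]]$descriptors,
                       he$best_by_size[[k]]$descriptors)
    }
    ## nested-model property of the exhaustive per-size optimum
    r2s <- vapply(he$best_by_size, `[[`, 0, "r_squared")
    expect_true(all(diff(r2s) >= -1e-10))
  }
})

test_that("a noiseless benchmark is recovered exactly by the search", {
  ## seed chosen so that the sampled 21-compound design leaves each true
  ## descriptor incrementally informative; prefilter thresholds relaxed to
  ## test the search and stopping logic in isolation
  spec <- synthetic_spec(seed = 8, noise_sd = 0)
  bench <- make_benchmark(spec)
  hm <- hm_fit(bench$train, hm_config(min_abs_t = 0, min_one_param_F = 0))
  expect_setequal(hm$descriptors, mmp_descriptor_names())
  expect_identical(hm$chosen_size, 5L)
  st <- model_stats(hm$model)
  expect_equal(st$r_squared, 1, tolerance = 1e-9)
})

test_that("the increment standard stops growth at the last useful size", {
  spec <- synthetic_spec(seed = 8, noise_sd = 0)
  bench <- make_benchmark(spec)
  hm <- hm_fit(bench$train, hm_config(min_abs_t = 0, min_one_param_F = 0))
  ## there are noise decoys beyond size 5, yet adding a 6th descriptor
  ## gains less than 0.02, so the chosen size stays 5
  expect_gte(length(hm$best_by_size), 6L)
  gain6 <- hm$best_by_size[[6]]$r_squared - hm$best_by_size[[5]]$r_squared
  expect_lt(gain6, 0.02)
  expect_identical(hm$chosen_size, 5L)
})

test_that("an all-collinear survivor pool forces single-descriptor models", {
  set.seed(61)
  n <- 25
  base <- rnorm(n)
  X <- cbind(A = base + rnorm(n, 0, 0.05),
             B = base + rnorm(n, 0, 0.05),
             C = base + rnorm(n, 0, 0.05))
  tab <- descriptor_table(X, activity = base + rnorm(n, 0, 0.2))
  hm <- hm_fit(tab, hm_config())
  expect_identical(length(hm$best_by_size), 1L)
  expect_identical(hm$chosen_size, 1L)
})

test_that("an empty survivor pool is an explicit error", {
  set.seed(71)
  n <- 21
  y <- rnorm(n)
  o1 <- lm.fit(cbind(1, y), rnorm(n))$residuals
  tab <- descriptor_table(cbind(O1 = o1), activity = y)
  expect_error(hm_fit(tab, hm_config()), "no admissible descriptors")
})

test_that("selection traces serialize with the full audit trail", {
  bench <- make_benchmark(synthetic_spec(seed = 5))
  hm <- hm_fit(bench$train, hm_config(min_abs_t = 0, min_one_param_F = 0))
  path <- withr::local_tempfile(fileext = ".json")
  write_hm_trace(hm, path, provenance = list(seed = 5))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(obj$type, "hm_selection")
  expect_identical(obj$excluded$HASMISS_1, 1L)
  expect_identical(obj$excluded$NEARCONST_1, 2L)
  expect_identical(obj$chosen_size, hm$chosen_size)
})
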