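# Symbol coding reminder: positive = function id (1 "+", 2 "-", 3 "*",
# 4 "/", 5 pow, 6 sqrt, 7 sin, 8 tan, 9 ln, 10 pow10), negative = terminal
# (descriptor column), 0 = the RNC placeholder.

test_that("gene geometry follows the Karva closure rule", {
  cfg <- gep_config()                      # study defaults: head 8
  expect_identical(cfg$tail, 9L)           # t = h(a_max - 1) + 1
  expect_identical(cfg$gene_length, 26L)   # head + tail + Dc
  cfg2 <- gep_config(head = 3)
  expect_identical(cfg2$gene_length, 11L)
})

test_that("K-expressions decode breadth-first", {
  ## "+ a b" is the one-function tree a + b
  X <- matrix(c(2, 5), 1, 2)
  chrom <- list(symbols = rbind(c(1L, -1L, -2L, -1L, -1L)),
                dc = rbind(rep(1L, 2)), constants = rbind(0))
  expect_equal(evaluate_chromosome(chrom, X), 7)

  ## "* + a b c": level-order filling gives (a + b) * c
  chrom2 <- list(symbols = rbind(c(3L, 1L, -3L, -1L, -2L, -3L, -3L)),
                 dc = rbind(rep(1L, 3)), constants = rbind(0))
  X3 <- matrix(c(2, 5, 10), 1, 3)
  expect_equal(evaluate_chromosome(chrom2, X3), (2 + 5) * 10)

  ## a head starting with a terminal is a single-node tree; the rest of the
  ## gene is noncoding
  chrom3 <- list(symbols = rbind(c(-2L, 1L, -1L, -1L, -1L)),
                 dc = rbind(rep(1L, 2)), constants = rbind(0))
  expect_equal(evaluate_chromosome(chrom3, X), 5)
  tree <- decode_gene(chrom3$symbols[1, ])
  expect_identical(length(tree$sym), 1L)
})

test_that("RNC placeholders consume Dc indices in reading order", {
  ## "+ ? ?" with dc = (2, 1): first ? takes constant 2, second constant 1
  chrom <- list(symbols = rbind(c(1L, 0L, 0L, -1L, -1L)),
                dc = rbind(c(2L, 1L)), constants = rbind(c(10, 20)))
  expect_equal(evaluate_chromosome(chrom, matrix(0, 1, 1)), 30)
  tree <- decode_gene(chrom$symbols[1, ], chrom$dc[1, ], chrom$constants[1, ])
  expect_equal(tree$value[2:3], c(20, 10))
})

test_that("protected math propagates non-finite values", {
  ## sqrt of a negative terminal
  chrom <- list(symbols = rbind(c(6L, -1L, -1L, -1L, -1L)),
                dc = rbind(rep(1L, 2)), constants = rbind(0))
  out <- evaluate_chromosome(chrom, matrix(-1, 1, 1))
  expect_false(is.finite(out))
  ## and the linking sum stays non-finite
  chrom5 <- list(symbols = rbind(c(6L, -1L, -1L, -1L, -1L),
                                 c(-1L, -1L, -1L, -1L, -1L)),
                 dc = rbind(rep(1L, 2), rep(1L, 2)),
                 constants = rbind(0, 0))
  expect_false(is.finite(evaluate_chromosome(chrom5, matrix(-1, 1, 1))))
})

test_that("addition linking sums the gene values", {
  ## five genes, each the bare terminal d1
  G <- 5
  chrom <- list(symbols = matrix(rep(c(-1L, -1L, -1L, -1L, -1L), G), G,
                                 byrow = TRUE, ncol = 5),
                dc = matrix(1L, G, 2), constants = matrix(0, G, 1))
  X <- matrix(c(1.5, -2), 2, 1)
  expect_equal(evaluate_chromosome(chrom, X), 5 * X[, 1])
})

test_that("engine evaluation matches the recursive pointer-tree oracle", {
  cfg <- gep_config()
  pop <- random_population(cfg, n_terminals = 5, seed = 202)
  set.seed(303)
  n_checked <- 0
  for (rep in 1:10) {
    X <- matrix(rnorm(nrow(pop[[1]]$symbols) * 0 + 5 * 100, sd = 2), 100, 5)
    for (ch in pop) {
      engine <- evaluate_chromosome(ch, X[rep * 7, , drop = FALSE])
      oracle <- oracle_eval_chromosome(ch, X[rep * 7, ])
      expect_same_numeric(engine, oracle, tol = 1e-12)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 1000)
})

test_that("decoding is total over random genes (fuzz)", {
  cfg <- gep_config()
  ab_head <- c(1:10, -(1:5), 0L)
  ab_tail <- c(-(1:5), 0L)
  set.seed(404)
  n_fail <- 0
  X <- matrix(rnorm(5), 1, 5)
  for (chunk in 1:10) {
    sym <- cbind(matrix(sample(ab_head, 1e4 * cfg$head, TRUE), 1e4),
                 matrix(sample(ab_tail, 1e4 * cfg$tail, TRUE), 1e4))
    dc <- matrix(sample.int(10, 1e4 * cfg$tail, TRUE), 1e4)
    for (i in seq_len(nrow(sym))) {
      chrom <- list(symbols = sym[i, , drop = FALSE],
                    dc = dc[i, , drop = FALSE],
                    constants = matrix(runif(10, -10, 10), 1))
      v <- tryCatch(evaluate_chromosome(chrom, X), error = function(e) NULL)
      if (is.null(v) || length(v) != 1L) n_fail <- n_fail + 1
    }
  }
  expect_identical(n_fail, 0)
})

test_that("chromosome genomes survive a JSON round trip", {
  cfg <- tiny_gep_config()
  ch <- random_population(cfg, 3, seed = 5)[[1]]
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(chromosome_to_list(ch), path, auto_unbox = TRUE,
                       digits = NA)
  back <- chromosome_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
  expect_identical(back$symbols, ch$symbols)
  expect_identical(back$dc, ch$dc)
  expect_equal(back$constants, ch$constants, tolerance = 1e-15)
  X <- matrix(rnorm(9), 3, 3)
  expect_equal(evaluate_chromosome(back, X), evaluate_chromosome(ch, X))
})

test_that("infix rendering evaluates to the same value", {
  cfg <- tiny_gep_config()
  pop <- random_population(cfg, 2, seed = 9)
  X <- matrix(c(0.7, -1.3), 1, 2)
  for (ch in pop[1:5]) {
    expr <- chromosome_expression(ch, c("d1", "d2"), digits = 17)
    val <- suppressWarnings(
      eval(parse(text = expr), list(d1 = X[1, 1], d2 = X[1, 2])))
    expect_same_numeric(val, evaluate_chromosome(ch, X), tol = 1e-9)
  }
})
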