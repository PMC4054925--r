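# Independent oracles, deliberately implemented with different algorithms
# and data structures than the package internals they check.

## -- ordinary least squares via the explicit normal equations ---------------
oracle_normal_equations <- function(X, y) {
  Xd <- cbind(1, X)
  drop(solve(t(Xd) %*% Xd, t(Xd) %*% y))
}

## -- leave-one-out Q^2 by naive n-times refitting ----------------------------
oracle_loo_q2 <- function(X, y) {
  n <- nrow(X)
  press <- 0
  for (i in seq_len(n)) {
    Xd <- cbind(1, X[-i, , drop = FALSE])
    b <- solve(t(Xd) %*% Xd, t(Xd) %*% y[-i])
    pred <- drop(c(1, X[i, ]) %*% b)
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

## -- Karva decoding as an explicit breadth-first pointer tree, evaluated by
##    scalar recursion row by row ---------------------------------------------
oracle_decode <- function(sym, dc = integer(0), consts = numeric(0)) {
  arities <- c(2L, 2L, 2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L)
  pos <- 0L
  rnc <- 0L
  new_node <- function() {
    pos <<- pos + 1L
    n <- new.env(parent = emptyenv())
    n$s <- sym[pos]
    if (n$s == 0L) { rnc <<- rnc + 1L; n$value <- consts[dc[rnc]] }
    n$children <- list()
    n
  }
  root <- new_node()
  queue <- list(root)
  while (length(queue)) {
    nd <- queue[[1L]]
    queue <- queue[-1L]
    a <- if (nd$s > 0L) arities[nd$s] else 0L
    for (k in seq_len(a)) {
      ch <- new_node()
      nd$children[[k]] <- ch
      queue <- c(queue, list(ch))
    }
  }
  root
}

oracle_eval_node <- function(nd, row) {
  s <- nd$s
  if (s == 0L) return(nd$value)
  if (s < 0L) return(row[-s])
  a <- oracle_eval_node(nd$children[[1L]], row)
  switch(s,
         a + oracle_eval_node(nd$children[[2L]], row),
         a - oracle_eval_node(nd$children[[2L]], row),
         a * oracle_eval_node(nd$children[[2L]], row),
         a / oracle_eval_node(nd$children[[2L]], row),
         a ^ oracle_eval_node(nd$children[[2L]], row),
         sqrt(a),
         sin(a),
         tan(a),
         log(a),
         10^a)
}

oracle_eval_chromosome <- function(chrom, row) {
  total <- 0
  for (g in seq_len(nrow(chrom$symbols))) {
    tree <- oracle_decode(chrom$symbols[g, ], chrom$dc[g, ], chrom$constants[g, ])
    total <- total + suppressWarnings(oracle_eval_node(tree, row))
  }
  total
}

## -- second, independent transcription of the published linear model --------
oracle_published_linear <- function(lumo, mreco, ksind, zx, maseoat,
                                    maseoat_slope = 0.84804) {
  -195.01 + 2.4570 * lumo - 3.6715 * mreco - 0.20681 * ksind -
    7.0757 * zx + maseoat_slope * maseoat
}

## -- second, independent transcription of the published GEP model -----------
oracle_published_gep <- function(lumo, mreco, ksind, zx, maseoat) {
  suppressWarnings(oracle_published_gep_(lumo, mreco, ksind, zx, maseoat))
}

oracle_published_gep_ <- function(lumo, mreco, ksind, zx, maseoat) {
  t1 <- sin(tan(tan(mreco) / sin(maseoat)))
  t2 <- sin(sin((tan(mreco) / lumo) - zx))
  t3 <- lumo
  t4 <- maseoat ^ (maseoat ^ lumo / ksind)
  t5 <- sin(sqrt(ksind - tan(sin(tan(ksind * (-7.653931))))))
  t1 + t2 + t3 + t4 + t5
}

## compare numeric vectors that may legitimately contain non-finite entries
expect_same_numeric <- function(a, b, tol = 1e-12) {
  expect_identical(is.finite(a), is.finite(b))
  fin <- is.finite(a)
  if (any(fin)) {
    expect_equal(a[fin], b[fin], tolerance = tol, ignore_attr = TRUE)
  }
}
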