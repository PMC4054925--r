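## Karva-notation chromosomes.
##
## A chromosome holds `genes` rows of three aligned matrices:
##   symbols : integer, genes x (head + tail); >0 function id, <0 terminal
##             (descriptor -s), 0 the RNC placeholder "?"
##   dc      : integer, genes x tail; 1-based indices into the constants row
##   constants: double, genes x constants_per_gene, drawn from const_bounds
## The tail region holds terminals only, which together with
## tail = head + 1 guarantees that every gene decodes to a complete
## expression tree (Karva closure).

new_chromosome <- function(symbols, dc, constants) {
  structure(list(symbols = symbols, dc = dc, constants = constants),
            class = "gep_chromosome")
}

## alphabets from which head and tail positions are drawn
gep_alphabets <- function(config, n_terminals) {
  if (n_terminals < 1L) stop_config("GEP needs at least one terminal")
  terminals <- -seq_len(n_terminals)
  if (config$constants_per_gene > 0L) terminals <- c(terminals, 0L)
  list(head = c(config$functions$ids, terminals), tail = terminals)
}

#' Random GEP population
#'
#' Samples structurally valid chromosomes: head positions uniform over
#' functions, terminals and the RNC placeholder; tail positions uniform over
#' terminals and the placeholder; Dc indices uniform over the constants;
#' constants uniform in the configured bounds.
#'
#' @param config a [gep_config()].
#' @param n_terminals number of descriptor terminals d1..dp.
#' @param seed integer seed.
#' @return List of `population_size` chromosomes.
#' @export
random_population <- function(config, n_terminals, seed = 1L) {
  ab <- gep_alphabets(config, n_terminals)
  G <- config$genes; h <- config$head; t <- config$tail
  nc <- config$constants_per_gene
  with_seed(seed, {
    lapply(seq_len(config$population_size), function(i) {
      symbols <- cbind(
        matrix(sample(ab$head, G * h, replace = TRUE), G, h),
        matrix(sample(ab$tail, G * t, replace = TRUE), G, t))
      dc <- matrix(if (nc > 0L) sample.int(nc, G * t, replace = TRUE) else 1L,
                   G, t)
      constants <- matrix(runif(G * max(nc, 0L), config$const_bounds[1L],
                                config$const_bounds[2L]), G, max(nc, 0L))
      new_chromosome(symbols, dc, constants)
    })
  })
}

#' Validate chromosome structure
#'
#' Checks the Karva closure invariants: correct matrix shapes, tail holding
#' terminals (or the RNC placeholder) only, head symbols drawn from the
#' configured alphabet, and Dc indices within the constants range.
#'
#' @param chrom a chromosome.
#' @param config a [gep_config()].
#' @param n_terminals number of descriptor terminals.
#' @return `TRUE`, invisibly; invalid structure raises an error.
#' @export
validate_chromosome <- function(chrom, config, n_terminals) {
  ab <- gep_alphabets(config, n_terminals)
  G <- config$genes; h <- config$head; t <- config$tail
  stopifnot(identical(dim(chrom$symbols), c(G, h + t)),
            identical(dim(chrom$dc), c(G, t)))
  if (!all(chrom$symbols[, seq_len(h), drop = FALSE] %in% ab$head)) {
    stop_numerical("invalid head symbol")
  }
  if (!all(chrom$symbols[, h + seq_len(t), drop = FALSE] %in% ab$tail)) {
    stop_numerical("non-terminal symbol in tail")
  }
  if (config$constants_per_gene > 0L) {
    if (!all(chrom$dc >= 1L & chrom$dc <= config$constants_per_gene)) {
      stop_numerical("Dc index out of range")
    }
    if (!all(chrom$constants >= config$const_bounds[1L] &
             chrom$constants <= config$const_bounds[2L])) {
      stop_numerical("constant outside bounds")
    }
  }
  invisible(TRUE)
}

#' Decode a Karva gene into an expression tree
#'
#' Karva (K-expression) decoding is breadth-first: symbols are read left to
#' right and each function node takes its children from the next unassigned
#' positions, level by level; reading stops when the tree is complete, so
#' trailing symbols are noncoding.  RNC placeholders ("?") consume Dc
#' indices in reading order and resolve to their constants.
#'
#' @param symbols integer symbol vector of one gene (head then tail).
#' @param dc integer Dc index vector of the gene.
#' @param constants numeric constants of the gene.
#' @return Object of class `gep_tree`: a list with parallel vectors `sym`,
#'   `left`, `right` (1-based child indices, `NA` = none) and `value`
#'   (resolved constants for `"?"` nodes).
#' @examples
#' # "* + a b c" decodes to (a + b) * c, read level by level
#' decode_gene(c(3L, 1L, -1L, -2L, -3L, -1L, -1L, -1L, -1L))
#' @export
decode_gene <- function(symbols, dc = integer(0), constants = numeric(0)) {
  d <- cpp_decode_gene(as.integer(symbols))
  m <- d$length
  sym <- symbols[seq_len(m)]
  value <- rep(NA_real_, m)
  is_rnc <- d$rnc_order >= 0L
  if (any(is_rnc)) {
    value[is_rnc] <- constants[dc[d$rnc_order[is_rnc] + 1L]]
  }
  structure(list(sym = sym,
                 left = ifelse(d$left >= 0L, d$left + 1L, NA_integer_),
                 right = ifelse(d$right >= 0L, d$right + 1L, NA_integer_),
                 value = value),
            class = "gep_tree")
}

#' @export
print.gep_tree <- function(x, ...) {
  cat("gep_tree with", length(x$sym), "nodes:",
      format_gep_tree(x, paste0("d", 1:9)), "\n")
  invisible(x)
}

#' Evaluate a chromosome on descriptor data
#'
#' Decodes every gene, evaluates it over the rows of `X` and returns the sum
#' of the gene values (addition linking).  Arithmetic is IEEE "protected":
#' invalid operations produce non-finite values that propagate to the output
#' and are later mapped to fitness zero, never masked.
#'
#' @param chrom a chromosome.
#' @param X numeric matrix with one column per terminal (a single row for a
#'   single compound).
#' @return Numeric vector of length `nrow(X)`.
#' @export
evaluate_chromosome <- function(chrom, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  cpp_eval_chromosome(chrom$symbols, chrom$dc, chrom$constants, X)
}

## infix rendering -----------------------------------------------------------

format_gep_tree <- function(tree, terminal_names, digits = 6) {
  rec <- function(i) {
    s <- tree$sym[i]
    if (s == 0L) return(format(tree$value[i], digits = digits))
    if (s < 0L) return(terminal_names[-s])
    nm <- GEP_FUNCTION_NAMES[s]
    if (GEP_FUNCTION_ARITY[s] == 1L) {
      inner <- rec(tree$left[i])
      return(switch(nm,
                    sqrt = paste0("sqrt(", inner, ")"),
                    sin = paste0("sin(", inner, ")"),
                    tan = paste0("tan(", inner, ")"),
                    ln = paste0("log(", inner, ")"),
                    pow10 = paste0("10^(", inner, ")")))
    }
    a <- rec(tree$left[i]); b <- rec(tree$right[i])
    if (nm == "pow") paste0("(", a, ")^(", b, ")")
    else paste0("(", a, " ", nm, " ", b, ")")
  }
  rec(1L)
}

#' Render a chromosome as an infix expression
#'
#' @param chrom a chromosome.
#' @param terminal_names descriptor names substituted for the terminals.
#' @param digits significant digits for embedded constants.
#' @return A single string: the sum of the per-gene infix expressions.
#' @export
chromosome_expression <- function(chrom, terminal_names, digits = 6) {
  terms <- vapply(seq_len(nrow(chrom$symbols)), function(g) {
    format_gep_tree(decode_gene(chrom$symbols[g, ], chrom$dc[g, ],
                                chrom$constants[g, ]),
                    terminal_names, digits)
  }, "")
  paste(terms, collapse = " + ")
}

## JSON genome ---------------------------------------------------------------

#' Serialize / restore a chromosome genome
#'
#' The genome travels as plain lists (per-gene symbol strings, Dc indices
#' and constants), suitable for `jsonlite`.
#'
#' @param chrom a chromosome.
#' @return `chromosome_to_list()`: a plain list; `chromosome_from_list()`:
#'   a `gep_chromosome`.
#' @export
chromosome_to_list <- function(chrom) {
  list(symbols = apply(chrom$symbols, 1L, as.integer, simplify = FALSE),
       dc = apply(chrom$dc, 1L, as.integer, simplify = FALSE),
       constants = apply(chrom$constants, 1L, as.numeric, simplify = FALSE))
}

#' @param genome a list produced by `chromosome_to_list()` (possibly
#'   round-tripped through JSON).
#' @rdname chromosome_to_list
#' @export
chromosome_from_list <- function(genome) {
  new_chromosome(do.call(rbind, lapply(genome$symbols, as.integer)),
                 do.call(rbind, lapply(genome$dc, as.integer)),
                 do.call(rbind, lapply(genome$constants, as.numeric)))
}

## ---- fitness functions ----------------------------------------------------

#' Relative-error GEP fitness with a selection range
#'
#' The per-case score is `R - |100 * (P - T) / T|`, floored at zero so a
#' case predicted with more than 100% relative error contributes nothing
#' (keeping the total non-negative for roulette selection); the chromosome
#' fitness is the sum over fitness cases, with maximum `R * n` at perfect
#' prediction.  Despite its traditional name ("absolute-error fitness"),
#' the formula scores relative error — it is implemented exactly as
#' published.  A non-finite prediction anywhere zeroes the fitness.
#'
#' @param predictions,targets numeric vectors of equal length.
#' @param selection_range the per-case ceiling R.
#' @return Scalar fitness in `[0, R * length(targets)]`.
#' @export
fitness_abs <- function(predictions, targets, selection_range = 100) {
  stopifnot(length(predictions) == length(targets))
  if (any(targets == 0)) {
    stop_config("fitness_abs: a target value is exactly 0, so relative ",
                "error is undefined; use the MSE fitness instead")
  }
  if (any(!is.finite(predictions))) return(0)
  sum(pmax(selection_range - abs(100 * (predictions - targets) / targets), 0))
}

#' Mean-squared-error GEP fitness
#'
#' `1000 / (1 + MSE)`: 1000 at a perfect fit, 500 at MSE 1, approaching 0
#' for poor models.  A non-finite prediction anywhere yields fitness 0
#' (the protected-math policy: invalid programs stay alive but are
#' unselectable).
#'
#' @param predictions,targets numeric vectors of equal length.
#' @return Scalar fitness in `[0, 1000]`.
#' @export
fitness_mse <- function(predictions, targets) {
  stopifnot(length(predictions) == length(targets))
  if (any(!is.finite(predictions))) return(0)
  1000 / (1 + mean((predictions - targets)^2))
}
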