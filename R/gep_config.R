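## Function set and run configuration of the GEP engine.

## Global function table: ids are fixed package-wide; a configuration may
## restrict the usable subset but never renumbers.
GEP_FUNCTION_NAMES <- c("+", "-", "*", "/", "pow", "sqrt", "sin", "tan",
                        "ln", "pow10")
GEP_FUNCTION_ARITY <- c(2L, 2L, 2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L)

#' GEP function set
#'
#' The operator suite available to chromosomes: addition, subtraction,
#' multiplication, division, power, square root, sine, tangent, natural
#' logarithm and 10^x.  All ten are enabled by default; pass a subset of
#' names to restrict the search space.
#'
#' @param names character subset of
#'   `c("+", "-", "*", "/", "pow", "sqrt", "sin", "tan", "ln", "pow10")`.
#' @return Object of class `gep_function_set` with elements `ids`, `names`
#'   and `arities`.
#' @export
gep_function_set <- function(names = GEP_FUNCTION_NAMES) {
  ids <- match(names, GEP_FUNCTION_NAMES)
  if (anyNA(ids)) {
    stop_config("unknown function(s): ",
                paste(names[is.na(ids)], collapse = ", "))
  }
  if (anyDuplicated(ids)) stop_config("duplicate function names")
  structure(list(ids = as.integer(ids),
                 names = GEP_FUNCTION_NAMES[ids],
                 arities = GEP_FUNCTION_ARITY[ids]),
            class = "gep_function_set")
}

#' @export
print.gep_function_set <- function(x, ...) {
  cat("gep_function_set:", paste(x$names, collapse = " "), "\n")
  invisible(x)
}

#' GEP run configuration
#'
#' Defaults follow the parameter selection of the source study's GEP runs:
#' 100 chromosomes of 5 genes linked by addition, head size 8 (hence tail 9,
#' Dc domain 9 and total gene size 26), 10 floating-point random numerical
#' constants per gene drawn from \[-10, 10\], the full ten-function suite,
#' stopping after 200 generations without improvement with 3 independent
#' tries, and the operator rates: mutation 0.044, inversion 0.1, IS and RIS
#' transposition 0.1, one- and two-point recombination 0.3, gene
#' recombination and gene transposition 0.1, RNC mutation 0.01, Dc mutation
#' 0.044, Dc inversion 0.1, Dc IS transposition 0.1.
#'
#' `max_complexity` is accepted for configuration compatibility with the
#' commercial GEP package but has no effect on this engine (no semantics are
#' defined for it here); a note is logged when verbose evolution is enabled.
#'
#' @param population_size chromosomes per generation (must be even, for
#'   pairwise recombination).
#' @param genes genes per chromosome, linked by addition.
#' @param head head length h; tail and Dc length are h + 1.
#' @param functions a [gep_function_set()].
#' @param rates named list of operator rates in \[0, 1\]; see Details.
#'   Mutation-type rates are per position, the others per chromosome (or
#'   per pair, for recombination).
#' @param constants_per_gene random numerical constants per gene (0 disables
#'   the "?" terminal).
#' @param const_bounds numeric length-2: RNC lower and upper bound.
#' @param generations_without_change stop a try when the best fitness has
#'   not improved for this many generations.
#' @param max_generations hard cap per try.
#' @param tries independent restarts; the best overall result is returned.
#' @param fitness `"mse"` (fitness 1000/(1+MSE)) or `"abs_error"` (the
#'   relative-error form with a selection range, see [fitness_abs()]).
#' @param selection_range selection range R of the `"abs_error"` fitness.
#' @param max_complexity accepted, unused (see Details).
#' @return Object of class `gep_config`.
#' @export
gep_config <- function(population_size = 100L,
                       genes = 5L,
                       head = 8L,
                       functions = gep_function_set(),
                       rates = list(),
                       constants_per_gene = 10L,
                       const_bounds = c(-10, 10),
                       generations_without_change = 200L,
                       max_generations = 2000L,
                       tries = 3L,
                       fitness = c("mse", "abs_error"),
                       selection_range = 100,
                       max_complexity = 5L) {
  default_rates <- list(mutation = 0.044,
                        inversion = 0.1,
                        is_transposition = 0.1,
                        ris_transposition = 0.1,
                        one_point_recombination = 0.3,
                        two_point_recombination = 0.3,
                        gene_recombination = 0.1,
                        gene_transposition = 0.1,
                        rnc_mutation = 0.01,
                        dc_mutation = 0.044,
                        dc_inversion = 0.1,
                        dc_is_transposition = 0.1)
  unknown <- setdiff(names(rates), names(default_rates))
  if (length(unknown)) {
    stop_config("gep_config: unknown rate(s): ", paste(unknown, collapse = ", "))
  }
  default_rates[names(rates)] <- rates
  bad <- vapply(default_rates, function(r) r < 0 || r > 1, TRUE)
  if (any(bad)) {
    stop_config("gep_config: rates must lie in [0, 1]: ",
                paste(names(default_rates)[bad], collapse = ", "))
  }
  population_size <- as.integer(population_size)
  if (population_size < 2L || population_size %% 2L != 0L) {
    stop_config("gep_config: population_size must be even and >= 2")
  }
  head <- as.integer(head)
  if (head < 1L) stop_config("gep_config: head must be >= 1")
  stopifnot(length(const_bounds) == 2L, const_bounds[1L] < const_bounds[2L])
  tail <- head + 1L   # t = h (max_arity - 1) + 1 with max arity 2
  structure(list(population_size = population_size,
                 genes = as.integer(genes),
                 head = head,
                 tail = tail,
                 gene_length = head + 2L * tail,
                 functions = functions,
                 rates = default_rates,
                 constants_per_gene = as.integer(constants_per_gene),
                 const_bounds = as.numeric(const_bounds),
                 generations_without_change = as.integer(generations_without_change),
                 max_generations = as.integer(max_generations),
                 tries = as.integer(tries),
                 fitness = match.arg(fitness),
                 selection_range = selection_range,
                 max_complexity = max_complexity),
            class = "gep_config")
}

#' @export
print.gep_config <- function(x, ...) {
  cat(sprintf(paste0("gep_config: %d chromosomes x %d genes, head %d",
                     " (gene length %d), %d RNCs in [%g, %g]\n"),
              x$population_size, x$genes, x$head, x$gene_length,
              x$constants_per_gene, x$const_bounds[1L], x$const_bounds[2L]))
  cat(sprintf("  fitness: %s; stop: %d generations without change, %d tries\n",
              x$fitness, x$generations_without_change, x$tries))
  invisible(x)
}
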