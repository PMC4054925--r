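# Small fixtures built in code.

toy_table <- function(n = 6, p = 4, seed = 11, with_activity = TRUE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("cpd%02d", seq_len(n)),
                              paste0("D", seq_len(p))))
  descriptor_table(X, activity = if (with_activity) rnorm(n))
}

## a minimal GEP config for structural tests (small, fast)
tiny_gep_config <- function(...) {
  gep_config(population_size = 10L, genes = 3L, head = 4L,
             constants_per_gene = 4L, max_generations = 5L,
             generations_without_change = 5L, tries = 1L, ...)
}

## random chromosomes without going through the evolution loop
random_chromosomes <- function(config, n_terminals, n, seed = 1) {
  cfg <- config
  stopifnot(n <= cfg$population_size || n > 0)
  pop <- random_population(config, n_terminals, seed = seed)
  pop[seq_len(min(n, length(pop)))]
}
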