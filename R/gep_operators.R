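## Genetic operators.
##
## Rate semantics: mutation-type rates (symbol mutation, Dc mutation, RNC
## mutation) are per position; inversion and the transpositions are per
## chromosome; the recombinations are per consecutive pair.  Mutation
## resamples a *different* symbol from the positional alphabet, so the
## configured rate equals the expected fraction of changed symbols.  All
## operators preserve the head/tail/Dc structure (closure), so offspring
## never need repair.

sample1 <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

## resample each masked entry from `alphabet` excluding its current value
mutate_entries <- function(vec, mask, alphabet) {
  for (i in which(mask)) {
    alt <- alphabet[alphabet != vec[i]]
    if (length(alt)) vec[i] <- sample1(alt)
  }
  vec
}

op_mutation <- function(chrom, config, ab) {
  rate <- config$rates$mutation
  if (rate <= 0) return(chrom)
  h <- config$head; t <- config$tail
  sym <- chrom$symbols
  mask <- matrix(runif(length(sym)) < rate, nrow(sym))
  if (any(mask)) {
    for (g in seq_len(nrow(sym))) {
      headmask <- mask[g, seq_len(h)]
      tailmask <- mask[g, h + seq_len(t)]
      sym[g, seq_len(h)] <- mutate_entries(sym[g, seq_len(h)], headmask, ab$head)
      sym[g, h + seq_len(t)] <- mutate_entries(sym[g, h + seq_len(t)],
                                               tailmask, ab$tail)
    }
    chrom$symbols <- sym
  }
  chrom
}

op_inversion <- function(chrom, config) {
  if (runif(1) >= config$rates$inversion) return(chrom)
  h <- config$head
  if (h < 2L) return(chrom)
  g <- sample.int(config$genes, 1L)
  ends <- sort(sample.int(h, 2L))
  idx <- ends[1L]:ends[2L]
  chrom$symbols[g, idx] <- chrom$symbols[g, rev(idx)]
  chrom
}

## insert `seg` into the head of gene g at position pos (never the root),
## shifting existing symbols right and truncating to the head length
head_insert <- function(chrom, g, seg, pos, h) {
  head_sym <- chrom$symbols[g, seq_len(h)]
  new_head <- append(head_sym, seg, after = pos - 1L)[seq_len(h)]
  chrom$symbols[g, seq_len(h)] <- new_head
  chrom
}

op_is_transposition <- function(chrom, config) {
  if (runif(1) >= config$rates$is_transposition) return(chrom)
  h <- config$head; len_gene <- h + config$tail
  if (h < 2L) return(chrom)
  gs <- sample.int(config$genes, 1L)   # source gene
  gt <- sample.int(config$genes, 1L)   # target gene
  start <- sample.int(len_gene, 1L)
  len <- min(sample.int(3L, 1L), len_gene - start + 1L, h - 1L)
  if (len < 1L) return(chrom)
  seg <- chrom$symbols[gs, start:(start + len - 1L)]
  pos <- if (h == 2L) 2L else sample(2:h, 1L)
  head_insert(chrom, gt, seg, pos, h)
}

op_ris_transposition <- function(chrom, config) {
  if (runif(1) >= config$rates$ris_transposition) return(chrom)
  h <- config$head; len_gene <- h + config$tail
  g <- sample.int(config$genes, 1L)
  ## scan the head from a random point for the first function symbol
  from <- sample.int(h, 1L)
  fpos <- from + which(chrom$symbols[g, from:h] > 0L)[1L] - 1L
  if (is.na(fpos)) return(chrom)   # no function downstream: do nothing
  len <- min(sample.int(3L, 1L), len_gene - fpos + 1L, h)
  seg <- chrom$symbols[g, fpos:(fpos + len - 1L)]
  head_insert(chrom, g, seg, 1L, h)
}

op_gene_transposition <- function(chrom, config) {
  if (runif(1) >= config$rates$gene_transposition || config$genes < 2L) {
    return(chrom)
  }
  g <- sample.int(config$genes, 1L)
  ord <- c(g, setdiff(seq_len(config$genes), g))
  chrom$symbols <- chrom$symbols[ord, , drop = FALSE]
  chrom$dc <- chrom$dc[ord, , drop = FALSE]
  chrom$constants <- chrom$constants[ord, , drop = FALSE]
  chrom
}

op_dc_mutation <- function(chrom, config) {
  rate <- config$rates$dc_mutation
  nc <- config$constants_per_gene
  if (rate <= 0 || nc < 2L) return(chrom)
  dc <- chrom$dc
  mask <- matrix(runif(length(dc)) < rate, nrow(dc))
  for (i in which(mask)) {
    alt <- setdiff(seq_len(nc), dc[i])
    dc[i] <- sample1(alt)
  }
  chrom$dc <- dc
  chrom
}

op_dc_inversion <- function(chrom, config) {
  if (runif(1) >= config$rates$dc_inversion) return(chrom)
  t <- config$tail
  if (t < 2L) return(chrom)
  g <- sample.int(config$genes, 1L)
  ends <- sort(sample.int(t, 2L))
  idx <- ends[1L]:ends[2L]
  chrom$dc[g, idx] <- chrom$dc[g, rev(idx)]
  chrom
}

op_dc_is_transposition <- function(chrom, config) {
  if (runif(1) >= config$rates$dc_is_transposition) return(chrom)
  t <- config$tail
  if (t < 2L) return(chrom)
  g <- sample.int(config$genes, 1L)
  start <- sample.int(t, 1L)
  len <- min(sample.int(3L, 1L), t - start + 1L)
  seg <- chrom$dc[g, start:(start + len - 1L)]
  pos <- sample.int(t, 1L)
  chrom$dc[g, ] <- append(chrom$dc[g, ], seg, after = pos - 1L)[seq_len(t)]
  chrom
}

op_rnc_mutation <- function(chrom, config) {
  rate <- config$rates$rnc_mutation
  if (rate <= 0 || config$constants_per_gene < 1L) return(chrom)
  cst <- chrom$constants
  mask <- runif(length(cst)) < rate
  if (any(mask)) {
    cst[mask] <- runif(sum(mask), config$const_bounds[1L],
                       config$const_bounds[2L])
    chrom$constants <- cst
  }
  chrom
}

## flattened one-/two-point recombination over (symbols | dc) per gene;
## whole genes beyond the cut also swap their constants, the split gene
## keeps each parent's own constants
flatten_len <- function(config) config$genes * (config$head + 2L * config$tail)

swap_after <- function(a, b, cut, config) {
  gl <- config$head + 2L * config$tail   # symbols + dc per gene
  sl <- config$head + config$tail
  for (g in seq_len(config$genes)) {
    off <- (g - 1L) * gl
    if (off + gl <= cut) next
    local_cut <- max(cut - off, 0L)
    ## symbol part
    if (local_cut < sl) {
      idx <- (local_cut + 1L):sl
      tmp <- a$symbols[g, idx]; a$symbols[g, idx] <- b$symbols[g, idx]
      b$symbols[g, idx] <- tmp
    }
    ## dc part
    dstart <- max(local_cut - sl, 0L)
    if (dstart < config$tail) {
      idx <- (dstart + 1L):config$tail
      tmp <- a$dc[g, idx]; a$dc[g, idx] <- b$dc[g, idx]
      b$dc[g, idx] <- tmp
    }
    if (local_cut == 0L) {   # whole gene swapped: constants travel with it
      tmp <- a$constants[g, ]; a$constants[g, ] <- b$constants[g, ]
      b$constants[g, ] <- tmp
    }
  }
  list(a, b)
}

op_one_point_recombination <- function(a, b, config) {
  if (runif(1) >= config$rates$one_point_recombination) return(list(a, b))
  cut <- sample.int(flatten_len(config) - 1L, 1L)
  swap_after(a, b, cut, config)
}

op_two_point_recombination <- function(a, b, config) {
  if (runif(1) >= config$rates$two_point_recombination) return(list(a, b))
  L <- flatten_len(config)
  cuts <- sort(sample.int(L - 1L, 2L))
  out <- swap_after(a, b, cuts[1L], config)
  swap_after(out[[1L]], out[[2L]], cuts[2L], config)
}

op_gene_recombination <- function(a, b, config) {
  if (runif(1) >= config$rates$gene_recombination) return(list(a, b))
  g <- sample.int(config$genes, 1L)
  tmp_s <- a$symbols[g, ]; a$symbols[g, ] <- b$symbols[g, ]; b$symbols[g, ] <- tmp_s
  tmp_d <- a$dc[g, ]; a$dc[g, ] <- b$dc[g, ]; b$dc[g, ] <- tmp_d
  tmp_c <- a$constants[g, ]; a$constants[g, ] <- b$constants[g, ]
  b$constants[g, ] <- tmp_c
  list(a, b)
}

#' One GEP generation: selection and genetic operators
#'
#' Performs fitness-proportional (roulette-wheel) selection with single-elite
#' cloning, then applies the configured operators at their rates: symbol
#' mutation, head inversion, IS and RIS transposition, gene transposition,
#' one-point, two-point and gene recombination, and the Dc-domain analogues
#' (Dc mutation, Dc inversion, Dc IS transposition) plus RNC mutation.  With
#' all rates zero the offspring equal the selected parents exactly.
#'
#' If every fitness is zero, selection falls back to uniform (the condition
#' is reported via a `message()` once per call).
#'
#' @param population list of chromosomes.
#' @param fitnesses non-negative numeric vector, one per chromosome.
#' @param config a [gep_config()].
#' @param n_terminals number of descriptor terminals.
#' @return List of chromosomes of the same size; element 1 is the cloned
#'   elite.
#' @export
reproduce <- function(population, fitnesses, config, n_terminals) {
  npop <- length(population)
  stopifnot(length(fitnesses) == npop)
  if (any(fitnesses < 0)) stop_numerical("reproduce: negative fitness")
  ab <- gep_alphabets(config, n_terminals)
  elite <- population[[which.max(fitnesses)]]
  if (sum(fitnesses) <= 0) {
    message("reproduce: all fitnesses zero; falling back to uniform selection")
    idx <- sample.int(npop, npop, replace = TRUE)
  } else {
    idx <- sample.int(npop, npop, replace = TRUE, prob = fitnesses)
  }
  off <- population[idx]
  for (i in seq_len(npop)) {
    ch <- off[[i]]
    ch <- op_mutation(ch, config, ab)
    ch <- op_inversion(ch, config)
    ch <- op_is_transposition(ch, config)
    ch <- op_ris_transposition(ch, config)
    ch <- op_gene_transposition(ch, config)
    ch <- op_dc_mutation(ch, config)
    ch <- op_dc_inversion(ch, config)
    ch <- op_dc_is_transposition(ch, config)
    ch <- op_rnc_mutation(ch, config)
    off[[i]] <- ch
  }
  for (i in seq(1L, npop - 1L, by = 2L)) {
    pair <- op_one_point_recombination(off[[i]], off[[i + 1L]], config)
    pair <- op_two_point_recombination(pair[[1L]], pair[[2L]], config)
    pair <- op_gene_recombination(pair[[1L]], pair[[2L]], config)
    off[[i]] <- pair[[1L]]; off[[i + 1L]] <- pair[[2L]]
  }
  off[[1L]] <- elite
  off
}
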