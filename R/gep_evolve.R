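## The evolutionary loop: independent restarts ("tries"), each evolving a
## population until the best fitness stagnates, with single-elite cloning so
## the best-fitness trace is non-decreasing within a try.

#' Evolve a GEP symbolic-regression model
#'
#' Runs `config$tries` independent restarts.  Each try initialises a random
#' population, then repeats fitness evaluation (see [fitness_mse()] /
#' [fitness_abs()]) and [reproduce()] until the best fitness has not
#' improved for `config$generations_without_change` generations or
#' `config$max_generations` is reached.  The best chromosome over all tries
#' is returned with its full fitness trace.  Runs are bit-reproducible for
#' a given seed.
#'
#' @param table a [descriptor_table()] with activity, or a numeric matrix
#'   (then `y` is required).
#' @param config a [gep_config()].
#' @param seed integer seed; per-try sub-streams are derived from it.
#' @param y activity vector when `table` is a matrix.
#' @param descriptors optional character vector choosing terminal columns
#'   (default: all complete columns of the table).
#' @param verbose print per-try progress and configuration notes.
#' @return Object of class `gep_qsar`: `best_chromosome`, `best_fitness`,
#'   `expression` (infix string), `traces` (per-try best-fitness vectors),
#'   `tries` (per-try summary data frame), `fitted_values`, plus the data,
#'   seed and configuration used.
#' @examples
#' X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("d", 1:4)))
#' tab <- descriptor_table(X, activity = X[, 1])
#' cfg <- gep_config(max_generations = 20, tries = 1,
#'                   generations_without_change = 20)
#' fit <- gep_fit(tab, cfg, seed = 1)
#' fit$best_fitness
#' @export
gep_fit <- function(table, config = gep_config(), seed = 1L, y = NULL,
                    descriptors = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "gep_config"))
  if (inherits(table, "descriptor_table")) {
    y <- table$activity
    X <- table$values
  } else {
    X <- as.matrix(table)
  }
  if (is.null(y)) stop_data("gep_fit: no activity values supplied")
  if (is.null(descriptors)) {
    descriptors <- colnames(X)[colSums(is.na(X)) == 0L]
  }
  absent <- setdiff(descriptors, colnames(X))
  if (length(absent)) {
    stop_data("gep_fit: descriptor column(s) not found: ",
              paste(absent, collapse = ", "))
  }
  X <- X[, descriptors, drop = FALSE]
  storage.mode(X) <- "double"
  if (anyNA(X)) stop_data("gep_fit: missing values in chosen descriptors")
  y <- as.numeric(y)
  if (config$fitness == "abs_error" && any(y == 0)) {
    stop_config("gep_fit: zero activity target with the relative-error ",
                "fitness; use fitness = \"mse\"")
  }
  if (verbose && !is.null(config$max_complexity)) {
    message("gep_fit: max_complexity is accepted for compatibility and ignored")
  }
  p <- ncol(X)
  fit_fun <- if (config$fitness == "mse") {
    function(pred) fitness_mse(pred, y)
  } else {
    function(pred) fitness_abs(pred, y, config$selection_range)
  }

  best <- list(fitness = -Inf, chromosome = NULL, try = NA_integer_)
  traces <- vector("list", config$tries)
  try_summary <- data.frame(try = seq_len(config$tries),
                            generations = NA_integer_,
                            best_fitness = NA_real_)
  for (tr in seq_len(config$tries)) {
    seed_try <- derive_seed(seed, paste0("gep-try-", tr))
    pop <- random_population(config, p, seed = seed_try)
    res <- with_seed(derive_seed(seed, paste0("gep-run-", tr)), {
      trace <- numeric(0)
      best_try <- list(fitness = -Inf, chromosome = NULL)
      stagnant <- 0L
      gen <- 0L
      while (gen < config$max_generations &&
             stagnant < config$generations_without_change) {
        gen <- gen + 1L
        fits <- vapply(pop, function(ch) {
          fit_fun(cpp_eval_chromosome(ch$symbols, ch$dc, ch$constants, X))
        }, 0)
        gen_best <- which.max(fits)
        if (fits[gen_best] > best_try$fitness) {
          best_try <- list(fitness = fits[gen_best],
                           chromosome = pop[[gen_best]])
          stagnant <- 0L
        } else {
          stagnant <- stagnant + 1L
        }
        trace[gen] <- best_try$fitness
        if (gen < config$max_generations &&
            stagnant < config$generations_without_change) {
          pop <- reproduce(pop, fits, config, p)
        }
      }
      list(trace = trace, best = best_try, generations = gen)
    })
    traces[[tr]] <- res$trace
    try_summary$generations[tr] <- res$generations
    try_summary$best_fitness[tr] <- res$best$fitness
    if (verbose) {
      message(sprintf("try %d: best fitness %.4f after %d generations",
                      tr, res$best$fitness, res$generations))
    }
    if (res$best$fitness > best$fitness) {
      best <- list(fitness = res$best$fitness,
                   chromosome = res$best$chromosome, try = tr)
    }
  }
  fitted <- evaluate_chromosome(best$chromosome, X)
  structure(list(best_chromosome = best$chromosome,
                 best_fitness = best$fitness,
                 best_try = best$try,
                 expression = chromosome_expression(best$chromosome,
                                                    descriptors),
                 traces = traces,
                 tries = try_summary,
                 fitted_values = fitted,
                 descriptor_names = descriptors,
                 X = X, y = y,
                 seed = as.integer(seed),
                 config = config),
            class = "gep_qsar")
}

#' @export
print.gep_qsar <- function(x, ...) {
  cat("GEP symbolic regression model\n")
  cat(sprintf("  best fitness (%s): %.4f  (try %d of %d)\n",
              x$config$fitness, x$best_fitness, x$best_try,
              nrow(x$tries)))
  cat("  expression:\n   ", x$expression, "\n")
  invisible(x)
}

#' @export
summary.gep_qsar <- function(object, ...) {
  ps <- prediction_stats(object$y, object$fitted_values)
  list(best_fitness = object$best_fitness,
       tries = object$tries,
       train = ps,
       expression = object$expression)
}

#' @export
fitted.gep_qsar <- function(object, ...) object$fitted_values

#' @export
residuals.gep_qsar <- function(object, ...) object$y - object$fitted_values

#' @export
predict.gep_qsar <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted_values)
  if (inherits(newdata, "descriptor_table")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  absent <- setdiff(object$descriptor_names, colnames(newdata))
  if (length(absent)) {
    stop_data("predict: descriptor column(s) absent from newdata: ",
              paste(absent, collapse = ", "))
  }
  m <- newdata[, object$descriptor_names, drop = FALSE]
  storage.mode(m) <- "double"
  if (anyNA(m)) stop_data("predict: missing descriptor values")
  evaluate_chromosome(object$best_chromosome, m)
}

#' @export
plot.gep_qsar <- function(x, which = c("trace", "fit"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    tr <- x$traces[[x$best_try]]
    graphics::plot(seq_along(tr), tr, type = "l", xlab = "generation",
                   ylab = "best fitness", main = "GEP evolution", ...)
  } else {
    graphics::plot(x$y, x$fitted_values, xlab = "experimental log(IC50)",
                   ylab = "predicted log(IC50)", main = "GEP model", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Serialize a GEP model to JSON
#'
#' Writes the genome (symbols, Dc indices, constants), the infix
#' expression, fitness and per-try summaries.
#'
#' @param fit a `gep_qsar` object.
#' @param path output path.
#' @param provenance optional named list embedded verbatim.
#' @return `path`, invisibly.
#' @export
write_gep_model <- function(fit, path, provenance = NULL) {
  stopifnot(inherits(fit, "gep_qsar"))
  out <- list(type = "gep_qsar",
              descriptor_names = fit$descriptor_names,
              genome = chromosome_to_list(fit$best_chromosome),
              expression = fit$expression,
              fitness = fit$best_fitness,
              fitness_kind = fit$config$fitness,
              tries = fit$tries,
              seed = fit$seed,
              provenance = provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialized GEP model
#'
#' @param path path to a JSON file written by [write_gep_model()].
#' @return A list of class `gep_qsar_loaded`; usable with
#'   [evaluate_chromosome()] via its `$best_chromosome`, or with `predict()`.
#' @export
read_gep_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$type, "gep_qsar")) stop_data(path, ": not a gep_qsar file")
  structure(list(best_chromosome = chromosome_from_list(obj$genome),
                 descriptor_names = unlist(obj$descriptor_names),
                 expression = obj$expression,
                 best_fitness = obj$fitness),
            class = c("gep_qsar_loaded", "gep_qsar"))
}
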