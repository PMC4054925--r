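## The heuristic method (HM) of CODESSA-style QSAR: rule-based descriptor
## pre-filtering, pairwise collinearity control, and a heuristic best-subset
## search over multiple linear regressions with a descriptor-count stopping
## standard based on the R^2 increment and the leave-one-out Q^2.

#' Configuration of the heuristic descriptor selection
#'
#' The four pre-filter exclusion rules are applied in order:
#' \enumerate{
#' \item descriptors not available for every compound (any missing value);
#' \item descriptors with too little variation: relative standard deviation
#'   (sd/|mean|, or plain sd when the mean is near zero) below
#'   `variance_floor`, or fewer than `min_distinct` distinct values;
#' \item descriptors whose one-parameter regression has F below
#'   `min_one_param_F` (1.0, after the method's published rule);
#' \item descriptors whose one-parameter Student |t| falls below `min_abs_t`
#'   (the method leaves this threshold user-defined; 1.5 by default).
#' }
#' Any two descriptors whose absolute Pearson correlation reaches
#' `collinearity_cap` (0.8 by default) are never allowed in the same model.
#' Model growth stops before size k unless the best k-descriptor model
#' improves R^2 by at least `delta_r2_stop` over the best (k-1)-descriptor
#' model without decreasing Q^2 — the "over-parameterization" guard.
#'
#' @param collinearity_cap pairwise |r| at or above which two descriptors are
#'   mutually exclusive; in (0, 1].
#' @param min_one_param_F rule-3 threshold on the one-parameter F.
#' @param min_abs_t rule-4 threshold on the one-parameter |t|.
#' @param variance_floor rule-2 relative-sd floor.
#' @param min_distinct rule-2 minimum number of distinct values.
#' @param delta_r2_stop minimum R^2 increment to accept one more descriptor.
#' @param max_subset_size largest model size searched.
#' @param beam_width beam width of the heuristic search.
#' @param search `"beam"` (default) or `"exhaustive"` (all admissible
#'   subsets; only sensible for small descriptor pools).
#' @return Object of class `hm_config`.
#' @export
hm_config <- function(collinearity_cap = 0.8,
                      min_one_param_F = 1.0,
                      min_abs_t = 1.5,
                      variance_floor = 1e-6,
                      min_distinct = 4L,
                      delta_r2_stop = 0.02,
                      max_subset_size = 8L,
                      beam_width = 10L,
                      search = c("beam", "exhaustive")) {
  search <- match.arg(search)
  if (!(collinearity_cap > 0 && collinearity_cap <= 1)) {
    stop_config("hm_config: collinearity_cap must lie in (0, 1]")
  }
  for (nm in c("min_one_param_F", "min_abs_t", "variance_floor",
               "delta_r2_stop")) {
    if (get(nm) < 0) stop_config("hm_config: ", nm, " must be >= 0")
  }
  structure(list(collinearity_cap = collinearity_cap,
                 min_one_param_F = min_one_param_F,
                 min_abs_t = min_abs_t,
                 variance_floor = variance_floor,
                 min_distinct = as.integer(min_distinct),
                 delta_r2_stop = delta_r2_stop,
                 max_subset_size = as.integer(max_subset_size),
                 beam_width = as.integer(beam_width),
                 search = search),
            class = "hm_config")
}

#' Rule-based descriptor pre-filter
#'
#' Applies the four exclusion rules of [hm_config()] in order and logs, for
#' every excluded descriptor, the first rule that removed it.  An empty
#' survivor set is a valid (logged) outcome, not an error.
#'
#' @param table a [descriptor_table()] with activity.
#' @param config an [hm_config()].
#' @return Object of class `hm_prefilter`: list with `excluded` (named
#'   integer vector mapping descriptor to rule id 1-4), `survivors`
#'   (character), and the per-descriptor one-parameter statistics.
#' @export
hm_prefilter <- function(table, config = hm_config()) {
  stopifnot(inherits(table, "descriptor_table"))
  y <- table$activity
  if (is.null(y)) stop_data("hm_prefilter: table has no activity")
  X <- table$values
  n <- nrow(X)
  excluded <- integer(0)
  one_t <- rep(NA_real_, ncol(X)); names(one_t) <- colnames(X)
  for (nm in colnames(X)) {
    v <- X[, nm]
    if (anyNA(v)) { excluded[nm] <- 1L; next }
    s <- sd(v)
    rel_sd <- if (abs(mean(v)) > 1e-12) s / abs(mean(v)) else s
    if (rel_sd < config$variance_floor ||
        length(unique(v)) < config$min_distinct) { excluded[nm] <- 2L; next }
    r <- cor(v, y)
    tval <- abs(r) * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    one_t[nm] <- tval
    if (tval^2 < config$min_one_param_F) { excluded[nm] <- 3L; next }
    if (tval < config$min_abs_t) { excluded[nm] <- 4L; next }
  }
  structure(list(excluded = excluded,
                 survivors = setdiff(colnames(X), names(excluded)),
                 one_param_t = one_t,
                 n = n),
            class = "hm_prefilter")
}

#' @export
print.hm_prefilter <- function(x, ...) {
  cat(sprintf("hm_prefilter: %d survivors, %d excluded\n",
              length(x$survivors), length(x$excluded)))
  if (length(x$excluded)) {
    for (r in sort(unique(x$excluded))) {
      cat(sprintf("  rule %d: %s\n", r,
                  paste(names(x$excluded)[x$excluded == r], collapse = ", ")))
    }
  }
  invisible(x)
}

#' Pairwise collinearity check for a descriptor subset
#'
#' `TRUE` iff every pair of descriptors in `subset` has absolute Pearson
#' correlation below the cap (singletons and the empty set pass trivially).
#'
#' @param subset character vector of descriptor names.
#' @param table a [descriptor_table()] (or a precomputed correlation matrix).
#' @param cap the collinearity cap.
#' @return Logical scalar.
#' @export
collinearity_ok <- function(subset, table, cap = 0.8) {
  if (length(subset) < 2L) return(TRUE)
  C <- if (is.matrix(table)) table else cor(table$values[, subset, drop = FALSE])
  C <- abs(C[subset, subset])
  diag(C) <- 0
  all(C < cap)
}

## R^2 of an OLS fit on the given columns (internal, no validation)
subset_r2 <- function(X, y, cols, sst) {
  f <- lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
  1 - sum(f$residuals^2) / sst
}

#' Heuristic best-subset descriptor selection
#'
#' Runs the rule-based pre-filter, then searches subsets of the surviving
#' descriptors under the collinearity constraint and records the best model
#' at each size.  The default search is a beam search seeded by the
#' descriptors with the highest one-parameter R^2, expanding each beam
#' member by every admissible survivor (a reproducible approximation of the
#' method's "rapid screening"); `search = "exhaustive"` enumerates all
#' admissible subsets instead.  Ties in R^2 are broken lexicographically by
#' descriptor names, so results are deterministic.
#'
#' The chosen size is the largest k reachable from size 1 through steps that
#' each gain at least `delta_r2_stop` in R^2 without a decrease in Q^2.
#'
#' @param table a [descriptor_table()] with activity.
#' @param config an [hm_config()].
#' @return Object of class `hm_qsar`: the pre-filter trace, `best_by_size`
#'   (per size: descriptor set, `r_squared`, `q_squared`), `chosen_size`,
#'   and `model`, the chosen [fit_ols()] fit.
#' @examples
#' bench <- make_benchmark(synthetic_spec(seed = 3))
#' fit <- hm_fit(bench$train, hm_config(min_abs_t = 0, min_one_param_F = 0))
#' fit
#' @export
hm_fit <- function(table, config = hm_config()) {
  stopifnot(inherits(table, "descriptor_table"), inherits(config, "hm_config"))
  pre <- hm_prefilter(table, config)
  surv <- pre$survivors
  if (!length(surv)) stop_data("hm_fit: no admissible descriptors survive the pre-filter")
  X <- table$values[, surv, drop = FALSE]
  y <- table$activity
  n <- nrow(X)
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) stop_numerical("hm_fit: zero-variance activity")
  Cabs <- abs(cor(X))
  diag(Cabs) <- 0
  kmax <- min(config$max_subset_size, length(surv), n - 3L)

  canon <- function(cols) paste(cols, collapse = ",")
  best_by_size <- list()

  if (config$search == "exhaustive") {
    for (k in seq_len(kmax)) {
      sets <- lapply(combn(surv, k, simplify = FALSE), sort)
      sets <- Filter(function(s) all(Cabs[s, s][upper.tri(diag(k))] <
                                       config$collinearity_cap), sets)
      if (!length(sets)) break
      r2s <- vapply(sets, function(s) subset_r2(X, y, s, sst), 0)
      o <- order(-r2s, vapply(sets, canon, ""))
      best_by_size[[k]] <- list(descriptors = sets[[o[1L]]],
                                r_squared = unname(r2s[o[1L]]))
    }
  } else {
    ## beam search seeded on one-parameter R^2
    r2_1 <- vapply(surv, function(s) subset_r2(X, y, s, sst), 0)
    o <- order(-r2_1, surv)
    beam <- lapply(surv[o[seq_len(min(config$beam_width, length(surv)))]], c)
    best_by_size[[1L]] <- list(descriptors = surv[o[1L]],
                               r_squared = unname(r2_1[o[1L]]))
    k <- 1L
    while (k < kmax) {
      seen <- character(0)
      cand <- list()
      for (b in beam) {
        for (s in setdiff(surv, b)) {
          if (any(Cabs[b, s] >= config$collinearity_cap)) next
          cols <- sort(c(b, s))
          key <- canon(cols)
          if (key %in% seen) next
          seen <- c(seen, key)
          cand[[length(cand) + 1L]] <- cols
        }
      }
      if (!length(cand)) break
      k <- k + 1L
      r2s <- vapply(cand, function(s) subset_r2(X, y, s, sst), 0)
      o <- order(-r2s, vapply(cand, canon, ""))
      keep <- o[seq_len(min(config$beam_width, length(cand)))]
      beam <- cand[keep]
      best_by_size[[k]] <- list(descriptors = cand[[o[1L]]],
                                r_squared = unname(r2s[o[1L]]))
    }
  }

  ## Q^2 per best model, then the increment/no-Q^2-decrease stopping standard
  for (k in seq_along(best_by_size)) {
    best_by_size[[k]]$q_squared <-
      loo_q2(X[, best_by_size[[k]]$descriptors, drop = FALSE], y)
  }
  chosen <- 1L
  while (chosen < length(best_by_size)) {
    nxt <- best_by_size[[chosen + 1L]]
    cur <- best_by_size[[chosen]]
    if (nxt$r_squared - cur$r_squared >= config$delta_r2_stop &&
        nxt$q_squared >= cur$q_squared) chosen <- chosen + 1L else break
  }
  chosen_desc <- best_by_size[[chosen]]$descriptors
  model <- fit_ols(X, y, descriptors = chosen_desc)
  structure(list(prefilter = pre,
                 best_by_size = best_by_size,
                 chosen_size = chosen,
                 descriptors = chosen_desc,
                 model = model,
                 config = config),
            class = "hm_qsar")
}

#' @export
print.hm_qsar <- function(x, ...) {
  cat("Heuristic descriptor selection (HM)\n")
  print(x$prefilter)
  cat("  best model per size (R2 / Q2):\n")
  for (k in seq_along(x$best_by_size)) {
    b <- x$best_by_size[[k]]
    cat(sprintf("   %s k=%d  R2=%.4f  Q2=%.4f  {%s}\n",
                if (k == x$chosen_size) "*" else " ", k,
                b$r_squared, b$q_squared, paste(b$descriptors, collapse = ", ")))
  }
  cat("  chosen model:\n")
  print(x$model)
  invisible(x)
}

#' @export
summary.hm_qsar <- function(object, ...) {
  list(chosen_size = object$chosen_size,
       descriptors = object$descriptors,
       stats = model_stats(object$model),
       excluded = object$prefilter$excluded)
}

#' @export
coef.hm_qsar <- function(object, ...) coef(object$model)

#' @export
predict.hm_qsar <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' @export
plot.hm_qsar <- function(x, newdata = NULL, ...) {
  obs <- x$model$y; pred <- x$model$fitted_values
  graphics::plot(obs, pred, xlab = "experimental log(IC50)",
                 ylab = "predicted log(IC50)",
                 main = "HM linear model", ...)
  if (!is.null(newdata) && !is.null(newdata$activity)) {
    graphics::points(newdata$activity, predict(x, newdata), pch = 17, col = 2)
  }
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Serialize a selection trace to JSON
#'
#' Writes the rule-by-rule exclusion log, the per-size best models and the
#' chosen model of an [hm_fit()] result.
#'
#' @param fit an `hm_qsar` object.
#' @param path output path.
#' @param provenance optional named list embedded verbatim.
#' @return `path`, invisibly.
#' @export
write_hm_trace <- function(fit, path, provenance = NULL) {
  stopifnot(inherits(fit, "hm_qsar"))
  out <- list(type = "hm_selection",
              excluded = as.list(fit$prefilter$excluded),
              best_by_size = lapply(fit$best_by_size, function(b) {
                list(descriptors = b$descriptors, r_squared = b$r_squared,
                     q_squared = b$q_squared)
              }),
              chosen_size = fit$chosen_size,
              chosen_descriptors = fit$descriptors,
              coefficients = as.list(fit$model$coefficients),
              stats = unclass(model_stats(fit$model)),
              provenance = provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
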