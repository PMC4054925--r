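## Ordinary least squares with the statistics vocabulary customary in
## CODESSA-style QSAR reporting: R^2, leave-one-out Rcv^2 (Q^2), Fisher F,
## standard error s, RMS, and per-coefficient errors with Student t tests.

#' Fit an ordinary least squares QSAR model
#'
#' Fits `y ~ descriptors` with an intercept, on raw (uncentred, unscaled)
#' descriptor values as is conventional for CODESSA-style heuristic MLR.
#' Returns the coefficient vector together with classical standard errors
#' and Student t statistics (`t = coefficient / error`).
#'
#' @param x numeric descriptor matrix (one column per descriptor) or a
#'   [descriptor_table()] carrying activity.
#' @param y activity vector; taken from `x$activity` when `x` is a
#'   descriptor table.
#' @param descriptors optional character vector selecting columns of `x`.
#' @return Object of class `qsar_lm` with elements `descriptor_names`,
#'   `coefficients`, `standard_errors`, `t_values`, `fitted_values`,
#'   `residuals`, `n`, `k`, `df_residual`, and the training `X`, `y`.
#' @examples
#' X <- cbind(a = 1:10, b = (1:10)^2)
#' fit <- fit_ols(X, 1 + 2 * X[, "a"] + rnorm(10, 0, .1))
#' coef(fit)
#' @export
fit_ols <- function(x, y = NULL, descriptors = NULL) {
  if (inherits(x, "descriptor_table")) {
    if (is.null(y)) y <- x$activity
    x <- x$values
  }
  if (is.null(y)) stop_data("fit_ols: no activity values supplied")
  X <- as.matrix(x)
  if (!is.null(descriptors)) {
    absent <- setdiff(descriptors, colnames(X))
    if (length(absent)) {
      stop_data("fit_ols: descriptor column(s) not found: ",
                paste(absent, collapse = ", "))
    }
    X <- X[, descriptors, drop = FALSE]
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop_data("fit_ols: length(y) != nrow(X)")
  if (anyNA(X) || anyNA(y)) {
    stop_data("fit_ols: missing values in the design or response; the ",
              "heuristic pre-filter (rule 1) removes incomplete descriptors")
  }
  if (n <= k + 1L) {
    stop_numerical("fit_ols: need n > k + 1 (n = ", n, ", k = ", k,
                   ") for residual degrees of freedom")
  }
  Xd <- cbind("(Intercept)" = 1, X)
  qx <- qr(Xd)
  if (qx$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qx$pivot[seq.int(qx$rank + 1L, ncol(Xd))]]
    stop_numerical("fit_ols: singular design; offending column(s): ",
                   paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qx, y)
  fitted <- drop(Xd %*% coefs)
  res <- y - fitted
  df_res <- n - k - 1L
  sigma2 <- sum(res^2) / df_res
  ## (X'X)^{-1} from the (pivoted) R factor
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)
  piv <- qx$pivot
  xtx_inv[piv, piv] <- xtx_inv
  se <- sqrt(sigma2 * diag(xtx_inv))
  names(se) <- colnames(Xd)
  structure(list(descriptor_names = colnames(X),
                 coefficients = coefs,
                 standard_errors = se,
                 t_values = coefs / se,
                 fitted_values = fitted,
                 residuals = res,
                 n = n, k = k, df_residual = df_res,
                 sigma = sqrt(sigma2),
                 X = X, y = y),
            class = "qsar_lm")
}

#' @export
print.qsar_lm <- function(x, digits = 5, ...) {
  cat(sprintf("qsar_lm: %d compounds, %d descriptor(s)\n", x$n, x$k))
  print(round(cbind(coefficient = x$coefficients,
                    error = x$standard_errors,
                    t = x$t_values), digits))
  invisible(x)
}

#' @export
coef.qsar_lm <- function(object, ...) object$coefficients

#' @export
residuals.qsar_lm <- function(object, ...) object$residuals

#' @export
fitted.qsar_lm <- function(object, ...) object$fitted_values

#' @export
summary.qsar_lm <- function(object, ...) {
  stats <- model_stats(object)
  structure(list(model = object, stats = stats), class = "summary.qsar_lm")
}

#' @export
print.summary.qsar_lm <- function(x, ...) {
  print(x$model)
  print(x$stats)
  invisible(x)
}

#' Quality statistics of a fitted linear QSAR model
#'
#' Computes the statistics used to judge CODESSA-style regressions:
#' \itemize{
#' \item `r_squared`: \eqn{R^2 = 1 - SSE/SST};
#' \item `q_squared_loo`: leave-one-out cross-validated \eqn{R_{CV}^2}
#'   (see [loo_q2()]);
#' \item `f_statistic`: \eqn{F = (SSR/k) / (SSE/(n-k-1))};
#' \item `std_error_s`: \eqn{s = \sqrt{SSE/(n-k-1)}};
#' \item `rms`: \eqn{\sqrt{SSE/n}}, so that `rms^2 * n` equals the residual
#'   sum of squares.
#' }
#'
#' @param model a [fit_ols()] fit.
#' @param X,y data on which to evaluate; default the training data stored in
#'   the model.
#' @return Object of class `qsar_model_stats` (a list with the fields above
#'   plus `n` and `k`).
#' @export
model_stats <- function(model, X = model$X, y = model$y) {
  stopifnot(inherits(model, "qsar_lm"))
  X <- as.matrix(X)[, model$descriptor_names, drop = FALSE]
  y <- as.numeric(y)
  n <- length(y); k <- model$k
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) stop_numerical("model_stats: zero-variance activity, R^2 undefined")
  pred <- drop(model$coefficients[1L] + X %*% model$coefficients[-1L])
  sse <- sum((y - pred)^2)
  ssr <- sst - sse
  df_res <- n - k - 1L
  structure(list(r_squared = 1 - sse / sst,
                 q_squared_loo = loo_q2(X, y),
                 f_statistic = (ssr / k) / (sse / df_res),
                 std_error_s = sqrt(sse / df_res),
                 rms = sqrt(sse / n),
                 n = n, k = k),
            class = "qsar_model_stats")
}

#' @export
print.qsar_model_stats <- function(x, digits = 4, ...) {
  cat(sprintf("  n = %d, k = %d\n", x$n, x$k))
  cat(sprintf("  R2 = %.*f, Rcv2 = %.*f, F = %.*f, s = %.*f, RMS = %.*f\n",
              digits, x$r_squared, digits, x$q_squared_loo,
              digits, x$f_statistic, digits, x$std_error_s, digits, x$rms))
  invisible(x)
}

#' Leave-one-out cross-validated Q-squared
#'
#' \eqn{Q^2 = 1 - PRESS/SST}, where PRESS sums squared leave-one-out
#' prediction errors.  Computed with the hat-matrix identity
#' \eqn{e_{(i)} = e_i / (1 - h_{ii})}, which is algebraically identical to
#' refitting the model n times.
#'
#' @param X descriptor matrix.
#' @param y activity vector.
#' @return The LOO \eqn{Q^2} (at most the training \eqn{R^2}).
#' @export
loo_q2 <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); k <- ncol(X)
  if (n - 1L <= k + 1L) {
    stop_numerical("loo_q2: need n - 1 > k + 1 for leave-one-out refits")
  }
  Xd <- cbind(1, X)
  qx <- qr(Xd)
  if (qx$rank < ncol(Xd)) stop_numerical("loo_q2: singular design")
  e <- qr.resid(qx, y)
  h <- rowSums(qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]^2)
  if (any(h > 1 - 1e-10)) {
    stop_numerical("loo_q2: a leave-one-out subset is rank deficient ",
                   "(leverage 1)")
  }
  press <- sum((e / (1 - h))^2)
  sst <- sum((y - mean(y))^2)
  1 - press / sst
}

#' Predict activity for new compounds
#'
#' @param object a [fit_ols()] model.
#' @param newdata a [descriptor_table()], data frame or matrix providing
#'   every model descriptor; a missing column, or a missing value in a
#'   required descriptor, is an error (never silently `NaN`).
#' @param ... unused.
#' @return Named numeric vector of predicted activities.
#' @export
predict.qsar_lm <- function(object, newdata, ...) {
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
  if (anyNA(m)) {
    bad <- colnames(m)[colSums(is.na(m)) > 0L]
    stop_data("predict: missing values in required descriptor(s): ",
              paste(bad, collapse = ", "))
  }
  drop(object$coefficients[1L] + m %*% object$coefficients[-1L])
}

#' External prediction statistics
#'
#' For a fixed model applied to a test set the literature reports an
#' "R-squared" under two different conventions, both returned here under
#' distinct names: `r_squared_cor`, the squared Pearson correlation between
#' predicted and observed, and `r_squared_identity`,
#' \eqn{1 - SSE/SST} about the observed mean (which can be negative for a
#' poor model).
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return List with `r_squared_cor`, `r_squared_identity`, `rms`, `n`.
#' @export
prediction_stats <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ok <- is.finite(observed) & is.finite(predicted)
  n <- sum(ok)
  o <- observed[ok]; p <- predicted[ok]
  sse <- sum((o - p)^2)
  sst <- sum((o - mean(o))^2)
  list(r_squared_cor = if (n > 2) cor(o, p)^2 else NA_real_,
       r_squared_identity = 1 - sse / sst,
       rms = sqrt(sse / n),
       n = n,
       n_nonfinite = length(observed) - n)
}

#' Serialize a linear model to JSON
#'
#' @param model a [fit_ols()] fit.
#' @param path output path.
#' @param provenance optional named list (seed, config hash, ...) embedded
#'   verbatim.
#' @return `path`, invisibly.
#' @export
write_qsar_lm <- function(model, path, provenance = NULL) {
  stopifnot(inherits(model, "qsar_lm"))
  stats <- model_stats(model)
  out <- list(type = "qsar_lm",
              descriptor_names = model$descriptor_names,
              coefficients = as.list(model$coefficients),
              standard_errors = as.list(model$standard_errors),
              t_values = as.list(model$t_values),
              stats = unclass(stats),
              provenance = provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialized linear model
#'
#' Restores the prediction-relevant part of a model written by
#' [write_qsar_lm()] (coefficients and descriptor names; training data are
#' not serialized).
#'
#' @param path path to the JSON file.
#' @return A list of class `qsar_lm_loaded` usable with `predict()`.
#' @export
read_qsar_lm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "qsar_lm")) stop_data(path, ": not a qsar_lm file")
  structure(list(descriptor_names = obj$descriptor_names,
                 coefficients = unlist(obj$coefficients),
                 standard_errors = unlist(obj$standard_errors),
                 t_values = unlist(obj$t_values)),
            class = c("qsar_lm_loaded", "qsar_lm"))
}
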