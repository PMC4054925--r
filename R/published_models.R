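## Evaluators for the two final QSAR models reported in the source MMP
## (gelatinase) inhibition study of 33 pyrrolidine derivatives: a five-
## descriptor multiple linear regression and a GEP-evolved symbolic model.
## Both operate on the same five CODESSA descriptors.

#' Names of the five MMP-study descriptors
#'
#' LUMO (LUMO energy), MRECO (minimum resonance energy for a C-O bond),
#' KSIND (Kier shape index, order 3), ZX (ZX shadow / ZX rectangle ratio)
#' and MASEOAT (minimum atomic state energy for an O atom).
#'
#' @return Character vector of length 5, in the model's descriptor order.
#' @export
mmp_descriptor_names <- function() {
  c("LUMO", "MRECO", "KSIND", "ZX", "MASEOAT")
}

#' Coefficients of the published MMP linear QSAR model
#'
#' The study prints the model twice, and the two sources disagree in the
#' fifth decimal of the MASEOAT slope: the regression equation in the text
#' gives 0.84804 while the coefficient table gives 0.84808.  Both variants
#' are retained; `"equation"` is the default for prediction,
#' `"table"` is the pair consistent with the printed standard errors and
#' t-statistics.
#'
#' @param variant `"equation"` or `"table"`.
#' @return Named numeric vector: intercept followed by the five slopes, in
#'   log(IC50) units per descriptor unit.
#' @export
mmp_hm_coefficients <- function(variant = c("equation", "table")) {
  variant <- match.arg(variant)
  co <- c("(Intercept)" = -1.9501e2,
          LUMO    =  2.4570,
          MRECO   = -3.6715,
          KSIND   = -2.0681e-1,
          ZX      = -7.0757,
          MASEOAT =  8.4804e-1)
  if (variant == "table") co[["MASEOAT"]] <- 8.4808e-1
  co
}

#' Standard errors of the published MMP linear model coefficients
#'
#' @return Named numeric vector in the same order as
#'   [mmp_hm_coefficients()].
#' @export
mmp_hm_errors <- function() {
  c("(Intercept)" = 1.2612e2,
    LUMO    = 5.0431e-1,
    MRECO   = 6.7200e-1,
    KSIND   = 7.7119e-2,
    ZX      = 2.1621e0,
    MASEOAT = 4.3585e-1)
}

#' Student t statistics of the published linear model, recomputed
#'
#' Recomputes t = coefficient / standard error from the published
#' coefficient/error pairs (the `"table"` coefficient variant, which is the
#' one printed alongside the errors).  Nothing is hard-coded beyond those
#' pairs; the t column is always computed.
#'
#' @return A data frame with columns `term`, `coefficient`, `error`, `t`.
#' @examples
#' mmp_hm_ttests()
#' @export
mmp_hm_ttests <- function() {
  co <- mmp_hm_coefficients("table")
  se <- mmp_hm_errors()
  data.frame(term = names(co),
             coefficient = unname(co),
             error = unname(se),
             t = unname(co / se),
             row.names = NULL)
}

## coerce prediction input to a numeric matrix holding the five descriptors
mmp_descriptor_matrix <- function(newdata) {
  need <- mmp_descriptor_names()
  if (inherits(newdata, "descriptor_table")) newdata <- newdata$values
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1L, dimnames = list(NULL, names(newdata)))
  }
  newdata <- as.matrix(newdata)
  absent <- setdiff(need, colnames(newdata))
  if (length(absent)) {
    stop_data("missing descriptor column(s): ", paste(absent, collapse = ", "))
  }
  m <- newdata[, need, drop = FALSE]
  storage.mode(m) <- "double"
  if (anyNA(m)) stop_data("missing descriptor values in prediction input")
  m
}

#' Predict log(IC50) with the published linear MMP model
#'
#' @param newdata a [descriptor_table()], data frame, matrix, or named
#'   numeric vector providing the columns in [mmp_descriptor_names()].
#' @param variant coefficient variant, see [mmp_hm_coefficients()].
#' @return Numeric vector of predicted log(IC50), one per row.
#' @examples
#' v <- c(LUMO = 0, MRECO = 0, KSIND = 0, ZX = 0, MASEOAT = 0)
#' predict_mmp_hm(v)   # intercept only: -195.01
#' @export
predict_mmp_hm <- function(newdata, variant = c("equation", "table")) {
  co <- mmp_hm_coefficients(match.arg(variant))
  m <- mmp_descriptor_matrix(newdata)
  drop(co[1L] + m %*% co[-1L])
}

#' Predict log(IC50) with the published GEP MMP model
#'
#' Evaluates the symbolic model evolved by gene expression programming in
#' the source study: the sum of five gene terms over the descriptors
#' (LUMO, MRECO, KSIND, ZX, MASEOAT), with the single evolved numerical
#' constant -7.653931 taken as printed.  Arithmetic is IEEE "protected"
#' in the GEP sense: invalid operations (for example a negative square-root
#' argument) yield a non-finite value that propagates to the output and is
#' reported through the `"nonfinite"` attribute rather than masked.
#'
#' @inheritParams predict_mmp_hm
#' @return Numeric vector of predictions with a logical attribute
#'   `"nonfinite"` flagging rows whose value is not finite.
#' @export
predict_mmp_gep <- function(newdata) {
  m <- mmp_descriptor_matrix(newdata)
  lumo <- m[, "LUMO"]; mreco <- m[, "MRECO"]; ksind <- m[, "KSIND"]
  zx <- m[, "ZX"]; maseoat <- m[, "MASEOAT"]
  out <- suppressWarnings(
    sin(tan(tan(mreco) / sin(maseoat))) +
    sin(sin((tan(mreco) / lumo) - zx)) +
    lumo +
    maseoat ^ (maseoat ^ lumo / ksind) +
    sin(sqrt(ksind - tan(sin(tan(ksind * -7.653931)))))
  )
  structure(unname(out), nonfinite = !is.finite(out))
}

#' The individual gene terms of the published GEP model
#'
#' Mostly of diagnostic interest: the model links its five genes by
#' addition, so `rowSums` of this matrix equals [predict_mmp_gep()].
#'
#' @inheritParams predict_mmp_hm
#' @return Numeric matrix with one column per gene term.
#' @export
mmp_gep_terms <- function(newdata) {
  m <- mmp_descriptor_matrix(newdata)
  lumo <- m[, "LUMO"]; mreco <- m[, "MRECO"]; ksind <- m[, "KSIND"]
  zx <- m[, "ZX"]; maseoat <- m[, "MASEOAT"]
  suppressWarnings(cbind(
    term1 = sin(tan(tan(mreco) / sin(maseoat))),
    term2 = sin(sin((tan(mreco) / lumo) - zx)),
    term3 = lumo,
    term4 = maseoat ^ (maseoat ^ lumo / ksind),
    term5 = sin(sqrt(ksind - tan(sin(tan(ksind * -7.653931)))))
  ))
}

#' Correlation matrix of the five MMP-study descriptors
#'
#' The printed matrix is symmetric with unit diagonal but is not positive
#' semidefinite (its smallest eigenvalue is about -0.055), as often happens
#' with correlation tables rounded to four decimals.  With
#' `repair = TRUE` the matrix is projected to the nearest correlation
#' matrix with all eigenvalues at least `eig_floor` (eigenvalue clipping
#' followed by rescaling to unit diagonal); the Frobenius distance moved is
#' recorded in the `"frobenius_distance"` attribute.
#'
#' @param repair return the repaired positive-definite version?
#' @param eig_floor smallest admissible eigenvalue of the repaired matrix.
#' @return A 5 x 5 correlation matrix with dimnames
#'   [mmp_descriptor_names()].
#' @export
mmp_descriptor_correlation <- function(repair = FALSE, eig_floor = 0.05) {
  nm <- mmp_descriptor_names()
  C <- matrix(c(
     1.0000,  0.1497, -0.5319, -0.0117, 0.1171,
     0.1497,  1.0000, -0.4830,  0.3261, 0.3261,
    -0.5319, -0.4830,  1.0000,  0.1729, -0.5478,
    -0.0117,  0.3261,  0.1729,  1.0000, 0.6954,
     0.1171,  0.3261, -0.5478,  0.6954, 1.0000), 5L, 5L,
    dimnames = list(nm, nm))
  if (repair) C <- repair_correlation(C, eig_floor) else C
}
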