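#' Compound-by-descriptor tables
#'
#' A `descriptor_table` is the universal input of the QSAR pipeline: a numeric
#' matrix of molecular descriptors (rows = compounds, columns = named
#' descriptors) together with an optional activity vector, here the base-10
#' logarithm of IC50 (molar).  Missing descriptor values are allowed and are
#' preserved as `NA`; they are never imputed, only excluded later by the
#' heuristic pre-filter.
#'
#' @param values numeric matrix, `n_compounds x n_descriptors`.  `NA` entries
#'   mark missing measurements.
#' @param compound_ids character vector of unique compound identifiers.
#'   Defaults to `rownames(values)`.
#' @param descriptor_names character vector of unique descriptor names.
#'   Defaults to `colnames(values)`.
#' @param activity optional numeric vector of log(IC50) values, one per
#'   compound.  Omit for prediction-only tables.
#'
#' @return An object of class `descriptor_table`: a list with elements
#'   `values` (matrix with dimnames), and `activity` (numeric or `NULL`).
#' @examples
#' x <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("c", 1:3), paste0("d", 1:4)))
#' tab <- descriptor_table(x, activity = c(-5.1, -4.8, -6))
#' tab
#' @export
descriptor_table <- function(values, compound_ids = rownames(values),
                             descriptor_names = colnames(values),
                             activity = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
  }
  if (is.null(compound_ids)) {
    compound_ids <- if (nrow(values) > 0L) {
      paste0("compound_", seq_len(nrow(values)))
    } else {
      character(0)
    }
  }
  if (is.null(descriptor_names)) {
    stop_data("descriptor_table: descriptor names are required")
  }
  compound_ids <- as.character(compound_ids)
  descriptor_names <- as.character(descriptor_names)
  if (length(compound_ids) != nrow(values)) {
    stop_data("descriptor_table: ", length(compound_ids), " compound ids for ",
              nrow(values), " rows")
  }
  if (length(descriptor_names) != ncol(values)) {
    stop_data("descriptor_table: ", length(descriptor_names),
              " descriptor names for ", ncol(values), " columns")
  }
  if (anyDuplicated(compound_ids)) {
    stop_data("descriptor_table: duplicate compound ids: ",
              paste(unique(compound_ids[duplicated(compound_ids)]), collapse = ", "))
  }
  if (anyDuplicated(descriptor_names)) {
    stop_data("descriptor_table: duplicate descriptor names: ",
              paste(unique(descriptor_names[duplicated(descriptor_names)]), collapse = ", "))
  }
  if (!is.null(activity)) {
    activity <- as.numeric(activity)
    if (length(activity) != nrow(values)) {
      stop_data("descriptor_table: activity has length ", length(activity),
                ", expected ", nrow(values))
    }
  }
  dimnames(values) <- list(compound_ids, descriptor_names)
  structure(list(values = values, activity = activity),
            class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("descriptor_table: %d compounds x %d descriptors%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$activity)) " (no activity)" else ", with log(IC50)"))
  miss <- missing_descriptors(x)
  if (length(miss)) {
    cat("  descriptors with missing values:", paste(miss, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.descriptor_table <- function(x) dim(x$values)

#' @export
as.data.frame.descriptor_table <- function(x, ...) {
  df <- as.data.frame(x$values)
  if (!is.null(x$activity)) df$log_IC50 <- x$activity
  df
}

#' Row/column subsetting of a descriptor table
#'
#' @param x a [descriptor_table()].
#' @param i,j row (compound) and column (descriptor) indices.
#' @param ... unused.
#' @return A `descriptor_table` with the selected compounds and descriptors;
#'   the activity vector is subset along with the rows.
#' @export
`[.descriptor_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  descriptor_table(x$values[i, j, drop = FALSE],
                   activity = if (!is.null(x$activity)) x$activity[i])
}

#' Names of descriptors carrying missing values
#'
#' @param x a [descriptor_table()].
#' @return Character vector of descriptor names with at least one `NA` entry.
#' @export
missing_descriptors <- function(x) {
  stopifnot(inherits(x, "descriptor_table"))
  colnames(x$values)[colSums(is.na(x$values)) > 0L]
}

#' Read a descriptor table from CSV
#'
#' The expected dialect is comma-separated UTF-8 with a header row and "."
#' as the decimal mark.  The first column holds compound identifiers; every
#' other column is numeric.  Empty cells are recorded as missing values
#' (never imputed).  A column named `activity_column`, when present, becomes
#' the activity vector; its absence simply yields a prediction-only table.
#'
#' @param path path to a CSV file.
#' @param activity_column name of the activity column (default `"log_IC50"`).
#' @return A [descriptor_table()].
#' @seealso [write_descriptor_table()]
#' @export
read_descriptor_table <- function(path, activity_column = "log_IC50") {
  if (!file.exists(path)) stop_data("file not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L) stop_data(path, ": need an id column plus data columns")
  ids <- raw[[1L]]
  numeric_part <- raw[-1L]
  parsed <- matrix(NA_real_, nrow(raw), ncol(numeric_part),
                   dimnames = list(NULL, names(numeric_part)))
  for (col in names(numeric_part)) {
    cell <- trimws(numeric_part[[col]])
    blank <- is.na(cell) | cell == ""
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!blank & is.na(val))
    if (length(bad)) {
      stop_data(sprintf("%s: non-numeric value %s in row %d, column '%s'",
                        path, dQuote(cell[bad[1L]]), bad[1L], col))
    }
    parsed[, col] <- val
  }
  activity <- NULL
  if (activity_column %in% colnames(parsed)) {
    activity <- parsed[, activity_column]
    parsed <- parsed[, setdiff(colnames(parsed), activity_column), drop = FALSE]
  }
  descriptor_table(parsed, compound_ids = ids, activity = activity)
}

#' Write a descriptor table to CSV
#'
#' Values are written with 17 significant digits so that finite entries
#' round-trip bit-for-bit through [read_descriptor_table()].  Missing values
#' are written as empty cells.
#'
#' @param x a [descriptor_table()].
#' @param path output file path.
#' @param activity_column column name used for the activity vector.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(x, path, activity_column = "log_IC50") {
  stopifnot(inherits(x, "descriptor_table"))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  out <- cbind(compound = rownames(x$values),
               apply(x$values, 2L, fmt))
  if (!is.null(x$activity)) {
    out <- cbind(out, fmt(x$activity))
    colnames(out)[ncol(out)] <- activity_column
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE, col.names = TRUE,
                     qmethod = "double", quote = TRUE)
  invisible(path)
}

#' Split a descriptor table into training and test sets
#'
#' Either give the test-set compound ids explicitly, or a `test_fraction`
#' plus `seed` for a reproducible random partition.  The two returned tables
#' always partition the input compounds.
#'
#' @param x a [descriptor_table()].
#' @param test_ids character vector of compound ids forming the test set.
#'   An empty vector yields an empty test table.
#' @param test_fraction fraction of compounds assigned to the test set
#'   (used when `test_ids` is `NULL`).
#' @param seed integer seed for the random split.
#' @return A list with elements `train` and `test`, both `descriptor_table`s.
#' @examples
#' x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("d", 1:4)))
#' tab <- descriptor_table(x, activity = rnorm(10))
#' sp <- split_train_test(tab, test_fraction = 0.3, seed = 7)
#' dim(sp$train); dim(sp$test)
#' @export
split_train_test <- function(x, test_ids = NULL, test_fraction = NULL,
                             seed = NULL) {
  stopifnot(inherits(x, "descriptor_table"))
  ids <- rownames(x$values)
  if (is.null(test_ids)) {
    if (is.null(test_fraction) || is.null(seed)) {
      stop_config("split_train_test: give test_ids, or test_fraction with seed")
    }
    n_test <- round(test_fraction * length(ids))
    test_ids <- with_seed(derive_seed(seed, "split"),
                          sample(ids, n_test))
  }
  test_ids <- as.character(test_ids)
  unknown <- setdiff(test_ids, ids)
  if (length(unknown)) {
    stop_data("split_train_test: unknown test ids: ",
              paste(unknown, collapse = ", "))
  }
  if (length(test_ids) == length(ids)) {
    stop_data("split_train_test: test set equals the full set; training set empty")
  }
  is_test <- ids %in% test_ids
  list(train = x[!is_test, ], test = x[is_test, ])
}
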