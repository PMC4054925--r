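## Pipeline driver: wires the stages into reproducible runs controlled by a
## single configuration (an R list, or a YAML/JSON file).  Every run writes a
## config echo with the seed and a content hash next to its artifacts, so a
## rerun with the same configuration and seed reproduces them byte for byte
## (no timestamps are written).

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_config("config file not found: ", config)
    ext <- tolower(tools::file_ext(config))
    config <- switch(ext,
                     yml = ,
                     yaml = yaml::read_yaml(config),
                     json = jsonlite::read_json(config, simplifyVector = TRUE),
                     stop_config("unsupported config format: .", ext))
  }
  if (!is.list(config)) stop_config("config must be a list or a file path")
  config
}

## canonical JSON echo of the config; returns its md5 hash
write_config_echo <- function(config, out_dir) {
  path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  unname(tools::md5sum(path))
}

build_synthetic_spec <- function(config) {
  args <- config$synthetic %||% list()
  known <- names(formals(synthetic_spec))
  unknown <- setdiff(names(args), known)
  if (length(unknown)) {
    stop_config("unknown synthetic option(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(args$seed)) args$seed <- config$seed %||% 1L
  if (!is.null(args$decoys)) args$decoys <- unlist(args$decoys)
  do.call(synthetic_spec, args)
}

build_hm_config <- function(config) {
  args <- config$hm %||% list()
  unknown <- setdiff(names(args), names(formals(hm_config)))
  if (length(unknown)) {
    stop_config("unknown hm option(s): ", paste(unknown, collapse = ", "))
  }
  do.call(hm_config, args)
}

build_gep_config <- function(config) {
  args <- config$gep %||% list()
  unknown <- setdiff(names(args), names(formals(gep_config)))
  if (length(unknown)) {
    stop_config("unknown gep option(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(args$functions)) args$functions <- gep_function_set(args$functions)
  do.call(gep_config, args)
}

load_table_from_config <- function(config, which = "train") {
  path <- config$data[[which]]
  if (is.null(path)) stop_config("config$data$", which, " is required")
  read_descriptor_table(path,
                        activity_column = config$data$activity_column %||% "log_IC50")
}

#' Run one pipeline command
#'
#' A single entry point over the package's stages, suitable for scripted
#' use.  Commands:
#' \describe{
#' \item{`simulate`}{generate a synthetic benchmark; writes `train.csv`,
#'   `test.csv`, `truth.json`.}
#' \item{`select`}{heuristic descriptor selection on the training table;
#'   writes `selection.json` (rule-by-rule exclusion log, per-size models,
#'   chosen model).}
#' \item{`fit-linear`}{OLS on given descriptors (default: the HM choice);
#'   writes `linear_model.json`.}
#' \item{`fit-gep`}{GEP evolution; writes `gep_model.json` and
#'   `expression.txt`.}
#' \item{`predict`}{predictions from a serialized model (or a published MMP
#'   model); writes `predictions.csv`.}
#' \item{`report`}{train/test summary in the customary vocabulary (R2,
#'   Rcv2, F, s, RMS); writes `report.txt`.}
#' }
#'
#' Every artifact directory receives a `config.json` echo whose md5 hash and
#' the seed are embedded in the JSON artifacts (`provenance` field).  On
#' error, partially written artifacts of the failing command are removed.
#'
#' @param command one of `"simulate"`, `"select"`, `"fit-linear"`,
#'   `"fit-gep"`, `"predict"`, `"report"`.
#' @param config a named list, or path to a YAML/JSON config file.  Top
#'   level keys: `seed`, `synthetic`, `hm`, `gep`, `data` (`train`, `test`,
#'   `activity_column`), `model` (for predict/report), `descriptors`.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list of the artifact paths written.
#' @export
qsar_run <- function(command = c("simulate", "select", "fit-linear",
                                 "fit-gep", "predict", "report"),
                     config = list(), out_dir = ".") {
  command <- match.arg(command)
  config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  written <- character(0)
  on_fail <- function(e) { unlink(written); stop(e) }
  art <- function(...) {
    p <- file.path(out_dir, ...)
    written <<- c(written, p)
    p
  }
  tryCatch({
    hash <- write_config_echo(config, out_dir)
    prov <- list(seed = seed, config_hash = hash)
    out <- switch(command,
      "simulate" = {
        bench <- make_benchmark(build_synthetic_spec(config))
        write_descriptor_table(bench$train, art("train.csv"))
        write_descriptor_table(bench$test, art("test.csv"))
        truth <- bench$truth
        truth$coefficients <- as.list(truth$coefficients)
        truth$provenance <- prov
        jsonlite::write_json(truth, art("truth.json"), auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
        written
      },
      "select" = {
        fit <- hm_fit(load_table_from_config(config), build_hm_config(config))
        write_hm_trace(fit, art("selection.json"), provenance = prov)
        written
      },
      "fit-linear" = {
        train <- load_table_from_config(config)
        desc <- config$descriptors
        if (is.null(desc)) {
          desc <- hm_fit(train, build_hm_config(config))$descriptors
        }
        model <- fit_ols(train, descriptors = desc)
        write_qsar_lm(model, art("linear_model.json"), provenance = prov)
        written
      },
      "fit-gep" = {
        train <- load_table_from_config(config)
        fit <- gep_fit(train, build_gep_config(config), seed = seed,
                       descriptors = config$descriptors)
        write_gep_model(fit, art("gep_model.json"), provenance = prov)
        writeLines(fit$expression, art("expression.txt"))
        written
      },
      "predict" = {
        input <- load_table_from_config(config, "input")
        model_id <- config$model %||% "linear_model.json"
        pred <- switch(model_id,
          "published-linear" = predict_mmp_hm(input),
          "published-gep" = predict_mmp_gep(input),
          predict(read_model_file(model_id), input))
        utils::write.csv(
          data.frame(compound = rownames(input$values),
                     predicted_log_IC50 = sprintf("%.17g", pred)),
          art("predictions.csv"), row.names = FALSE, quote = TRUE)
        written
      },
      "report" = {
        train <- load_table_from_config(config)
        model_path <- config$model
        if (is.null(model_path)) stop_config("report needs config$model")
        model <- read_model_file(model_path)
        lines <- c("QSAR model report", "=================",
                   paste0("seed: ", seed, "  config: ", hash))
        st <- NULL
        if (inherits(model, "qsar_lm")) {
          refit <- fit_ols(train, descriptors = model$descriptor_names)
          st <- model_stats(refit)
          lines <- c(lines, "",
                     sprintf("training set (n = %d, k = %d):", st$n, st$k),
                     sprintf("  R2 = %.4f  Rcv2 = %.4f  F = %.2f  s = %.4f  RMS = %.4f",
                             st$r_squared, st$q_squared_loo, st$f_statistic,
                             st$std_error_s, st$rms))
        }
        if (!is.null(config$data$test)) {
          test <- load_table_from_config(config, "test")
          ps <- prediction_stats(test$activity, predict(model, test))
          lines <- c(lines, "",
                     sprintf("test set (n = %d):", ps$n),
                     sprintf("  R2 (squared correlation) = %.4f", ps$r_squared_cor),
                     sprintf("  R2 (about identity line) = %.4f", ps$r_squared_identity),
                     sprintf("  RMS = %.4f", ps$rms))
        }
        writeLines(lines, art("report.txt"))
        written
      })
    invisible(out)
  }, gq_error = on_fail)
}

## dispatch on serialized model type
read_model_file <- function(path) {
  if (!file.exists(path)) stop_config("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  switch(obj$type %||% "",
         qsar_lm = read_qsar_lm(path),
         gep_qsar = read_gep_model(path),
         stop_data(path, ": unrecognized model file"))
}
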