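# File I/O: chemprop-style CSV property tables (empty cell = missing), SDF
# V2000 with tag fields, YAML run configs, JSON metric reports.

#' Read a molecule/property table
#'
#' CSV: the column named `smiles` (case-insensitive, else the first column)
#' holds structures, an optional `id`/`name` column holds identifiers, and
#' every remaining numeric column becomes a task; empty cells are missing
#' values. SDF: structures from the connection table, tasks from numeric tag
#' fields. Row order is preserved.
#'
#' @param path File path.
#' @param format `"csv"` or `"sdf"` (default: from the file extension).
#' @return `mt_records` with every numeric column as a primary task (refine
#'   roles with [make_records()]); fully non-numeric columns are kept as
#'   annotation. A structures-only table is returned as a plain data frame.
#' @export
read_table <- function(path, format = c("auto", "csv", "sdf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") read_table_csv(path) else read_table_sdf(path)
}

read_table_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (nrow(df) == 0L) stop("empty table: ", path)
  nms <- tolower(names(df))
  smi_col <- which(nms == "smiles")[1L]
  if (is.na(smi_col)) smi_col <- 1L
  if (!is.character(df[[smi_col]]))
    stop("no parsable smiles column in ", path)
  id_col <- which(nms %in% c("id", "name"))[1L]
  out <- data.frame(smiles = df[[smi_col]], stringsAsFactors = FALSE)
  if (!is.na(id_col)) out$id <- as.character(df[[id_col]])
  task_cols <- setdiff(seq_along(df), c(smi_col, id_col))
  task_names <- character()
  for (j in task_cols) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (all(is.na(v)) && any(!is.na(df[[j]]))) {
      # entirely non-numeric: annotation column, not a task
      out[[names(df)[j]]] <- as.character(df[[j]])
      next
    }
    bad <- which(!is.na(df[[j]]) & is.na(v))
    if (length(bad))
      message(sprintf("read_table: column '%s': %d non-numeric cells at rows %s treated as missing",
                      names(df)[j], length(bad),
                      paste(utils::head(bad, 5L), collapse = ",")))
    out[[names(df)[j]]] <- v
    task_names <- c(task_names, names(df)[j])
  }
  bad_smiles <- which(is.na(out$smiles) | !nzchar(out$smiles))
  if (length(bad_smiles) == nrow(out))
    stop("no parsable smiles column in ", path)
  if (length(bad_smiles))
    message(sprintf("read_table: %d rows with empty smiles at lines %s",
                    length(bad_smiles),
                    paste(utils::head(bad_smiles + 1L, 5L), collapse = ",")))
  if (length(task_names) == 0L) return(out)  # structures-only table
  make_records(out, tasks = do.call(rbind, lapply(task_names, task_spec)))
}

read_table_sdf <- function(path) {
  sdfset <- ChemmineR::read.SDFset(path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  smi <- chemmine_convert("SDF", "SMI", paste0(txt, "\n"))
  smi_lines <- strsplit(smi, "\n", fixed = TRUE)[[1L]]
  smi_lines <- smi_lines[nzchar(smi_lines)]
  smiles <- vapply(strsplit(smi_lines, "\t|[[:space:]]+"), `[`, character(1),
                   1L)
  n <- length(sdfset)
  if (length(smiles) != n)
    stop("could not convert every SDF record to SMILES in ", path)
  blocks <- ChemmineR::datablock(sdfset)
  tags <- unique(unlist(lapply(blocks, names)))
  out <- data.frame(smiles = smiles,
                    id = ChemmineR::sdfid(sdfset),
                    stringsAsFactors = FALSE)
  for (tg in tags) {
    v <- vapply(blocks, function(b)
      if (tg %in% names(b)) b[[tg]] else NA_character_, character(1))
    num <- suppressWarnings(as.numeric(v))
    if (all(is.na(num) | !is.na(num))) {
      if (any(!is.na(num))) out[[tg]] <- num
    }
  }
  if (ncol(out) <= 2L) {
    message("read_table: SDF has no numeric tag fields; returning structures only")
    return(out)
  }
  make_records(out)
}

#' Write a record table as chemprop-style CSV
#'
#' Missing values become empty cells; values round-trip through
#' [read_table()] at full double precision.
#'
#' @param records `mt_records` or data frame.
#' @param path Output path.
#' @export
write_table <- function(records, path) {
  df <- as.data.frame(records)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run configuration
#'
#' Collects every knob of a training run: architecture, split settings,
#' task roles, ensemble size, seeds and bootstrap size. Round-trips through
#' YAML losslessly; unknown keys are rejected.
#'
#' @param depth,hidden_size,ffn_num_layers,dropout See [model_params()].
#' @param aggregation Atom aggregation, `"mean"` or `"sum"`.
#' @param split_type `"random"` or `"scaffold_balanced"`.
#' @param split_sizes Train/validation/test fractions.
#' @param test_threshold,train_threshold Curation similarity thresholds.
#' @param ensemble_size Number of ensemble members.
#' @param seed Base seed.
#' @param epochs,batch_size Training loop settings.
#' @param n_boot Bootstrap resamples for evaluation.
#' @return Object of class `mt_config` (named list).
#' @export
run_config <- function(depth = 3L, hidden_size = 300L, ffn_num_layers = 2L,
                       dropout = 0, aggregation = "mean",
                       split_type = "random",
                       split_sizes = c(0.9, 0.1, 0),
                       test_threshold = 0.25, train_threshold = 0.4,
                       ensemble_size = 1L, seed = 0L, epochs = 30L,
                       batch_size = 50L, n_boot = 1000L) {
  cfg <- list(depth = as.integer(depth), hidden_size = as.integer(hidden_size),
              ffn_num_layers = as.integer(ffn_num_layers),
              dropout = as.numeric(dropout), aggregation = aggregation,
              split_type = split_type, split_sizes = as.numeric(split_sizes),
              test_threshold = as.numeric(test_threshold),
              train_threshold = as.numeric(train_threshold),
              ensemble_size = as.integer(ensemble_size),
              seed = as.integer(seed), epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              n_boot = as.integer(n_boot))
  stopifnot(cfg$depth >= 1L, cfg$hidden_size >= 1L, cfg$dropout >= 0,
            cfg$dropout < 1, length(cfg$split_sizes) == 3L,
            abs(sum(cfg$split_sizes) - 1) < 1e-8,
            cfg$split_type %in% c("random", "scaffold_balanced"),
            cfg$aggregation %in% c("mean", "sum"), cfg$ensemble_size >= 1L)
  class(cfg) <- "mt_config"
  cfg
}

#' Read a YAML run configuration
#' @param path YAML file.
#' @return `mt_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' Write a run configuration to YAML
#' @param config `mt_config`.
#' @param path Output file.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "mt_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a metric report as JSON
#'
#' @param report `mt_metric_report`.
#' @param path Output file.
#' @export
write_metrics_json <- function(report, path) {
  out <- list()
  for (i in seq_len(nrow(report))) {
    out[[report$metric[i]]] <- list(estimate = report$estimate[i],
                                    lower = report$lower[i],
                                    upper = report$upper[i])
  }
  out$n <- attr(report, "n")
  out$n_boot <- attr(report, "n_boot")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
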