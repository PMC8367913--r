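# Task bookkeeping: records are a data frame (smiles, optional id, one
# numeric column per task) carrying a "tasks" attribute that names each task
# and assigns its role -- "primary" endpoints are reported at predict time,
# "helper" tasks enter the training loss only.

#' Define a task
#'
#' @param name Task (column) name.
#' @param role `"primary"` (reported at predict time) or `"helper"` (used
#'   only in the training loss).
#' @param source Free-text provenance label (e.g. `"opera"`, `"chembl"`,
#'   `"external_predictor"`).
#' @return One-row data frame.
#' @export
task_spec <- function(name, role = c("primary", "helper"), source = "") {
  role <- match.arg(role)
  data.frame(name = name, role = role, source = source,
             stringsAsFactors = FALSE)
}

#' Attach task definitions to a molecule table
#'
#' @param df Data frame with a `smiles` column, an optional `id` column and
#'   one numeric column per task (`NA` = unobserved).
#' @param tasks Data frame of task specs (rows from [task_spec()]); defaults
#'   to all non-structure columns as primary tasks.
#' @return The data frame with class `mt_records` and a `tasks` attribute.
#' @export
make_records <- function(df, tasks = NULL) {
  stopifnot(is.data.frame(df), "smiles" %in% names(df))
  task_cols <- setdiff(names(df), c("smiles", "id"))
  if (is.null(tasks)) {
    tasks <- do.call(rbind, lapply(task_cols, task_spec))
  }
  stopifnot(all(tasks$name %in% names(df)), !anyDuplicated(tasks$name))
  if (!any(tasks$role == "primary"))
    stop("at least one primary task is required")
  for (nm in tasks$name) df[[nm]] <- as.numeric(df[[nm]])
  attr(df, "tasks") <- tasks
  class(df) <- c("mt_records", "data.frame")
  df
}

#' Task definitions of a record table
#' @param records `mt_records`.
#' @return Data frame with columns `name`, `role`, `source`.
#' @export
record_tasks <- function(records) {
  t <- attr(records, "tasks")
  if (is.null(t)) stop("records carry no task definitions; see make_records()")
  t
}

#' Target matrix and observation mask of a record table
#'
#' @param records `mt_records`.
#' @return List with `values` (molecules x tasks, `NA` where unobserved) and
#'   `mask` (logical, `TRUE` where a measurement exists).
#' @export
target_matrix <- function(records) {
  tasks <- record_tasks(records)
  values <- as.matrix(as.data.frame(records)[, tasks$name, drop = FALSE])
  storage.mode(values) <- "double"
  mask <- is.finite(values)
  list(values = values, mask = mask)
}

#' Merge several single-property datasets into one multitask table
#'
#' In `"separate"` mode each dataset becomes its own task column (treating
#' e.g. logP_opera and logP_chembl as distinct tasks); in `"merged"` mode all
#' values are pooled into a single column. Molecules occurring in several
#' datasets (matched by canonical SMILES) become single rows with several
#' observed entries; duplicate measurements within one dataset are aggregated
#' by their median (logged).
#'
#' @param datasets Named list of data frames, each with a `smiles` column and
#'   one numeric value column.
#' @param mode `"separate"` or `"merged"`.
#' @param merged_name Task name used in merged mode.
#' @return `mt_records` with one row per distinct molecule.
#' @export
assemble_tasks <- function(datasets, mode = c("separate", "merged"),
                           merged_name = "merged") {
  mode <- match.arg(mode)
  stopifnot(is.list(datasets), length(datasets) >= 1L,
            !is.null(names(datasets)), all(nzchar(names(datasets))))
  cleaned <- lapply(names(datasets), function(nm) {
    d <- datasets[[nm]]
    stopifnot(is.data.frame(d), nrow(d) >= 1L, "smiles" %in% names(d))
    val_col <- setdiff(names(d), c("smiles", "id"))[1L]
    can <- canonical_smiles(d$smiles)
    ok <- !is.na(can)
    if (any(!ok))
      message(sprintf("assemble_tasks: dropped %d unparsable molecules from '%s'",
                      sum(!ok), nm))
    d <- data.frame(smiles = can[ok], value = as.numeric(d[[val_col]][ok]),
                    stringsAsFactors = FALSE)
    if (anyDuplicated(d$smiles)) {
      ndup <- nrow(d) - length(unique(d$smiles))
      message(sprintf("assemble_tasks: aggregated %d duplicate measurements in '%s' by median",
                      ndup, nm))
      agg <- stats::aggregate(value ~ smiles, data = d, FUN = stats::median)
      d <- agg
    }
    d
  })
  names(cleaned) <- names(datasets)
  all_smiles <- unique(unlist(lapply(cleaned, `[[`, "smiles")))
  if (mode == "merged") {
    pooled <- do.call(rbind, cleaned)
    agg <- stats::aggregate(value ~ smiles, data = pooled, FUN = stats::median)
    df <- data.frame(smiles = all_smiles, stringsAsFactors = FALSE)
    df[[merged_name]] <- agg$value[match(all_smiles, agg$smiles)]
    tasks <- task_spec(merged_name, "primary",
                       paste(names(datasets), collapse = "+"))
  } else {
    df <- data.frame(smiles = all_smiles, stringsAsFactors = FALSE)
    for (nm in names(cleaned)) {
      df[[nm]] <- cleaned[[nm]]$value[match(all_smiles, cleaned[[nm]]$smiles)]
    }
    tasks <- do.call(rbind, lapply(names(cleaned), function(nm)
      task_spec(nm, "primary", nm)))
  }
  make_records(df, tasks)
}

#' Canonical SMILES via OpenBabel
#'
#' @param smiles Character vector.
#' @return Character vector of canonical SMILES (`NA` where unparsable).
#' @export
canonical_smiles <- function(smiles) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  ok <- nzchar(trimws(smiles)) & !is.na(smiles)
  idx <- which(ok)
  if (!length(idx)) return(out)
  src <- paste0(paste(trimws(smiles[idx]), paste0("MTLOGP_", idx),
                      collapse = "\n"), "\n")
  can <- chemmine_convert("SMI", "CAN", src)
  for (ln in strsplit(can, "\n", fixed = TRUE)[[1L]]) {
    if (!nzchar(ln)) next
    f <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (length(f) < 2L) next
    i <- suppressWarnings(as.integer(sub("^MTLOGP_", "", f[2L])))
    if (!is.na(i)) out[i] <- f[1L]
  }
  out
}

#' Add helper-task columns computed by an external provider
#'
#' The provider stands in for any auxiliary predictor (another model's logP /
#' logD output, a slower physics-based calculator, ...). Its values join the
#' training loss as `"helper"` tasks and are never part of the prediction
#' output. Provider failures leave the affected entries masked.
#'
#' @param records `mt_records`.
#' @param provider Function taking the SMILES vector and returning a data
#'   frame of named numeric columns (one per helper task), or `NULL` for the
#'   identity (singletask path).
#' @param source Provenance label stored in the task specs.
#' @return `mt_records` with the helper columns appended.
#' @export
attach_helper_tasks <- function(records, provider,
                                source = "external_predictor") {
  if (is.null(provider)) return(records)
  tasks <- record_tasks(records)
  vals <- tryCatch(provider(records$smiles), error = function(e) {
    message("helper provider failed for the whole batch: ",
            conditionMessage(e))
    NULL
  })
  if (is.null(vals)) return(records)
  stopifnot(is.data.frame(vals), nrow(vals) == nrow(records))
  df <- as.data.frame(records)
  for (nm in names(vals)) {
    v <- suppressWarnings(as.numeric(vals[[nm]]))
    if (any(!is.finite(v) & !is.na(v))) v[!is.finite(v)] <- NA_real_
    n_bad <- sum(is.na(v))
    if (n_bad > 0L)
      message(sprintf("helper task '%s': %d molecules masked (provider failure)",
                      nm, n_bad))
    df[[nm]] <- v
    tasks <- rbind(tasks, task_spec(nm, "helper", source))
  }
  make_records(df, tasks)
}

#' Masked multitask mean-squared-error loss
#'
#' Mean of squared errors over observed entries only; unobserved entries
#' contribute neither to the loss nor to any gradient.
#'
#' @param pred Prediction matrix (molecules x tasks).
#' @param targets List with `values` and `mask` (see [target_matrix()]), or
#'   an `mt_records` object.
#' @return Scalar loss.
#' @export
masked_loss <- function(pred, targets) {
  if (inherits(targets, "mt_records")) targets <- target_matrix(targets)
  stopifnot(is.matrix(pred), all(dim(pred) == dim(targets$values)))
  m <- targets$mask
  n_obs <- sum(m)
  if (n_obs == 0L) stop("masked_loss: no observed entries")
  err <- (pred - targets$values)[m]
  sum(err^2) / n_obs
}
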