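# Ensembles: N independently seeded models trained on identical data; the
# reported prediction is the member mean and its uncertainty the standard
# error of the mean (SEM) across members.

#' Train an ensemble of independently seeded models
#'
#' Member `i` is trained with seed `base_seed + i - 1` on identical data; no
#' weights are shared. A 10-member ensemble of the multitask model is the
#' configuration that performed best in the lipophilicity application this
#' package implements.
#'
#' @param records `mt_records` training table.
#' @param params `mt_params`.
#' @param n_members Number of members (>= 1).
#' @param base_seed Integer seed of the first member.
#' @param ... Further arguments passed to [train_dmpnn()] (epochs,
#'   batch_size, split, ...).
#' @return Object of class `mt_ensemble` with `members` and `seeds`.
#' @export
train_ensemble <- function(records, params, n_members = 10L, base_seed,
                           ...) {
  stopifnot(n_members >= 1L)
  seeds <- as.integer(base_seed) + seq_len(n_members) - 1L
  members <- vector("list", n_members)
  for (i in seq_len(n_members)) {
    members[[i]] <- tryCatch(
      train_dmpnn(records, params, seed = seeds[i], ...),
      error = function(e) stop(sprintf("ensemble member %d failed: %s", i,
                                       conditionMessage(e)), call. = FALSE))
  }
  ens <- list(members = members, seeds = seeds)
  class(ens) <- "mt_ensemble"
  ens
}

#' @export
print.mt_ensemble <- function(x, ...) {
  cat(sprintf("<mt_ensemble> %d members, seeds %s\n", length(x$members),
              paste(x$seeds, collapse = ",")))
  invisible(x)
}

#' Ensemble prediction with per-compound SEM
#'
#' The point prediction for each molecule and primary task is the mean over
#' members; the uncertainty is the standard error of the mean, i.e. the
#' sample standard deviation (n-1 denominator) of the member predictions
#' divided by `sqrt(n_members)`. A singleton ensemble reports SEM 0.
#'
#' @param ensemble `mt_ensemble` (or a single `mt_model`, treated as a
#'   singleton).
#' @param newdata SMILES vector or records table.
#' @param descriptors Optional descriptor matrix.
#' @return Object of class `mt_ensemble_pred`: list with `mean` and `sem`
#'   matrices (molecules x primary tasks), the full `member_values` array
#'   (molecules x tasks x members), `tasks`, and the input `smiles`.
#' @export
predict_with_sem <- function(ensemble, newdata, descriptors = NULL) {
  if (inherits(ensemble, "mt_model"))
    ensemble <- structure(list(members = list(ensemble),
                               seeds = ensemble$seed), class = "mt_ensemble")
  stopifnot(inherits(ensemble, "mt_ensemble"), length(ensemble$members) >= 1L)
  smiles <- if (is.data.frame(newdata)) newdata$smiles else newdata
  tasks <- ensemble$members[[1L]]$tasks
  primary <- tasks$name[tasks$role == "primary"]
  n_mem <- length(ensemble$members)
  preds <- lapply(ensemble$members, function(m)
    predict_primary(m, newdata, descriptors))
  arr <- array(unlist(preds), dim = c(length(smiles), length(primary), n_mem),
               dimnames = list(NULL, primary, NULL))
  mean_ <- apply(arr, c(1L, 2L), mean)
  sem_ <- if (n_mem == 1L) {
    matrix(0, length(smiles), length(primary), dimnames = list(NULL, primary))
  } else {
    apply(arr, c(1L, 2L), stats::sd) / sqrt(n_mem)
  }
  out <- list(mean = mean_, sem = sem_, member_values = arr,
              tasks = tasks, smiles = smiles,
              id = if (is.data.frame(newdata) && "id" %in% names(newdata))
                newdata$id else NULL)
  class(out) <- "mt_ensemble_pred"
  out
}

#' @export
print.mt_ensemble_pred <- function(x, ...) {
  cat(sprintf("<mt_ensemble_pred> %d molecules x %d primary tasks, %d members\n",
              nrow(x$mean), ncol(x$mean), dim(x$member_values)[3L]))
  invisible(x)
}

#' Ensemble predictions as a submission-style table
#'
#' One `pred_<task>` and one `sem_<task>` column per primary task -- the
#' shape of a blind-challenge submission table.
#'
#' @param x `mt_ensemble_pred`.
#' @param row.names,optional,... Standard [as.data.frame()] arguments
#'   (ignored).
#' @return Data frame with `id`, `smiles`, `pred_*`, `sem_*` columns.
#' @export
as.data.frame.mt_ensemble_pred <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  df <- data.frame(id = if (is.null(x$id)) seq_along(x$smiles) else x$id,
                   smiles = x$smiles, stringsAsFactors = FALSE)
  for (task in colnames(x$mean)) {
    df[[paste0("pred_", task)]] <- x$mean[, task]
    df[[paste0("sem_", task)]] <- x$sem[, task]
  }
  df
}
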