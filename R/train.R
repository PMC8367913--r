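# Training: masked multitask MSE on z-scored targets, Adam with a
# Noam-style schedule (linear warmup, exponential decay), best-validation
# checkpointing on the primary tasks.

noam_lr <- function(step, total_steps, warmup_steps, init_lr, max_lr,
                    final_lr) {
  if (warmup_steps > 0 && step <= warmup_steps)
    return(init_lr + (max_lr - init_lr) * step / warmup_steps)
  decay_steps <- max(total_steps - warmup_steps, 1)
  gamma <- (final_lr / max_lr)^(1 / decay_steps)
  max(max_lr * gamma^(step - warmup_steps), final_lr)
}

flatten_weights <- function(w) {
  out <- list(W_in = w$W_in, b_in = w$b_in, W_msg = w$W_msg,
              W_atom = w$W_atom, b_atom = w$b_atom)
  for (l in seq_along(w$ffn)) {
    out[[paste0("ffn_W", l)]] <- w$ffn[[l]]$W
    out[[paste0("ffn_b", l)]] <- w$ffn[[l]]$b
  }
  out
}

unflatten_into <- function(w, flat) {
  w$W_in <- flat$W_in; w$b_in <- flat$b_in; w$W_msg <- flat$W_msg
  w$W_atom <- flat$W_atom; w$b_atom <- flat$b_atom
  for (l in seq_along(w$ffn)) {
    w$ffn[[l]]$W <- flat[[paste0("ffn_W", l)]]
    w$ffn[[l]]$b <- flat[[paste0("ffn_b", l)]]
  }
  w
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    flat[[nm]] <- flat[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

# Fit per-task z-score scalers on observed training values only.
fit_scalers <- function(values, mask, train_idx) {
  n_tasks <- ncol(values)
  mean_ <- numeric(n_tasks); sd_ <- numeric(n_tasks)
  for (j in seq_len(n_tasks)) {
    v <- values[train_idx, j][mask[train_idx, j]]
    if (length(v) < 2L)
      stop(sprintf("task %d has fewer than 2 observed training molecules", j))
    mean_[j] <- mean(v)
    s <- stats::sd(v)
    sd_[j] <- if (is.finite(s) && s > 0) s else 1
  }
  list(mean = mean_, sd = sd_)
}

featurize_records <- function(records) {
  parsed <- parse_smiles_batch(records$smiles,
                               ids = if ("id" %in% names(records))
                                 records$id else NULL)
  if (length(parsed$failures)) {
    bad <- records$smiles[parsed$failures]
    warning(sprintf("dropping %d unfeaturizable molecules: %s",
                    length(bad), paste(utils::head(bad, 5L), collapse = ", ")),
            call. = FALSE)
  }
  keep <- setdiff(seq_len(nrow(records)), parsed$failures)
  graphs <- lapply(parsed$mols[keep], build_directed_graph)
  list(graphs = graphs, keep = keep)
}

#' Train a multitask D-MPNN
#'
#' Targets are z-scored per task on the observed training values; the loss is
#' the masked mean squared error over all observed entries with equal task
#' weighting. The checkpoint kept is the epoch with the lowest validation
#' loss on the primary tasks only (helper tasks regularize but do not drive
#' model selection). With `epochs = 0` the freshly initialized model is
#' returned unchanged.
#'
#' @param records `mt_records` training table (see [make_records()]).
#' @param params `mt_params` architecture settings.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout; required for reproducibility.
#' @param epochs Number of passes over the training data.
#' @param batch_size Molecules per gradient step.
#' @param split Optional `mt_split` fixing train/validation rows; by default
#'   a seeded random 0.9/0.1/0 split is drawn.
#' @param descriptors Optional numeric matrix (rows = molecules) for the
#'   descriptors-as-input channel; requires a matching
#'   `extra_descriptor_dim`.
#' @param lr Learning-rate schedule, a list with `init`, `max`, `final` and
#'   `warmup_epochs` (linear warmup to `max`, then exponential decay).
#' @param verbose Print per-epoch losses.
#' @return Object of class `mt_model`: parameters, best weights, per-task
#'   scalers, task specs, training history and the featurization version.
#' @export
train_dmpnn <- function(records, params, seed, epochs = 30L, batch_size = 50L,
                        split = NULL, descriptors = NULL,
                        lr = list(init = 1e-4, max = 2e-3, final = 1e-4,
                                  warmup_epochs = 2),
                        verbose = FALSE) {
  stopifnot(inherits(records, "mt_records"), inherits(params, "mt_params"))
  tasks <- record_tasks(records)
  if (params$n_tasks != nrow(tasks)) {
    params$n_tasks <- nrow(tasks)
  }
  tm <- target_matrix(records)
  if (any(rowSums(tm$mask) == 0L))
    stop("every molecule must have at least one observed task")
  feat <- featurize_records(records)
  graphs <- feat$graphs
  values <- tm$values[feat$keep, , drop = FALSE]
  mask <- tm$mask[feat$keep, , drop = FALSE]
  if (!is.null(descriptors))
    descriptors <- descriptors[feat$keep, , drop = FALSE]
  n <- length(graphs)
  set.seed(as.integer(seed))
  if (is.null(split)) {
    split <- random_split(n, fractions = c(0.9, 0.1, 0), seed = seed)
  }
  tr <- split$train; va <- split$validation
  scalers <- fit_scalers(values, mask, tr)
  norm_values <- sweep(sweep(values, 2L, scalers$mean), 2L, scalers$sd, "/")
  norm_values[!mask] <- 0
  weights <- init_weights(params)
  primary <- which(tasks$role == "primary")
  model <- structure(list(params = params, weights = weights,
                          scalers = scalers, tasks = tasks, seed = seed,
                          history = data.frame(), version = FEATURIZATION_VERSION),
                     class = "mt_model")
  if (epochs == 0L) return(model)
  flat <- flatten_weights(weights)
  adam <- adam_init(flat)
  steps_per_epoch <- max(1L, ceiling(length(tr) / batch_size))
  total_steps <- steps_per_epoch * epochs
  warmup_steps <- lr$warmup_epochs * steps_per_epoch
  best_val <- Inf
  best_flat <- flat
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(tr)
    ep_loss <- 0; ep_obs <- 0
    for (b in seq_len(steps_per_epoch)) {
      idx <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, length(ord))]
      idx <- idx[!is.na(idx)]
      if (!length(idx)) next
      bg <- combine_graphs(graphs[idx])
      bdesc <- if (is.null(descriptors)) NULL else
        descriptors[idx, , drop = FALSE]
      cache <- dmpnn_forward(bg, unflatten_into(weights, flat), params,
                             descriptors = bdesc, cache = TRUE,
                             training = TRUE)
      bm <- mask[idx, , drop = FALSE]
      bt <- norm_values[idx, , drop = FALSE]
      n_obs <- sum(bm)
      if (n_obs == 0L) next
      resid <- (cache$out - bt) * bm
      loss <- sum(resid^2) / n_obs
      if (!is.finite(loss))
        stop(sprintf("NaN/Inf loss at epoch %d, batch %d; try a lower learning rate",
                     ep, b))
      dout <- 2 * resid / n_obs
      grads <- dmpnn_backward(bg, unflatten_into(weights, flat), params,
                              cache, dout)
      gflat <- list(W_in = grads$W_in, b_in = grads$b_in, W_msg = grads$W_msg,
                    W_atom = grads$W_atom, b_atom = grads$b_atom)
      for (l in seq_along(grads$ffn)) {
        gflat[[paste0("ffn_W", l)]] <- grads$ffn[[l]]$W
        gflat[[paste0("ffn_b", l)]] <- grads$ffn[[l]]$b
      }
      step <- step + 1L
      lr_now <- noam_lr(step, total_steps, warmup_steps, lr$init, lr$max,
                        lr$final)
      upd <- adam_step(flat, gflat, adam, lr_now)
      flat <- upd$flat; adam <- upd$state
      ep_loss <- ep_loss + loss * n_obs; ep_obs <- ep_obs + n_obs
    }
    train_loss <- ep_loss / max(ep_obs, 1)
    val_loss <- NA_real_
    if (length(va)) {
      w_now <- unflatten_into(weights, flat)
      vpred <- predict_batched(graphs[va], w_now, params,
                               if (is.null(descriptors)) NULL else
                                 descriptors[va, , drop = FALSE])
      vm <- mask[va, primary, drop = FALSE]
      vt <- norm_values[va, primary, drop = FALSE]
      vp <- vpred[, primary, drop = FALSE]
      val_loss <- sum(((vp - vt) * vm)^2) / max(sum(vm), 1L)
      if (val_loss < best_val) {
        best_val <- val_loss
        best_flat <- flat
      }
    } else {
      best_flat <- flat
    }
    history <- rbind(history, data.frame(epoch = ep, train_loss = train_loss,
                                         val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %s", ep, train_loss,
                      ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
  }
  model$weights <- unflatten_into(weights, best_flat)
  model$history <- history
  model$split <- split
  model
}

# Forward over a list of graphs in chunks (normalized scale, all tasks).
predict_batched <- function(graphs, weights, params, descriptors = NULL,
                            chunk = 500L) {
  n <- length(graphs)
  out <- matrix(NA_real_, n, params$n_tasks)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    bg <- combine_graphs(graphs[i:j])
    d <- if (is.null(descriptors)) NULL else descriptors[i:j, , drop = FALSE]
    out[i:j, ] <- dmpnn_forward(bg, weights, params, descriptors = d)
    i <- j + 1L
  }
  out
}

#' Predict all tasks (de-normalized units)
#'
#' @param model `mt_model`.
#' @param newdata Character vector of SMILES or an `mt_records` table.
#' @param descriptors Optional descriptor matrix matching `newdata` rows.
#' @return Numeric matrix (molecules x tasks) in original units; rows of
#'   unfeaturizable molecules are `NA` (with a warning naming them).
#' @export
predict_tasks <- function(model, newdata, descriptors = NULL) {
  stopifnot(inherits(model, "mt_model"))
  if (!identical(model$version, FEATURIZATION_VERSION))
    stop(sprintf("model featurization version '%s' does not match '%s'",
                 model$version, FEATURIZATION_VERSION))
  smiles <- if (is.data.frame(newdata)) newdata$smiles else newdata
  parsed <- parse_smiles_batch(smiles)
  keep <- setdiff(seq_along(smiles), parsed$failures)
  if (length(parsed$failures))
    warning(sprintf("%d molecules could not be featurized: %s",
                    length(parsed$failures),
                    paste(utils::head(smiles[parsed$failures], 5L),
                          collapse = ", ")), call. = FALSE)
  out <- matrix(NA_real_, length(smiles), model$params$n_tasks,
                dimnames = list(NULL, model$tasks$name))
  if (length(keep)) {
    graphs <- lapply(parsed$mols[keep], build_directed_graph)
    d <- if (is.null(descriptors)) NULL else
      descriptors[keep, , drop = FALSE]
    norm_pred <- predict_batched(graphs, model$weights, model$params, d)
    pred <- sweep(sweep(norm_pred, 2L, model$scalers$sd, "*"), 2L,
                  model$scalers$mean, "+")
    out[keep, ] <- pred
  }
  out
}

#' Predict primary tasks only
#'
#' Helper-task outputs are computed internally but dropped: helpers exist to
#' regularize training and are never part of the reported prediction.
#'
#' @inheritParams predict_tasks
#' @return Numeric matrix (molecules x primary tasks).
#' @export
predict_primary <- function(model, newdata, descriptors = NULL) {
  full <- predict_tasks(model, newdata, descriptors)
  primary <- model$tasks$name[model$tasks$role == "primary"]
  full[, primary, drop = FALSE]
}

#' @export
predict.mt_model <- function(object, newdata, ...) {
  predict_primary(object, newdata, ...)
}

#' @export
print.mt_model <- function(x, ...) {
  cat(sprintf("<mt_model> %d tasks (%d primary), depth %d, hidden %d\n",
              x$params$n_tasks, sum(x$tasks$role == "primary"),
              x$params$depth, x$params$hidden_size))
  if (nrow(x$history))
    cat(sprintf("  trained %d epochs; best val loss %.4f\n",
                max(x$history$epoch), min(x$history$val_loss, na.rm = TRUE)))
  invisible(x)
}

#' Save a trained model to a checkpoint file
#'
#' The checkpoint is a single serialized RDS file holding parameters,
#' weights, task specs, scalers and the featurization version tag; loading
#' into a package with a different featurization version is refused.
#'
#' @param model `mt_model` or `mt_ensemble`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mt_model") || inherits(model, "mt_ensemble"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_model()].
#' @return The `mt_model` / `mt_ensemble`.
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  v <- if (inherits(m, "mt_ensemble")) m$members[[1L]]$version else m$version
  if (!identical(v, FEATURIZATION_VERSION))
    stop(sprintf("checkpoint featurization version '%s' does not match '%s'",
                 v, FEATURIZATION_VERSION))
  m
}
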