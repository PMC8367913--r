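# Ensemble training, mean/SEM arithmetic, member independence.

# A rigged model whose prediction is a constant: all weights zero except the
# final feed-forward bias. Exercises the real prediction path end to end.
constant_model <- function(value, tasks = task_spec("y", "primary")) {
  p <- model_params(depth = 2L, hidden_size = 4L,
                    n_tasks = nrow(tasks))
  set.seed(0)
  w <- init_weights(p)
  for (nm in c("W_in", "b_in", "W_msg", "W_atom", "b_atom")) w[[nm]][] <- 0
  for (l in seq_along(w$ffn)) { w$ffn[[l]]$W[] <- 0; w$ffn[[l]]$b[] <- 0 }
  w$ffn[[length(w$ffn)]]$b[] <- value
  structure(list(params = p, weights = w,
                 scalers = list(mean = rep(0, nrow(tasks)),
                                sd = rep(1, nrow(tasks))),
                 tasks = tasks, seed = 0L, history = data.frame(),
                 version = mtlogp:::FEATURIZATION_VERSION),
            class = "mt_model")
}

test_that("SEM follows the hand-computed arithmetic", {
  ens <- structure(list(members = lapply(c(1, 2, 3), constant_model),
                        seeds = 1:3), class = "mt_ensemble")
  pred <- predict_with_sem(ens, c("CCO", "c1ccccc1"))
  expect_equal(unname(pred$mean[, 1L]), c(2, 2))
  expect_equal(unname(pred$sem[, 1L]), rep(1 / sqrt(3), 2L), tolerance = 1e-12)
  expect_equal(dim(pred$member_values), c(2L, 1L, 3L))
})

test_that("identical members give SEM 0 and singletons behave like the model", {
  ens <- structure(list(members = lapply(c(2, 2, 2), constant_model),
                        seeds = 1:3), class = "mt_ensemble")
  pred <- predict_with_sem(ens, "CCN")
  expect_equal(unname(pred$sem[, 1L]), 0)

  single <- constant_model(1.5)
  pred1 <- predict_with_sem(single, "CCN")
  expect_equal(unname(pred1$mean[, 1L]), 1.5)
  expect_equal(unname(pred1$sem[, 1L]), 0)
})

test_that("ensemble members are independently seeded and reproducible", {
  df <- generate_synthetic(30, seed = 21)
  rec <- synthetic_records(df)
  p <- model_params(depth = 2L, hidden_size = 8L)
  ens <- train_ensemble(rec, p, n_members = 3L, base_seed = 100L,
                        epochs = 2L, batch_size = 10L)
  expect_equal(ens$seeds, c(100L, 101L, 102L))
  # distinct weights across members
  expect_false(identical(ens$members[[1L]]$weights$W_in,
                         ens$members[[2L]]$weights$W_in))
  expect_false(identical(ens$members[[2L]]$weights$W_in,
                         ens$members[[3L]]$weights$W_in))
  # rerun with the same base seed reproduces the ensemble
  ens2 <- train_ensemble(rec, p, n_members = 3L, base_seed = 100L,
                         epochs = 2L, batch_size = 10L)
  expect_equal(ens$members[[2L]]$weights$W_in, ens2$members[[2L]]$weights$W_in)
  # member 1 equals a plain training run with the base seed
  solo <- train_dmpnn(rec, p, seed = 100L, epochs = 2L, batch_size = 10L)
  expect_equal(ens$members[[1L]]$weights$W_in, solo$weights$W_in)
})

test_that("ensemble mean error never exceeds the mean member error", {
  df <- generate_synthetic(120, noise_sd = 0.2, seed = 31)
  rec <- synthetic_records(df)
  p <- model_params(depth = 2L, hidden_size = 16L)
  ens <- train_ensemble(rec, p, n_members = 3L, base_seed = 50L,
                        epochs = 4L, batch_size = 20L)
  eval_df <- generate_synthetic(60, noise_sd = 0.2, seed = 32)
  pred <- predict_with_sem(ens, eval_df$smiles)
  member_rmse <- vapply(seq_len(3L), function(i)
    rmse(eval_df$logp_observed, pred$member_values[, 1L, i]), numeric(1))
  ens_rmse <- rmse(eval_df$logp_observed, pred$mean[, 1L])
  expect_lte(ens_rmse, mean(member_rmse) + 1e-12)
  # SEM is non-negative and order-invariant
  expect_true(all(pred$sem >= 0))
  perm <- structure(list(members = ens$members[c(3L, 1L, 2L)],
                         seeds = ens$seeds[c(3L, 1L, 2L)]),
                    class = "mt_ensemble")
  pred_perm <- predict_with_sem(perm, eval_df$smiles)
  expect_equal(pred_perm$sem, pred$sem, tolerance = 1e-12)
})

test_that("prediction tables have the submission shape", {
  ens <- structure(list(members = lapply(c(1, 3), constant_model),
                        seeds = 1:2), class = "mt_ensemble")
  df <- as.data.frame(predict_with_sem(ens, c("CCO", "CCN")))
  expect_named(df, c("id", "smiles", "pred_y", "sem_y"))
  expect_equal(df$pred_y, c(2, 2))
  expect_equal(df$sem_y, rep(sd(c(1, 3)) / sqrt(2), 2L))
})
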