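# Task assembly, helper injection, masked loss, training loop contracts.

test_that("assemble_tasks separates or merges datasets", {
  d1 <- data.frame(smiles = c("CCO", "CCN", "CCS"), logp = c(1, 2, 3))
  d2 <- data.frame(smiles = c("CCC", "CCCC"), logp = c(0.5, 1.5))
  sep <- assemble_tasks(list(opera = d1, chembl = d2), mode = "separate")
  expect_equal(nrow(record_tasks(sep)), 2L)
  tm <- target_matrix(sep)
  expect_true(all(rowSums(tm$mask) == 1L))

  mrg <- assemble_tasks(list(opera = d1, chembl = d2), mode = "merged")
  expect_equal(nrow(record_tasks(mrg)), 1L)
  expect_true(all(target_matrix(mrg)$mask))
})

test_that("overlapping molecules become single rows with two observations", {
  d1 <- data.frame(smiles = c("CCO", "CCN", "CCS", "CCC", "CCF"),
                   logp = 1:5)
  d2 <- data.frame(smiles = c("OCC", "NCC", "SCC", "CCCCC"),  # 3 overlap
                   logp = c(10, 20, 30, 40))
  sep <- assemble_tasks(list(a = d1, b = d2), mode = "separate")
  tm <- target_matrix(sep)
  expect_equal(nrow(sep), 6L)  # 5 + 1 new
  expect_equal(sum(rowSums(tm$mask) == 2L), 3L)
})

test_that("duplicate measurements within a dataset aggregate by median", {
  d <- data.frame(smiles = c("CCO", "OCC", "CCO", "CCN"),
                  logp = c(1, 3, 2, 7))
  expect_message(
    rec <- assemble_tasks(list(x = d), mode = "separate"),
    "duplicate")
  tm <- target_matrix(rec)
  i <- match(canonical_smiles("CCO"), rec$smiles)
  expect_equal(unname(tm$values[i, 1L]), 2)  # median of 1,3,2
})

test_that("attach_helper_tasks adds helper columns and keeps them out of predictions", {
  df <- data.frame(smiles = c("CCO", "CCN", "CCS", "CCC", "CCCC", "CCCCC"),
                   y = c(0.1, 0.5, 0.9, 0.3, 0.7, 1.1))
  rec <- make_records(df)
  const0 <- function(s) data.frame(h1 = rep(0, length(s)))
  rec2 <- attach_helper_tasks(rec, const0)
  expect_equal(record_tasks(rec2)$role, c("primary", "helper"))
  expect_true(all(rec2$h1 == 0))
  # no provider = identity (singletask path)
  expect_identical(attach_helper_tasks(rec, NULL), rec)

  p <- model_params(depth = 2L, hidden_size = 8L, n_tasks = 2L)
  fit <- suppressWarnings(train_dmpnn(rec2, p, seed = 5L, epochs = 2L,
                                      batch_size = 3L))
  pred <- predict_primary(fit, c("CCO", "CCCOC"))
  expect_equal(colnames(pred), "y")
  expect_equal(ncol(pred), 1L)
  full <- predict_tasks(fit, c("CCO", "CCCOC"))
  expect_equal(ncol(full), 2L)
})

test_that("synthetic helper columns correlate with the primary truth", {
  df <- benchmark_data()
  expect_gt(cor(df$helper_logp, df$true_logp), 0.9)
  expect_gt(cor(df$helper_logd, df$true_logp), 0.8)
})

test_that("masked_loss follows its contract", {
  v <- matrix(c(1, 2, 3, 4), 2L, 2L)
  m <- matrix(TRUE, 2L, 2L)
  expect_equal(masked_loss(v, list(values = v, mask = m)), 0)
  # single observed cell with error 2 -> loss 4
  m1 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2L, 2L)
  p1 <- v; p1[1L, 1L] <- v[1L, 1L] + 2
  expect_equal(masked_loss(p1, list(values = v, mask = m1)), 4)
  # values under the mask are ignored bit-for-bit
  v2 <- v; v2[!m1] <- 1e6
  expect_identical(masked_loss(p1, list(values = v2, mask = m1)),
                   masked_loss(p1, list(values = v, mask = m1)))
  expect_error(masked_loss(v, list(values = v, mask = !m)), "no observed")
})

test_that("training decreases the loss and is seed-deterministic", {
  df <- generate_synthetic(50, noise_sd = 0.1, seed = 3)
  rec <- synthetic_records(df)
  p <- model_params(depth = 2L, hidden_size = 16L)
  fit <- train_dmpnn(rec, p, seed = 9L, epochs = 5L, batch_size = 10L)
  expect_lt(fit$history$train_loss[5L], fit$history$train_loss[1L])
  fit2 <- train_dmpnn(rec, p, seed = 9L, epochs = 5L, batch_size = 10L)
  expect_identical(fit$history$val_loss, fit2$history$val_loss)
  expect_equal(fit$weights$W_in, fit2$weights$W_in)
})

test_that("epochs = 0 returns the initialized model unchanged", {
  df <- generate_synthetic(20, seed = 4)
  rec <- synthetic_records(df)
  p <- model_params(depth = 2L, hidden_size = 8L)
  fit <- train_dmpnn(rec, p, seed = 1L, epochs = 0L)
  expect_s3_class(fit, "mt_model")
  expect_equal(nrow(fit$history), 0L)
  # weights equal a fresh Xavier draw under the same seed
  set.seed(1L)
  w <- init_weights(p)
  expect_equal(fit$weights$W_in, w$W_in)
})

test_that("perturbing masked targets changes neither loss nor gradients", {
  df <- generate_synthetic(12, seed = 6)
  rec <- synthetic_records(df, helpers = TRUE)
  tm <- target_matrix(rec)
  tm$values[2L, 2L] <- NA  # mask one helper cell
  tm$mask[2L, 2L] <- FALSE
  p <- model_params(depth = 2L, hidden_size = 4L, n_tasks = 3L)
  set.seed(8)
  w <- init_weights(p)
  graphs <- lapply(parse_smiles_batch(rec$smiles)$mols, build_directed_graph)
  bg <- combine_graphs(graphs)
  grad_for <- function(values) {
    values[!tm$mask] <- 0
    cache <- mtlogp:::dmpnn_forward(bg, w, p, cache = TRUE)
    resid <- (cache$out - values) * tm$mask
    dout <- 2 * resid / sum(tm$mask)
    mtlogp:::dmpnn_backward(bg, w, p, cache, dout)
  }
  v1 <- tm$values
  v2 <- tm$values
  v2[!tm$mask] <- 123.45
  g1 <- grad_for(v1)
  g2 <- grad_for(v2)
  expect_identical(g1$W_in, g2$W_in)
  expect_identical(g1$ffn[[1L]]$W, g2$ffn[[1L]]$W)
})

test_that("normalization round-trips through training", {
  df <- generate_synthetic(40, noise_sd = 0.1, seed = 10)
  rec <- synthetic_records(df)
  p <- model_params(depth = 2L, hidden_size = 8L)
  fit <- train_dmpnn(rec, p, seed = 2L, epochs = 3L, batch_size = 10L)
  pred <- predict_primary(fit, rec$smiles[1:5])
  # de-normalized predictions live on the scale of the targets
  expect_true(all(is.finite(pred)))
  expect_lt(abs(mean(pred) - mean(df$logp_observed)), 3 * sd(df$logp_observed))
  # a model asked to predict garbage rows isolates the failure
  expect_warning(p2 <- predict_primary(fit, c("CCO", "C1CC")), "featurized")
  expect_true(is.na(p2[2L, 1L]))
  expect_false(is.na(p2[1L, 1L]))
})

test_that("model checkpoints round-trip through save/load", {
  df <- generate_synthetic(20, seed = 12)
  rec <- synthetic_records(df)
  p <- model_params(depth = 2L, hidden_size = 6L)
  fit <- train_dmpnn(rec, p, seed = 3L, epochs = 1L, batch_size = 10L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, path)
  fit2 <- load_model(path)
  expect_equal(predict_primary(fit2, "CCO"), predict_primary(fit, "CCO"))
  # version mismatch is refused
  fit3 <- fit
  fit3$version <- "mtlogp-feat-0"
  save_model(fit3, path)
  expect_error(load_model(path), "version")
})
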