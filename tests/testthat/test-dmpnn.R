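# Network mechanics: edge-state init, reverse-edge exclusion, readout,
# forward equivalence against the nested-loop oracle, batching, gradients.

test_that("init_edge_states handles degenerate graphs", {
  p <- model_params(hidden_size = 4L)
  set.seed(1)
  w <- init_weights(p)
  g0 <- build_directed_graph("C")
  h0 <- init_edge_states(g0, w)
  expect_equal(dim(h0), c(0L, 4L))
  # zero weights give all-zero states
  wz <- w
  wz$W_in[] <- 0; wz$b_in[] <- 0
  g <- build_directed_graph("CC")
  expect_true(all(init_edge_states(g, wz) == 0))
})

test_that("reverse-edge exclusion zeroes the message on a two-atom molecule", {
  p <- model_params(hidden_size = 6L, depth = 4L)
  set.seed(2)
  w <- init_weights(p)
  g <- build_directed_graph("CC")
  h0 <- init_edge_states(g, w)
  h <- h0
  for (t in 1:5) {
    h <- message_pass(g, h, h0, w)
    # the only incoming edge of each edge's source is its own reverse,
    # so the aggregated message is empty and the state stays relu(h0) = h0
    expect_equal(h, h0, tolerance = 1e-12)
  }
})

test_that("message passing on a path sends the upstream edge state", {
  # A-B-C: message into edge (B->C) is exactly the state of (A->B)
  p <- model_params(hidden_size = 3L, depth = 2L)
  w <- init_weights(p)
  w$W_msg <- diag(3)  # identity propagation, pre-activation additive
  g <- build_directed_graph("CCO")
  h0 <- init_edge_states(g, w)
  h1 <- message_pass(g, h0, h0, w)
  e_ab <- which(g$edge_source == 1L & g$edge_target == 2L)
  e_bc <- which(g$edge_source == 2L & g$edge_target == 3L)
  expect_equal(h1[e_bc, ], pmax(h0[e_bc, ] + h0[e_ab, ], 0))
})

test_that("star-graph messages sum the other leaves", {
  p <- model_params(hidden_size = 4L, depth = 2L)
  set.seed(3)
  w <- init_weights(p)
  w$W_msg <- diag(4)
  g <- build_directed_graph("C(C)(C)(C)C")  # neopentane: center atom 1
  h0 <- init_edge_states(g, w)
  h1 <- message_pass(g, h0, h0, w)
  leaves <- setdiff(seq_len(g$n_atoms), 1L)
  for (lf in leaves) {
    e_out <- which(g$edge_source == 1L & g$edge_target == lf)
    others <- which(g$edge_target == 1L & g$edge_source != lf)
    expect_length(others, 3L)
    expected <- pmax(h0[e_out, ] + colSums(h0[others, , drop = FALSE]), 0)
    expect_equal(h1[e_out, ], expected)
  }
})

test_that("readout of a single atom uses a zero message", {
  p <- model_params(hidden_size = 5L)
  set.seed(4)
  w <- init_weights(p)
  g <- build_directed_graph("C")
  states <- matrix(0, 0L, 5L)
  vec <- readout(g, states, w, aggregation = "mean")
  manual <- pmax(c(cbind(g$atom_features, matrix(0, 1L, 5L)) %*% w$W_atom) +
                   w$b_atom, 0)
  expect_equal(c(vec), manual)
})

test_that("vectorized forward matches the nested-loop oracle", {
  pool <- test_smiles_pool()
  set.seed(11)
  smiles <- sample(pool, 22L, replace = TRUE)
  for (i in seq_along(smiles)) {
    depth <- sample(1:3, 1L)
    hidden <- sample(2:8, 1L)
    ffn <- sample(1:3, 1L)
    agg <- sample(c("mean", "sum"), 1L)
    p <- model_params(depth = depth, hidden_size = hidden,
                      ffn_num_layers = ffn, n_tasks = sample(1:3, 1L),
                      aggregation = agg)
    w <- init_weights(p)
    g <- build_directed_graph(smiles[i])
    bg <- combine_graphs(list(g))
    fast <- mtlogp:::dmpnn_forward(bg, w, p)
    slow <- oracle_forward(g, w, p)
    expect_equal(c(fast), slow, tolerance = 1e-6,
                 label = sprintf("forward(%s, depth=%d, hidden=%d)",
                                 smiles[i], depth, hidden))
  }
})

test_that("descriptor channel matches the oracle too", {
  p <- model_params(depth = 2L, hidden_size = 5L, ffn_num_layers = 2L,
                    extra_descriptor_dim = 3L, n_tasks = 2L)
  set.seed(12)
  w <- init_weights(p)
  g <- build_directed_graph("CC(=O)NC")
  d <- matrix(rnorm(3), 1L, 3L)
  fast <- mtlogp:::dmpnn_forward(combine_graphs(list(g)), w, p,
                                 descriptors = d)
  slow <- oracle_forward(g, w, p, descriptors = d)
  expect_equal(c(fast), slow, tolerance = 1e-6)
})

test_that("batching does not change predictions", {
  p <- model_params(depth = 3L, hidden_size = 8L, n_tasks = 2L)
  set.seed(13)
  w <- init_weights(p)
  smiles <- c("CCO", "c1ccccc1", "CC(C)C", "CC(=O)NC", "C", "CCS", "CCN",
              "c1ccncc1")
  graphs <- lapply(smiles, build_directed_graph)
  full <- mtlogp:::dmpnn_forward(combine_graphs(graphs), w, p)
  for (i in seq_along(graphs)) {
    single <- mtlogp:::dmpnn_forward(combine_graphs(graphs[i]), w, p)
    expect_equal(c(single), c(full[i, ]), tolerance = 1e-6)
  }
})

test_that("predictions are invariant to atom renumbering", {
  p <- model_params(depth = 3L, hidden_size = 8L)
  set.seed(14)
  w <- init_weights(p)
  pairs <- list(c("CCO", "OCC"),
                c("CC(C)Cc1ccc(C)cc1", "Cc1ccc(CC(C)C)cc1"),
                c("CC(=O)NC", "CNC(C)=O"))
  for (pr in pairs) {
    o1 <- mtlogp:::dmpnn_forward(combine_graphs(list(build_directed_graph(pr[1L]))), w, p)
    o2 <- mtlogp:::dmpnn_forward(combine_graphs(list(build_directed_graph(pr[2L]))), w, p)
    expect_equal(c(o1), c(o2), tolerance = 1e-5, label = pr[1L])
  }
})

test_that("analytic gradients match finite differences", {
  p <- model_params(depth = 3L, hidden_size = 4L, ffn_num_layers = 2L,
                    n_tasks = 2L)
  set.seed(15)
  w <- init_weights(p)
  graphs <- lapply(c("CCO", "c1ccccc1C", "CC(=O)NC"), build_directed_graph)
  bg <- combine_graphs(graphs)
  tgt <- matrix(rnorm(6), 3L, 2L)
  msk <- matrix(c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE), 3L, 2L)
  lossfn <- function(w) {
    out <- mtlogp:::dmpnn_forward(bg, w, p)
    sum(((out - tgt) * msk)^2) / sum(msk)
  }
  cache <- mtlogp:::dmpnn_forward(bg, w, p, cache = TRUE)
  dout <- 2 * ((cache$out - tgt) * msk) / sum(msk)
  g <- mtlogp:::dmpnn_backward(bg, w, p, cache, dout)
  eps <- 1e-6
  probe <- function(get, set, grad) {
    ii <- sample(length(get(w)), min(5L, length(get(w))))
    for (i in ii) {
      wp <- w; x <- get(wp); x[i] <- x[i] + eps; wp <- set(wp, x)
      wm <- w; x <- get(wm); x[i] <- x[i] - eps; wm <- set(wm, x)
      fd <- (lossfn(wp) - lossfn(wm)) / (2 * eps)
      expect_equal(fd, grad[i], tolerance = 1e-4)
    }
  }
  probe(function(w) w$W_in, function(w, x) { w$W_in[] <- x; w }, g$W_in)
  probe(function(w) w$W_msg, function(w, x) { w$W_msg[] <- x; w }, g$W_msg)
  probe(function(w) w$W_atom, function(w, x) { w$W_atom[] <- x; w }, g$W_atom)
  probe(function(w) w$ffn[[2]]$W, function(w, x) { w$ffn[[2]]$W[] <- x; w },
        g$ffn[[2]]$W)
})

test_that("depth 1 reduces to init + readout", {
  p1 <- model_params(depth = 1L, hidden_size = 6L)
  set.seed(16)
  w <- init_weights(p1)
  g <- build_directed_graph("CCO")
  bg <- combine_graphs(list(g))
  out <- mtlogp:::dmpnn_forward(bg, w, p1)
  # manual: h0, atom readout, ffn -- no message pass at all
  h0 <- init_edge_states(bg, w)
  vec <- readout(bg, h0, w, "mean")
  x <- vec
  for (l in 1:2) {
    x <- x %*% w$ffn[[l]]$W + rep(w$ffn[[l]]$b, each = 1L)
    if (l < 2) x <- pmax(x, 0)
  }
  expect_equal(out, x, tolerance = 1e-10, ignore_attr = TRUE)
})
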