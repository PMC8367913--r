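# Dependency-free nested-loop re-implementation of the D-MPNN forward pass,
# used as the independent oracle for the vectorized implementation. Scalar
# loops only -- no matrix products, no shared code with dmpnn_forward().

oracle_forward <- function(graph, weights, params, descriptors = NULL) {
  A <- graph$n_atoms
  E <- graph$n_directed_edges
  h <- params$hidden_size
  af <- graph$atom_features
  ef <- graph$edge_features
  src <- graph$edge_source
  tgt <- graph$edge_target
  rev <- graph$reverse_edge
  da <- ncol(af)
  db <- ncol(ef)
  relu1 <- function(x) if (x > 0) x else 0
  # initial edge states
  z0 <- matrix(0, E, h)
  if (E > 0) for (e in 1:E) for (k in 1:h) {
    acc <- weights$b_in[k]
    for (j in 1:da) acc <- acc + af[src[e], j] * weights$W_in[j, k]
    for (j in 1:db) acc <- acc + ef[e, j] * weights$W_in[da + j, k]
    z0[e, k] <- acc
  }
  hcur <- matrix(0, E, h)
  if (E > 0) for (e in 1:E) for (k in 1:h) hcur[e, k] <- relu1(z0[e, k])
  # message passing (reverse edge excluded)
  if (params$depth > 1L && E > 0) for (t in 1:(params$depth - 1L)) {
    hn <- matrix(0, E, h)
    for (e in 1:E) {
      msg <- numeric(h)
      for (k in 1:E) {
        if (tgt[k] == src[e] && k != rev[e]) msg <- msg + hcur[k, ]
      }
      for (kk in 1:h) {
        acc <- z0[e, kk]
        for (j in 1:h) acc <- acc + msg[j] * weights$W_msg[j, kk]
        hn[e, kk] <- relu1(acc)
      }
    }
    hcur <- hn
  }
  # atom readout
  hv <- matrix(0, A, h)
  for (v in 1:A) {
    msg <- numeric(h)
    if (E > 0) for (e in 1:E) if (tgt[e] == v) msg <- msg + hcur[e, ]
    for (k in 1:h) {
      acc <- weights$b_atom[k]
      for (j in 1:da) acc <- acc + af[v, j] * weights$W_atom[j, k]
      for (j in 1:h) acc <- acc + msg[j] * weights$W_atom[da + j, k]
      hv[v, k] <- relu1(acc)
    }
  }
  vec <- numeric(h)
  for (k in 1:h) {
    s <- 0
    for (v in 1:A) s <- s + hv[v, k]
    vec[k] <- if (params$aggregation == "mean") s / A else s
  }
  if (!is.null(descriptors)) vec <- c(vec, as.numeric(descriptors))
  # feed-forward head
  x <- vec
  L <- params$ffn_num_layers
  for (l in 1:L) {
    W <- weights$ffn[[l]]$W
    b <- weights$ffn[[l]]$b
    y <- numeric(ncol(W))
    for (k in seq_len(ncol(W))) {
      acc <- b[k]
      for (j in seq_len(nrow(W))) acc <- acc + x[j] * W[j, k]
      y[k] <- if (l < L) relu1(acc) else acc
    }
    x <- y
  }
  x
}

# A small pool of diverse, valid SMILES used by randomized property tests.
test_smiles_pool <- function() {
  c("C", "CC", "CCO", "CCN", "c1ccccc1", "Cc1ccccc1", "CC(C)C", "C(C)(C)(C)C",
    "CC(=O)NC", "c1ccncc1", "CC(=O)OC", "CCS", "CC(F)C", "CC(Cl)C",
    "c1ccsc1", "c1ccoc1", "CC(=O)O", "CCOCC", "CC#N", "C=CC",
    "CN1CCCC1", "OCC(O)CO", "Clc1ccccc1", "CC(C)Cc1ccc(C)cc1",
    "CCc1ccccc1CC(C)N", "COc1ccccc1OC", "CS(=O)(=O)N", "NC(=O)CC",
    "CCCCCC", "CC1CCCCC1")
}

# Cached synthetic benchmark shared by the heavier training tests so the
# dataset is assembled only once per test run.
benchmark_env <- new.env(parent = emptyenv())

benchmark_data <- function() {
  if (is.null(benchmark_env$df)) {
    benchmark_env$df <- generate_synthetic(2000, noise_sd = 0.3,
                                           helper_noise_sd = 0.2, seed = 7)
  }
  benchmark_env$df
}
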