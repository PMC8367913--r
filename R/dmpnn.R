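# The directed message-passing network. Edge states are initialized from
# (source-atom features, bond features), updated for depth-1 steps by summing
# incoming edge states while excluding each edge's reverse, read out per atom,
# aggregated per molecule, and passed through a feed-forward head with one
# output unit per task.

#' Model hyperparameters
#'
#' Defaults follow the usual D-MPNN ("chemprop") settings: depth 3, hidden
#' size 300, two feed-forward layers, no dropout, mean aggregation. The
#' settings reported to work best for lipophilicity (depth 5, hidden 700,
#' three feed-forward layers, dropout 0) are available via
#' `model_params(depth = 5, hidden_size = 700, ffn_num_layers = 3)`.
#'
#' @param depth Number of message-passing steps (>= 1; depth 1 is
#'   initialization plus readout, no message exchange).
#' @param hidden_size Width of the edge states and feed-forward hidden
#'   layers.
#' @param ffn_num_layers Number of feed-forward layers (the last one is the
#'   linear task output).
#' @param dropout Dropout fraction in `[0, 1)`, applied after activations
#'   during training only.
#' @param n_tasks Number of output tasks.
#' @param extra_descriptor_dim Length of an optional per-molecule descriptor
#'   vector concatenated to the learned molecule vector before the head
#'   (descriptors-as-input mode); 0 disables the channel.
#' @param aggregation Atom-to-molecule aggregation, `"mean"` or `"sum"`.
#' @return Object of class `mt_params`.
#' @export
model_params <- function(depth = 3L, hidden_size = 300L, ffn_num_layers = 2L,
                         dropout = 0, n_tasks = 1L, extra_descriptor_dim = 0L,
                         aggregation = c("mean", "sum")) {
  aggregation <- match.arg(aggregation)
  depth <- as.integer(depth); hidden_size <- as.integer(hidden_size)
  ffn_num_layers <- as.integer(ffn_num_layers); n_tasks <- as.integer(n_tasks)
  extra_descriptor_dim <- as.integer(extra_descriptor_dim)
  stopifnot(depth >= 1L, hidden_size >= 1L, ffn_num_layers >= 1L,
            dropout >= 0, dropout < 1, n_tasks >= 1L,
            extra_descriptor_dim >= 0L)
  p <- list(depth = depth, hidden_size = hidden_size,
            ffn_num_layers = ffn_num_layers, dropout = dropout,
            n_tasks = n_tasks, extra_descriptor_dim = extra_descriptor_dim,
            aggregation = aggregation)
  class(p) <- "mt_params"
  p
}

xavier <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize network weights
#'
#' Xavier-uniform initialization drawn from the current RNG state; call
#' `set.seed()` first (the training loop does this for you). All linear maps
#' carry a bias except the message-update matrix `W_msg`.
#'
#' @param params `mt_params`.
#' @param atom_dim,bond_dim Feature dimensions (default: the package's
#'   featurization, see [feature_dims()]).
#' @return Object of class `mt_weights` (named list of matrices/vectors).
#' @export
init_weights <- function(params, atom_dim = feature_dims()[["atom"]],
                         bond_dim = feature_dims()[["bond"]]) {
  h <- params$hidden_size
  w <- list(
    W_in = xavier(atom_dim + bond_dim, h), b_in = numeric(h),
    W_msg = xavier(h, h),
    W_atom = xavier(atom_dim + h, h), b_atom = numeric(h)
  )
  ffn_in <- h + params$extra_descriptor_dim
  L <- params$ffn_num_layers
  ffn <- vector("list", L)
  for (l in seq_len(L)) {
    n_in <- if (l == 1L) ffn_in else h
    n_out <- if (l == L) params$n_tasks else h
    ffn[[l]] <- list(W = xavier(n_in, n_out), b = numeric(n_out))
  }
  w$ffn <- ffn
  attr(w, "atom_dim") <- as.integer(atom_dim)
  attr(w, "bond_dim") <- as.integer(bond_dim)
  class(w) <- "mt_weights"
  w
}

relu <- function(x) (x > 0) * x

add_bias <- function(m, b) m + rep(b, each = nrow(m))

# Sum rows of `m` by integer group `idx` into an `n`-row matrix (groups with
# no members stay zero). rowsum() drops absent groups, hence the scatter.
scatter_sum <- function(m, idx, n) {
  out <- matrix(0, n, ncol(m))
  if (length(idx) == 0L || nrow(m) == 0L) return(out)
  rs <- rowsum(m, idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

drop_mask <- function(nr, nc, p) {
  matrix((stats::runif(nr * nc) >= p) / (1 - p), nr, nc)
}

#' Initial edge states
#'
#' `h0_e = relu(W_in %*% c(atom_features[source(e)], edge_features[e]) + b)`.
#'
#' @param graph `mt_graph` or `mt_batch_graph`.
#' @param weights `mt_weights`.
#' @return Matrix (n_directed_edges x hidden).
#' @export
init_edge_states <- function(graph, weights) {
  ein <- cbind(graph$atom_features[graph$edge_source, , drop = FALSE],
               graph$edge_features)
  relu(add_bias(ein %*% weights$W_in, weights$b_in))
}

#' One message-passing step
#'
#' For edge `e = (v -> w)` the incoming message sums the states of edges into
#' `v` except the reverse edge `(w -> v)`; the update is
#' `relu(h0_e + W_msg %*% m_e)`.
#'
#' @param graph `mt_graph` or `mt_batch_graph`.
#' @param states Current edge states (n_directed_edges x hidden).
#' @param h0 Initial edge states from [init_edge_states()].
#' @param weights `mt_weights`.
#' @return Updated edge-state matrix.
#' @export
message_pass <- function(graph, states, h0, weights) {
  s <- scatter_sum(states, graph$edge_target, graph$n_atoms)
  m <- s[graph$edge_source, , drop = FALSE]
  if (graph$n_directed_edges > 0L)
    m <- m - states[graph$reverse_edge, , drop = FALSE]
  relu(h0 + m %*% weights$W_msg)
}

#' Atom readout and molecule aggregation
#'
#' Sums final edge states into their target atoms, applies the atom update
#' `relu(W_atom %*% c(atom_features, message) + b)` and aggregates atoms to a
#' molecule vector (mean by default).
#'
#' @param graph `mt_graph` or `mt_batch_graph`.
#' @param states Final edge states.
#' @param weights `mt_weights`.
#' @param aggregation `"mean"` or `"sum"`.
#' @return Matrix (n_molecules x hidden).
#' @export
readout <- function(graph, states, weights, aggregation = "mean") {
  sa <- scatter_sum(states, graph$edge_target, graph$n_atoms)
  ain <- cbind(graph$atom_features, sa)
  ha <- relu(add_bias(ain %*% weights$W_atom, weights$b_atom))
  mol_index <- if (inherits(graph, "mt_batch_graph")) graph$mol_index
    else rep(1L, graph$n_atoms)
  n_mols <- if (inherits(graph, "mt_batch_graph")) graph$n_mols else 1L
  vec <- scatter_sum(ha, mol_index, n_mols)
  if (aggregation == "mean") {
    napm <- tabulate(mol_index, nbins = n_mols)
    vec <- vec / pmax(napm, 1L)
  }
  vec
}

# Full forward pass on a batched graph. Returns normalized-scale outputs;
# with cache=TRUE all intermediates needed by dmpnn_backward() are kept.
# `training` enables dropout (drawn from the current RNG stream).
dmpnn_forward <- function(bg, weights, params, descriptors = NULL,
                          cache = FALSE, training = FALSE) {
  h <- params$hidden_size
  p_drop <- if (training) params$dropout else 0
  ein <- cbind(bg$atom_features[bg$edge_source, , drop = FALSE],
               bg$edge_features)
  z0 <- add_bias(ein %*% weights$W_in, weights$b_in)
  hcur <- relu(z0)
  h_list <- if (cache) list(hcur) else NULL
  m_list <- if (cache) list() else NULL
  msg_masks <- if (cache) list() else NULL
  if (params$depth > 1L) for (t in seq_len(params$depth - 1L)) {
    s <- scatter_sum(hcur, bg$edge_target, bg$n_atoms)
    m <- s[bg$edge_source, , drop = FALSE]
    if (bg$n_directed_edges > 0L)
      m <- m - hcur[bg$reverse_edge, , drop = FALSE]
    hcur <- relu(z0 + m %*% weights$W_msg)
    mask <- NULL
    if (p_drop > 0) {
      mask <- drop_mask(nrow(hcur), ncol(hcur), p_drop)
      hcur <- hcur * mask
    }
    if (cache) {
      m_list[[t]] <- m
      h_list[[t + 1L]] <- hcur
      msg_masks[[t]] <- if (is.null(mask)) TRUE else mask
    }
  }
  sa <- scatter_sum(hcur, bg$edge_target, bg$n_atoms)
  ain <- cbind(bg$atom_features, sa)
  ha <- relu(add_bias(ain %*% weights$W_atom, weights$b_atom))
  atom_mask <- NULL
  if (p_drop > 0) {
    atom_mask <- drop_mask(nrow(ha), ncol(ha), p_drop)
    ha <- ha * atom_mask
  }
  vec <- scatter_sum(ha, bg$mol_index, bg$n_mols)
  napm <- tabulate(bg$mol_index, nbins = bg$n_mols)
  if (params$aggregation == "mean") vec <- vec / pmax(napm, 1L)
  x <- vec
  if (params$extra_descriptor_dim > 0L) {
    stopifnot(!is.null(descriptors),
              ncol(descriptors) == params$extra_descriptor_dim)
    x <- cbind(vec, descriptors)
  }
  L <- params$ffn_num_layers
  x_list <- if (cache) list(x) else NULL
  ffn_masks <- if (cache) list() else NULL
  for (l in seq_len(L)) {
    x <- add_bias(x %*% weights$ffn[[l]]$W, weights$ffn[[l]]$b)
    if (l < L) {
      x <- relu(x)
      mask <- NULL
      if (p_drop > 0) {
        mask <- drop_mask(nrow(x), ncol(x), p_drop)
        x <- x * mask
      }
      if (cache) {
        x_list[[l + 1L]] <- x
        ffn_masks[[l]] <- if (is.null(mask)) TRUE else mask
      }
    }
  }
  out <- x
  if (!cache) return(out)
  list(out = out, ein = ein, z0 = z0, h_list = h_list, m_list = m_list,
       msg_masks = msg_masks, sa = sa, ain = ain, ha = ha,
       atom_mask = atom_mask, vec = vec, x_list = x_list,
       ffn_masks = ffn_masks, napm = napm)
}

# Gradients of all weights given d(loss)/d(output). Mirrors dmpnn_forward().
dmpnn_backward <- function(bg, weights, params, cache, dout) {
  L <- params$ffn_num_layers
  g <- list(W_in = NULL, b_in = NULL, W_msg = NULL, W_atom = NULL,
            b_atom = NULL, ffn = vector("list", L))
  dx <- dout
  for (l in rev(seq_len(L))) {
    xprev <- cache$x_list[[l]]
    g$ffn[[l]] <- list(W = crossprod(xprev, dx), b = colSums(dx))
    dx <- dx %*% t(weights$ffn[[l]]$W)
    if (l > 1L) {
      mask <- cache$ffn_masks[[l - 1L]]
      if (!isTRUE(mask)) dx <- dx * mask
      dx <- dx * (cache$x_list[[l]] > 0)
    }
  }
  h <- params$hidden_size
  dvec <- dx[, seq_len(h), drop = FALSE]
  if (params$aggregation == "mean") dvec <- dvec / pmax(cache$napm, 1L)
  dha <- dvec[bg$mol_index, , drop = FALSE]
  if (!is.null(cache$atom_mask)) dha <- dha * cache$atom_mask
  dpa <- dha * (cache$ha > 0)
  g$W_atom <- crossprod(cache$ain, dpa)
  g$b_atom <- colSums(dpa)
  dain <- dpa %*% t(weights$W_atom)
  atom_dim <- ncol(bg$atom_features)
  dsa <- dain[, (atom_dim + 1L):(atom_dim + h), drop = FALSE]
  dh <- dsa[bg$edge_target, , drop = FALSE]
  dz0 <- matrix(0, nrow(cache$z0), h)
  g$W_msg <- matrix(0, h, h)
  if (params$depth > 1L) for (t in rev(seq_len(params$depth - 1L))) {
    mask <- cache$msg_masks[[t]]
    if (!isTRUE(mask)) dh <- dh * mask
    dp <- dh * (cache$h_list[[t + 1L]] != 0)
    dz0 <- dz0 + dp
    g$W_msg <- g$W_msg + crossprod(cache$m_list[[t]], dp)
    dm <- dp %*% t(weights$W_msg)
    tm <- scatter_sum(dm, bg$edge_source, bg$n_atoms)
    dh <- tm[bg$edge_target, , drop = FALSE]
    if (bg$n_directed_edges > 0L)
      dh <- dh - dm[bg$reverse_edge, , drop = FALSE]
  }
  dz0 <- dz0 + dh * (cache$z0 > 0)
  g$W_in <- crossprod(cache$ein, dz0)
  g$b_in <- colSums(dz0)
  g
}
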