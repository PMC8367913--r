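# Atom/bond feature vectors and the directed molecular graph consumed by the
# message-passing network. Feature vocabulary follows the usual D-MPNN
# convention: one-hot blocks plus a scaled atomic mass.

.ELEMENTS <- c("B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I")
.MASSES <- c(B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
             Si = 28.086, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904,
             I = 126.904)
.HYBS <- c("sp", "sp2", "sp3")
.CHARGES <- c(-2L, -1L, 0L, 1L, 2L)

one_hot <- function(idx, n) {
  m <- matrix(0, length(idx), n)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Dimensions of the atom and bond feature vectors
#' @return Named integer vector with entries `atom` and `bond`.
#' @export
feature_dims <- function() {
  c(atom = length(.ELEMENTS) + 1L + 6L + length(.CHARGES) + 1L + 1L + 5L +
      1L + length(.HYBS) + 1L + 1L,
    bond = 4L + 1L + 1L)
}

atom_feature_matrix <- function(mol) {
  a <- mol$atoms
  el <- match(a$element, .ELEMENTS, nomatch = length(.ELEMENTS) + 1L)
  deg <- pmin(a$degree, 5L) + 1L
  chg <- match(a$charge, .CHARGES, nomatch = length(.CHARGES) + 1L)
  nh <- pmin(a$n_h, 4L) + 1L
  hyb <- match(a$hyb, .HYBS, nomatch = length(.HYBS) + 1L)
  mass <- .MASSES[a$element]
  mass[is.na(mass)] <- 0
  cbind(
    one_hot(el, length(.ELEMENTS) + 1L),
    one_hot(deg, 6L),
    one_hot(chg, length(.CHARGES) + 1L),
    0,                                   # chirality flag (reserved; stereo not perceived)
    one_hot(nh, 5L),
    as.numeric(a$aromatic),
    one_hot(hyb, length(.HYBS) + 1L),
    mass / 100
  )
}

bond_feature_matrix <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0L) return(matrix(0, 0L, feature_dims()[["bond"]]))
  code <- ifelse(b$order == "ar", 4L,
          ifelse(b$order == "2", 2L,
          ifelse(b$order == "3", 3L, 1L)))   # "am"/"1"/unknown -> single
  cbind(one_hot(code, 4L), as.numeric(b$conjugated), as.numeric(b$in_ring))
}

#' Build the directed molecular graph for a parsed molecule
#'
#' Every bond becomes two directed edges with identical bond features; the
#' reverse-edge index is an involution used by the message-passing update to
#' exclude back-flow.
#'
#' @param mol An `mt_mol` from [parse_smiles()], or a SMILES string.
#' @return An object of class `mt_graph` with `n_atoms`, `n_directed_edges`,
#'   `atom_features`, `edge_features`, `edge_source`, `edge_target`,
#'   `reverse_edge` and `incoming_edges` (list of edge indices per atom).
#' @examples
#' \donttest{
#' g <- build_directed_graph(parse_smiles("CC"))
#' g$reverse_edge  # c(2, 1)
#' }
#' @export
build_directed_graph <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(inherits(mol, "mt_mol"))
  nb <- nrow(mol$bonds)
  ne <- 2L * nb
  src <- tgt <- integer(ne)
  if (nb) {
    src[seq(1L, ne, by = 2L)] <- mol$bonds$a1
    tgt[seq(1L, ne, by = 2L)] <- mol$bonds$a2
    src[seq(2L, ne, by = 2L)] <- mol$bonds$a2
    tgt[seq(2L, ne, by = 2L)] <- mol$bonds$a1
  }
  rev_e <- if (nb) as.integer(seq_len(ne) + c(1L, -1L)) else integer()
  bf <- bond_feature_matrix(mol)
  ef <- if (nb) bf[rep(seq_len(nb), each = 2L), , drop = FALSE] else
    matrix(0, 0L, feature_dims()[["bond"]])
  g <- list(
    n_atoms = mol$n_atoms,
    n_directed_edges = ne,
    atom_features = atom_feature_matrix(mol),
    edge_features = ef,
    edge_source = src,
    edge_target = tgt,
    reverse_edge = rev_e,
    incoming_edges = split(seq_len(ne), factor(tgt, levels = seq_len(mol$n_atoms))),
    smiles = mol$smiles,
    id = mol$id
  )
  class(g) <- "mt_graph"
  g
}

#' Concatenate molecular graphs into one batched graph
#'
#' Atom and edge indices are offset so a single set of matrix operations
#' evaluates the whole batch; `mol_index` maps atoms back to molecules.
#'
#' @param graphs List of `mt_graph` objects.
#' @return An `mt_batch_graph`.
#' @export
combine_graphs <- function(graphs) {
  stopifnot(length(graphs) >= 1L)
  na <- vapply(graphs, `[[`, integer(1), "n_atoms")
  ne <- vapply(graphs, `[[`, integer(1), "n_directed_edges")
  a_off <- cumsum(c(0L, na[-length(na)]))
  e_off <- cumsum(c(0L, ne[-length(ne)]))
  src <- unlist(lapply(seq_along(graphs), function(i)
    graphs[[i]]$edge_source + a_off[i]), use.names = FALSE)
  tgt <- unlist(lapply(seq_along(graphs), function(i)
    graphs[[i]]$edge_target + a_off[i]), use.names = FALSE)
  rev_e <- unlist(lapply(seq_along(graphs), function(i)
    graphs[[i]]$reverse_edge + e_off[i]), use.names = FALSE)
  bg <- list(
    n_mols = length(graphs),
    n_atoms = sum(na),
    n_directed_edges = sum(ne),
    atom_features = do.call(rbind, lapply(graphs, `[[`, "atom_features")),
    edge_features = do.call(rbind, lapply(graphs, `[[`, "edge_features")),
    edge_source = as.integer(src),
    edge_target = as.integer(tgt),
    reverse_edge = as.integer(rev_e),
    mol_index = rep(seq_along(graphs), times = na),
    atoms_per_mol = na
  )
  class(bg) <- "mt_batch_graph"
  bg
}
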