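# Molecule perception via OpenBabel (ChemmineOB). A parsed molecule is a
# light-weight list holding per-atom and per-bond annotation on the heavy-atom
# graph; hydrogens are counted but never become graph nodes.

FEATURIZATION_VERSION <- "mtlogp-feat-1"

#' Parse a single SMILES string
#'
#' Perceives aromaticity, hybridization, formal charges and implicit hydrogen
#' counts with OpenBabel and returns the heavy-atom molecular graph. Salts and
#' mixtures are reduced to their largest fragment (a message is emitted).
#'
#' @param smiles SMILES string.
#' @param id Optional identifier attached to the molecule.
#' @return An object of class `mt_mol` with elements `smiles`, `id`,
#'   `n_atoms`, `atoms` (data frame: `element`, `aromatic`, `hyb`, `charge`,
#'   `n_h`, `degree`, `in_ring`) and `bonds` (data frame: `a1`, `a2`, `order`,
#'   `aromatic`, `in_ring`, `conjugated`).
#' @examples
#' \donttest{
#' mol <- parse_smiles("c1ccccc1")
#' mol$n_atoms
#' }
#' @export
parse_smiles <- function(smiles, id = NULL) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(trimws(smiles)))
    stop("parse_smiles() expects a single non-empty SMILES string")
  res <- parse_smiles_batch(smiles, ids = if (is.null(id)) NA_character_ else id)
  if (length(res$mols) == 0L || is.null(res$mols[[1L]]))
    stop(sprintf("invalid SMILES: '%s'", smiles))
  res$mols[[1L]]
}

#' Parse a vector of SMILES strings in one OpenBabel pass
#'
#' Unparsable entries are returned as `NULL` and reported in `$failures`
#' rather than aborting the batch, so curation code can drop-and-log.
#'
#' @param smiles Character vector of SMILES.
#' @param ids Optional identifiers (recycled `NA` if missing).
#' @return List with `mols` (list of `mt_mol` or `NULL`) and `failures`
#'   (integer indices of entries that failed to parse).
#' @export
parse_smiles_batch <- function(smiles, ids = NULL) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  if (is.null(ids)) ids <- rep(NA_character_, n)
  ids <- as.character(ids)
  mols <- vector("list", n)
  ok_syntax <- nzchar(trimws(smiles)) & !is.na(smiles) & !grepl("[[:space:]]", trimws(smiles))
  idx <- which(ok_syntax)
  if (length(idx)) {
    # an invalid SMILES aborts OpenBabel's stream at that record, so restart
    # the conversion after each failure point until all entries are seen
    parsed <- list()
    charges <- list()
    remaining <- idx
    while (length(remaining)) {
      src <- paste0(paste(trimws(smiles[remaining]),
                          paste0("MTLOGP_", remaining), collapse = "\n"),
                    "\n")
      pm <- parse_mol2_blocks(chemmine_convert("SMI", "MOL2", src,
                                               add_h = TRUE))
      ps <- parse_sdf_charges(chemmine_convert("SMI", "SDF", src))
      parsed <- c(parsed, pm)
      charges <- c(charges, ps)
      present <- paste0("MTLOGP_", remaining) %in% names(pm)
      if (all(present)) break
      remaining <- remaining[-seq_len(which(!present)[1L])]
    }
    for (k in seq_along(idx)) {
      i <- idx[k]
      p <- parsed[[paste0("MTLOGP_", i)]]
      if (is.null(p) || p$n_atoms < 1L) next
      chg <- charges[[paste0("MTLOGP_", i)]]
      mols[[i]] <- finish_mol(p, chg, smiles = trimws(smiles[i]), id = ids[i])
    }
  }
  failures <- which(vapply(mols, is.null, logical(1)))
  list(mols = mols, failures = failures)
}

# One funnel for all ChemmineOB conversions so options are consistent.
chemmine_convert <- function(from, to, source, add_h = FALSE) {
  opts <- data.frame(names = if (add_h) "h" else character(0),
                     args = if (add_h) "" else character(0),
                     stringsAsFactors = FALSE)
  if (nrow(opts) == 0L)
    ChemmineOB::convertFormat(from, to, source = source,
                              options = data.frame(names = "", args = ""))
  else
    ChemmineOB::convertFormat(from, to, source = source, options = opts)
}

# Split a multi-molecule MOL2 string into per-title structures.
parse_mol2_blocks <- function(text) {
  out <- list()
  if (!nzchar(text)) return(out)
  blocks <- strsplit(text, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1L]]
  blocks <- blocks[-1L]
  for (b in blocks) {
    # each block starts "\n<title>\n<natoms nbonds ...>\n..."
    lines <- strsplit(b, "\n", fixed = TRUE)[[1L]]
    title <- trimws(lines[2L])
    counts <- as.integer(strsplit(trimws(lines[3L]), "[[:space:]]+")[[1L]][1:2])
    na_all <- counts[1L]; nb_all <- counts[2L]
    atom_at <- which(trimws(lines) == "@<TRIPOS>ATOM")[1L]
    bond_at <- which(trimws(lines) == "@<TRIPOS>BOND")[1L]
    if (is.na(atom_at) || na_all < 1L) next
    atom_lines <- lines[(atom_at + 1L):(atom_at + na_all)]
    af <- strsplit(trimws(atom_lines), "[[:space:]]+")
    type <- vapply(af, `[`, character(1), 6L)
    element <- sub("\\..*$", "", type)
    hyb_suffix <- ifelse(grepl("\\.", type), sub("^[^.]*\\.", "", type), "")
    bonds <- NULL
    if (!is.na(bond_at) && nb_all > 0L) {
      bond_lines <- lines[(bond_at + 1L):(bond_at + nb_all)]
      bf <- strsplit(trimws(bond_lines), "[[:space:]]+")
      bonds <- data.frame(
        a1 = as.integer(vapply(bf, `[`, character(1), 2L)),
        a2 = as.integer(vapply(bf, `[`, character(1), 3L)),
        order = vapply(bf, `[`, character(1), 4L),
        stringsAsFactors = FALSE
      )
    }
    out[[title]] <- list(
      n_atoms = na_all,
      element = element,
      hyb_suffix = hyb_suffix,
      bonds = bonds
    )
  }
  out
}

# Formal charges per heavy atom from the parallel SDF conversion (M CHG).
parse_sdf_charges <- function(text) {
  out <- list()
  if (!nzchar(text)) return(out)
  recs <- strsplit(text, "\\$\\$\\$\\$\n")[[1L]]
  for (r in recs) {
    lines <- strsplit(r, "\n", fixed = TRUE)[[1L]]
    if (length(lines) < 4L) next
    title <- trimws(lines[1L])
    natoms <- suppressWarnings(as.integer(substr(lines[4L], 1L, 3L)))
    if (is.na(natoms)) next
    chg <- integer(natoms)
    for (ml in grep("^M  CHG", lines, value = TRUE)) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ml)), "[[:space:]]+")[[1L]])
      k <- f[1L]
      for (j in seq_len(k)) chg[f[2L * j]] <- f[2L * j + 1L]
    }
    out[[title]] <- chg
  }
  out
}

# Assemble the mt_mol: strip hydrogens, count them, annotate rings/degree,
# keep only the largest connected fragment.
finish_mol <- function(p, chg, smiles, id) {
  heavy <- which(p$element != "H")
  if (length(heavy) == 0L) return(NULL)
  map <- integer(p$n_atoms)
  map[heavy] <- seq_along(heavy)
  n_h <- integer(length(heavy))
  bonds <- p$bonds
  if (!is.null(bonds)) {
    h1 <- p$element[bonds$a1] == "H"
    h2 <- p$element[bonds$a2] == "H"
    hb <- h1 | h2
    if (any(hb)) {
      heavy_end <- ifelse(h1[hb], bonds$a2[hb], bonds$a1[hb])
      heavy_end <- heavy_end[p$element[heavy_end] != "H"]
      tab <- table(map[heavy_end])
      n_h[as.integer(names(tab))] <- as.integer(tab)
      bonds <- bonds[!hb, , drop = FALSE]
    }
    if (nrow(bonds)) {
      bonds$a1 <- map[bonds$a1]
      bonds$a2 <- map[bonds$a2]
    }
  }
  if (is.null(bonds)) bonds <- data.frame(a1 = integer(), a2 = integer(),
                                          order = character(), stringsAsFactors = FALSE)
  n <- length(heavy)
  # SDF output (no -h) lists the same heavy atoms in the same input order
  charge <- integer(n)
  if (!is.null(chg)) {
    k <- min(n, length(chg))
    charge[seq_len(k)] <- chg[seq_len(k)]
  }
  # ring perception: a bond is in a ring iff it is not a bridge
  in_ring_bond <- rep(FALSE, nrow(bonds))
  if (nrow(bonds)) {
    g <- igraph::make_graph(edges = rbind(bonds$a1, bonds$a2), n = n,
                            directed = FALSE)
    br <- igraph::bridges(g)
    in_ring_bond <- !(seq_len(nrow(bonds)) %in% as.integer(br))
  }
  degree <- tabulate(c(bonds$a1, bonds$a2), nbins = n)
  aromatic <- p$hyb_suffix[heavy] == "ar"
  if (nrow(bonds)) {
    ar_b <- bonds$order == "ar"
    aromatic[unique(c(bonds$a1[ar_b], bonds$a2[ar_b]))] <- TRUE
  }
  hyb <- vapply(p$hyb_suffix[heavy], function(s) {
    switch(s, "1" = "sp", "2" = , "ar" = , "am" = , "pl3" = , "co2" = ,
           "cat" = "sp2", "3" = "sp3", "other")
  }, character(1), USE.NAMES = FALSE)
  in_ring_atom <- rep(FALSE, n)
  if (any(in_ring_bond))
    in_ring_atom[unique(c(bonds$a1[in_ring_bond], bonds$a2[in_ring_bond]))] <- TRUE
  unsat <- hyb %in% c("sp", "sp2")
  conj <- rep(FALSE, nrow(bonds))
  if (nrow(bonds))
    conj <- bonds$order %in% c("2", "3", "ar", "am") |
      (unsat[bonds$a1] & unsat[bonds$a2])
  mol <- list(
    smiles = smiles,
    id = if (is.na(id)) NULL else id,
    n_atoms = n,
    atoms = data.frame(element = p$element[heavy], aromatic = aromatic,
                       hyb = hyb, charge = charge, n_h = n_h, degree = degree,
                       in_ring = in_ring_atom, stringsAsFactors = FALSE),
    bonds = data.frame(a1 = bonds$a1, a2 = bonds$a2, order = bonds$order,
                       aromatic = if (nrow(bonds)) bonds$order == "ar" else logical(),
                       in_ring = in_ring_bond, conjugated = conj,
                       stringsAsFactors = FALSE)
  )
  class(mol) <- "mt_mol"
  largest_fragment(mol)
}

# Keep the largest connected fragment (salt/mixture stripping).
largest_fragment <- function(mol) {
  if (mol$n_atoms <= 1L || nrow(mol$bonds) == 0L) {
    if (mol$n_atoms > 1L && nrow(mol$bonds) == 0L) {
      # n disconnected atoms: keep the first
      message(sprintf("keeping largest fragment of '%s' (1/%d atoms)",
                      mol$smiles, mol$n_atoms))
      mol$atoms <- mol$atoms[1L, , drop = FALSE]
      mol$n_atoms <- 1L
    }
    return(mol)
  }
  g <- igraph::make_graph(edges = rbind(mol$bonds$a1, mol$bonds$a2),
                          n = mol$n_atoms, directed = FALSE)
  comp <- igraph::components(g)
  if (comp$no == 1L) return(mol)
  keep_comp <- which.max(comp$csize)
  keep <- which(comp$membership == keep_comp)
  message(sprintf("keeping largest fragment of '%s' (%d/%d atoms)",
                  mol$smiles, length(keep), mol$n_atoms))
  map <- integer(mol$n_atoms)
  map[keep] <- seq_along(keep)
  kb <- mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep
  mol$atoms <- mol$atoms[keep, , drop = FALSE]
  rownames(mol$atoms) <- NULL
  mol$bonds <- mol$bonds[kb, , drop = FALSE]
  mol$bonds$a1 <- map[mol$bonds$a1]
  mol$bonds$a2 <- map[mol$bonds$a2]
  rownames(mol$bonds) <- NULL
  mol$n_atoms <- length(keep)
  mol
}

#' @export
print.mt_mol <- function(x, ...) {
  cat(sprintf("<mt_mol> %s: %d heavy atoms, %d bonds\n",
              x$smiles, x$n_atoms, nrow(x$bonds)))
  invisible(x)
}
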