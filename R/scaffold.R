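# Bemis-Murcko frameworks: rings plus linkers, side chains removed. The
# scaffold subgraph is pruned on our own graph and canonicalized through
# OpenBabel (a generated V2000 molblock with aromatic bonds as order 4).

scaffold_atom_set <- function(mol) {
  keep <- rep(TRUE, mol$n_atoms)
  if (nrow(mol$bonds) == 0L) return(integer())
  repeat {
    deg <- tabulate(c(mol$bonds$a1[keep[mol$bonds$a1] & keep[mol$bonds$a2]],
                      mol$bonds$a2[keep[mol$bonds$a1] & keep[mol$bonds$a2]]),
                    nbins = mol$n_atoms)
    drop <- keep & deg <= 1L
    if (!any(drop)) break
    keep[drop] <- FALSE
    if (!any(keep)) break
  }
  which(keep)
}

mol_to_molblock <- function(elements, charges, bonds, title = "scaffold") {
  n <- length(elements)
  nb <- nrow(bonds)
  atom_lines <- sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    elements)
  bond_lines <- if (nb) sprintf("%3d%3d%3d  0", bonds$a1, bonds$a2, bonds$code)
    else character()
  chg_idx <- which(charges != 0L)
  chg_lines <- if (length(chg_idx))
    vapply(chg_idx, function(i) sprintf("M  CHG  1 %3d %3d", i, charges[i]),
           character(1)) else character()
  paste0(title, "\n mtlogp\n\n",
         sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000\n", n, nb),
         paste(c(atom_lines, bond_lines, chg_lines, "M  END", "$$$$"),
               collapse = "\n"), "\n")
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Returns the canonical SMILES of the ring-and-linker framework; acyclic
#' molecules map to the empty scaffold class `""`.
#'
#' @param mol An `mt_mol` or SMILES string.
#' @return Scaffold SMILES (`""` for acyclic molecules).
#' @export
murcko_scaffold <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  murcko_scaffolds(list(mol))[1L]
}

#' Bemis-Murcko scaffolds for a set of molecules
#'
#' @param mols List of `mt_mol` objects (or character vector of SMILES).
#'   `NULL` entries yield `NA`.
#' @return Character vector of scaffold SMILES (`""` = acyclic).
#' @export
murcko_scaffolds <- function(mols) {
  if (is.character(mols)) mols <- parse_smiles_batch(mols)$mols
  out <- rep(NA_character_, length(mols))
  blocks <- character()
  which_block <- integer()
  for (i in seq_along(mols)) {
    mol <- mols[[i]]
    if (is.null(mol)) next
    keep <- scaffold_atom_set(mol)
    if (length(keep) == 0L) { out[i] <- ""; next }
    map <- integer(mol$n_atoms)
    map[keep] <- seq_along(keep)
    kb <- mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep
    b <- mol$bonds[kb, , drop = FALSE]
    code <- ifelse(b$order == "ar", 4L,
            ifelse(b$order == "2", 2L,
            ifelse(b$order == "3", 3L, 1L)))
    blocks <- c(blocks, mol_to_molblock(
      mol$atoms$element[keep], mol$atoms$charge[keep],
      data.frame(a1 = map[b$a1], a2 = map[b$a2], code = code),
      title = paste0("MTLOGP_", i)))
    which_block <- c(which_block, i)
  }
  if (length(blocks)) {
    can <- chemmine_convert("SDF", "CAN", paste(blocks, collapse = ""))
    lines <- strsplit(can, "\n", fixed = TRUE)[[1L]]
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      f <- strsplit(ln, "[[:space:]]+")[[1L]]
      if (length(f) < 2L) next
      i <- suppressWarnings(as.integer(sub("^MTLOGP_", "", f[2L])))
      if (!is.na(i)) out[i] <- f[1L]
    }
  }
  out
}
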